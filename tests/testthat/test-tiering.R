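kb <- default_knowledge_base()

test_that("the rule engine reproduces the schema's anchor cases", {
  # pathogenic germline variant in a therapeutic DSB-repair gene: tier 1 G,
  # flagged as the germline-therapeutic (G1*) mark
  g <- assign_tier(list(patient_id = "P1", gene = "BRCA2",
                        alt_class = "mutation", origin = "germline",
                        pathogenicity = "pathogenic",
                        cancer_type = "prostate"), kb)
  expect_equal(g[c("tier", "subcategory", "germline_therapeutic_flag")],
               list(tier = 1L, subcategory = "G",
                    germline_therapeutic_flag = TRUE))

  # investigational/off-label rationale: tier 2 S (ERBB2 amplification in a
  # cancer type outside its approved indication)
  s2 <- assign_tier(list(gene = "ERBB2", alt_class = "amplification",
                         origin = "somatic", pathogenicity = "other",
                         cancer_type = "CUP"), kb)
  expect_equal(s2[c("tier", "subcategory")], list(tier = 2L, subcategory = "S"))

  # same event in its approved indication: tier 1 S
  s1 <- assign_tier(list(gene = "ERBB2", alt_class = "amplification",
                         origin = "somatic", pathogenicity = "other",
                         cancer_type = "breast"), kb)
  expect_equal(s1[c("tier", "subcategory")], list(tier = 1L, subcategory = "S"))

  # FDA-approved resistance in indication: tier 1 R
  r1 <- assign_tier(list(gene = "KRAS", alt_class = "mutation",
                         origin = "somatic", pathogenicity = "other",
                         cancer_type = "lung"), kb)
  expect_equal(r1[c("tier", "subcategory")], list(tier = 1L, subcategory = "R"))

  # preclinical resistance: tier 2 R
  r2 <- assign_tier(list(gene = "MDM2", alt_class = "amplification",
                         origin = "somatic", pathogenicity = "other",
                         cancer_type = "sarcoma"), kb)
  expect_equal(r2[c("tier", "subcategory")], list(tier = 2L, subcategory = "R"))

  # biological relevance only: tier 3 S
  s3 <- assign_tier(list(gene = "TP53", alt_class = "mutation",
                         origin = "somatic", pathogenicity = "other",
                         cancer_type = "lung"), kb)
  expect_equal(s3[c("tier", "subcategory")], list(tier = 3L, subcategory = "S"))

  # diagnosis change: tier 1 D; without a change, tier 3
  d <- assign_tier(list(gene = "NA1", alt_class = "diagnosis_marker",
                        origin = "somatic", cancer_type = "CUP"), kb,
                   diagnosis_changed = TRUE)
  expect_equal(d[c("tier", "subcategory")], list(tier = 1L, subcategory = "D"))
  d0 <- assign_tier(list(gene = "NA1", alt_class = "diagnosis_marker",
                         origin = "somatic", cancer_type = "CUP"), kb,
                    diagnosis_changed = FALSE)
  expect_equal(d0$tier, 3L)
})

test_that("stronger evidence dominates when several entries match", {
  kb2 <- rbind(kb, data.frame(
    entry_id = c("X1", "X2"), gene = "GENEX", alt_pattern = "mutation",
    context = c("ANY", "lung"),
    evidence = c("BIOLOGICAL_ONLY", "FDA_APPROVED_BENEFIT"),
    germline_risk = "NONE", germline_therapeutic = FALSE))
  a <- assign_tier(list(gene = "GENEX", alt_class = "mutation",
                        origin = "somatic", pathogenicity = "other",
                        cancer_type = "lung"), kb2)
  expect_equal(a[c("tier", "subcategory")], list(tier = 1L, subcategory = "S"))
  expect_equal(a$rationale, "X2")
})

test_that("unmatched and malformed alterations are handled per contract", {
  a <- assign_tier(list(gene = "NOGENE", alt_class = "mutation",
                        origin = "somatic", pathogenicity = "other",
                        cancer_type = "lung"), kb)
  expect_equal(a$tier, 3L)
  expect_equal(a$rationale, "")
  expect_error(assign_tier(list(gene = "BRCA1", alt_class = "amplification",
                                origin = "germline",
                                pathogenicity = "pathogenic"), kb),
               "class mutation")
  expect_error(assign_tier(list(gene = "X", alt_class = "nonsense",
                                origin = "somatic"), kb), "unknown alteration")
})

test_that("tiering is total, idempotent and evidence-monotone over randomized fixtures", {
  evidence_ladder <- c("BIOLOGICAL_ONLY", "PRECLINICAL_RESISTANCE",
                       "INVESTIGATIONAL_OR_OFF_LABEL",
                       "FDA_APPROVED_RESISTANCE", "FDA_APPROVED_BENEFIT")
  set.seed(2024)
  n_cases <- 2000L
  for (i in seq_len(n_cases)) {
    alt <- random_alteration(kb)
    a1 <- assign_tier(alt, kb)
    # totality: every validated alteration gets exactly one assignment
    expect_true(a1$tier %in% 1:3)
    expect_true(a1$subcategory %in% c("G", "D", "S", "R"))
    # idempotence / determinism
    expect_identical(assign_tier(alt, kb), a1)
    # evidence monotonicity: upgrading one matching somatic entry never
    # increases the numeric tier
    if (i %% 5 == 0 && alt$origin == "somatic") {
      match_rows <- which(kb$gene == alt$gene)
      if (length(match_rows)) {
        r <- sample(match_rows, 1)
        lev <- match(kb$evidence[r], evidence_ladder)
        if (!is.na(lev) && lev < length(evidence_ladder)) {
          kb_up <- kb
          kb_up$evidence[r] <- evidence_ladder[lev + 1L]
          a2 <- assign_tier(alt, kb_up)
          expect_lte(a2$tier, a1$tier)
        }
      }
    }
  }
})

test_that("actionability summarises per patient with deduplication", {
  alts <- data.frame(
    patient_id = c("A", "A", "B", "C"),
    gene = c("BRCA2", "TP53", "TP53", "ERBB2"),
    alt_class = c("mutation", "mutation", "mutation", "amplification"),
    origin = c("germline", "somatic", "somatic", "somatic"),
    pathogenicity = c("pathogenic", "other", "other", "other"),
    cancer_type = c("prostate", "prostate", "lung", "CUP"))
  tiers <- assign_tiers(alts, kb)
  s <- summarize_actionability(tiers)
  # A: tier-1 G + tier-3 -> actionable once; B: tier-3 only; C: tier-2 S
  expect_equal(s$n_actionable, 2L)
  expect_equal(s$n_tier2_somatic, 1L)
  # duplicating a record never changes patient-level counts
  tiers_dup <- rbind(tiers, tiers[4, ])
  expect_equal(summarize_actionability(tiers_dup)$n_actionable, 2L)
  expect_error(summarize_actionability(tiers[0, ]), "non-empty")
})
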