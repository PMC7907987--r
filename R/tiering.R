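ALT_CLASSES <- c("mutation", "amplification", "homozygous_deletion", "fusion",
                 "outlier_expression", "viral", "diagnosis_marker", "loh")
EVIDENCE_LEVELS <- c("FDA_APPROVED_BENEFIT", "FDA_APPROVED_RESISTANCE",
                     "INVESTIGATIONAL_OR_OFF_LABEL", "PRECLINICAL_RESISTANCE",
                     "BIOLOGICAL_ONLY")
GERMLINE_RISKS <- c("HIGH_PENETRANT", "MODERATE_PENETRANT", "AR_CANCER_RISK",
                    "AR_NONCANCER", "NONE")

#' Read a therapy knowledge base from TSV
#'
#' The knowledge base is a frozen local snapshot of gene-alteration-context
#' evidence (the role live resources such as OncoKB or CIViC play in a
#' clinical pipeline). Columns: `entry_id`, `gene`, `alt_pattern`
#' (pipe-separated alteration classes or `ANY`), `context` (cancer-type
#' label or `ANY`), `evidence` (one of FDA_APPROVED_BENEFIT,
#' FDA_APPROVED_RESISTANCE, INVESTIGATIONAL_OR_OFF_LABEL,
#' PRECLINICAL_RESISTANCE, BIOLOGICAL_ONLY), `germline_risk`,
#' `germline_therapeutic` (logical).
#'
#' @param path TSV file path.
#' @return a validated knowledge-base data frame.
#' @export
read_knowledge_base <- function(path) {
  kb <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("entry_id", "gene", "alt_pattern", "context", "evidence",
                "germline_risk", "germline_therapeutic")
  missing <- setdiff(required, names(kb))
  stop_if_not(length(missing) == 0,
              paste("knowledge base lacks column(s):",
                    paste(missing, collapse = ", ")))
  bad <- !(kb$evidence %in% c(EVIDENCE_LEVELS, "NONE"))
  stop_if_not(!any(bad), "knowledge base contains unknown evidence levels")
  stop_if_not(all(kb$germline_risk %in% GERMLINE_RISKS),
              "knowledge base contains unknown germline risk levels")
  kb$germline_therapeutic <- as.logical(kb$germline_therapeutic)
  stop_if_not(!any(kb$evidence == "NONE" & kb$germline_risk == "NONE"),
              "entries must carry somatic evidence or a germline risk")
  kb
}

#' Bundled example knowledge base
#'
#' A small curated snapshot shipped with the package (synthetic, for the
#' synthetic cohort and the examples; real deployments supply their own
#' frozen export via [read_knowledge_base()]). Somatic evidence entries come
#' from the shipped TSV; germline cancer-risk entries are derived from the
#' gene panel so the two stay consistent.
#'
#' @param panel gene panel used to derive germline entries (default
#'   [default_gene_panel()]).
#' @return knowledge-base data frame.
#' @export
default_knowledge_base <- function(panel = default_gene_panel()) {
  somatic <- read_knowledge_base(
    system.file("extdata", "knowledge_base_synthetic.tsv",
                package = "seqdirect", mustWork = TRUE))
  germline <- data.frame(
    entry_id = paste0("GL_", panel$gene),
    gene = panel$gene,
    alt_pattern = "mutation",
    context = "ANY",
    evidence = "NONE",
    germline_risk = panel$category,
    germline_therapeutic = panel$therapeutic_target,
    stringsAsFactors = FALSE)
  rbind(somatic, germline)
}

validate_alteration <- function(alt) {
  required <- c("gene", "alt_class", "origin")
  missing <- setdiff(required, names(alt))
  stop_if_not(length(missing) == 0,
              paste("alteration lacks field(s):", paste(missing, collapse = ", ")))
  stop_if_not(alt$alt_class %in% ALT_CLASSES,
              paste("unknown alteration class:", alt$alt_class))
  stop_if_not(alt$origin %in% c("somatic", "germline"),
              "origin must be somatic or germline")
  if (alt$origin == "germline") {
    stop_if_not(alt$alt_class == "mutation",
                "germline records must be of class mutation")
    stop_if_not(!is.null(alt$pathogenicity) && !is.na(alt$pathogenicity),
                "germline records require a pathogenicity call")
  }
  invisible(alt)
}

kb_matches <- function(kb, gene, alt_class, context_exact = NULL) {
  hit <- kb$gene == gene &
    vapply(kb$alt_pattern, function(p) {
      p == "ANY" || alt_class %in% strsplit(p, "|", fixed = TRUE)[[1]]
    }, logical(1))
  if (!is.null(context_exact)) {
    hit <- hit & (kb$context == "ANY" | kb$context == context_exact)
  }
  kb[hit, , drop = FALSE]
}

# subcategory priority for conflict resolution: G < D < S < R
SUBCAT_ORDER <- c(G = 1L, D = 2L, S = 3L, R = 4L)

tier_of_entry <- function(evidence, in_context) {
  switch(evidence,
         FDA_APPROVED_BENEFIT = if (in_context) list(1L, "S") else list(2L, "S"),
         FDA_APPROVED_RESISTANCE = if (in_context) list(1L, "R") else list(2L, "R"),
         INVESTIGATIONAL_OR_OFF_LABEL = list(2L, "S"),
         PRECLINICAL_RESISTANCE = list(2L, "R"),
         BIOLOGICAL_ONLY = list(3L, "S"),
         NULL)
}

#' Assign a clinical-actionability tier to one alteration
#'
#' Deterministic rule engine implementing the three-tier schema:
#'
#' * Tier 1 — established clinical utility in the patient's cancer type:
#'   pathogenic/likely-pathogenic germline variants with a cancer-risk
#'   knowledge-base entry (subcategory G, flagged `germline_therapeutic`
#'   when the gene has direct therapeutic implications, the "G1*" mark);
#'   a transcriptome-driven change of diagnosis (subcategory D); somatic
#'   events matching FDA-approved benefit (S) or resistance (R) evidence in
#'   that indication.
#' * Tier 2 — rationale for investigational or off-label therapy (S), or
#'   resistance postulated from strong preclinical evidence (R). Somatic
#'   events whose FDA-approved evidence is for a different indication also
#'   land here (off-label rationale).
#' * Tier 3 — biological relevance without current therapeutic implication;
#'   alterations with no knowledge-base match default here with an empty
#'   rationale.
#'
#' When several entries match, the strongest wins: tier ascending, then
#' subcategory order G < D < S < R, then entry id.
#'
#' @param alt one alteration: list or one-row data frame with `gene`,
#'   `alt_class`, `origin`, `pathogenicity`, `cancer_type`.
#' @param kb knowledge-base data frame.
#' @param diagnosis_changed did transcriptome profiling change this
#'   patient's cancer diagnosis (drives tier 1 D for diagnosis markers)?
#' @return list with `tier` (1/2/3), `subcategory` (G/D/S/R),
#'   `germline_therapeutic_flag`, and `rationale` (matched `entry_id` or
#'   `""`).
#' @export
assign_tier <- function(alt, kb, diagnosis_changed = FALSE) {
  if (is.data.frame(alt)) alt <- as.list(alt[1, ])
  validate_alteration(alt)
  ctype <- alt$cancer_type %||% "ANY"

  if (alt$origin == "germline") {
    if (!(alt$pathogenicity %in% c("pathogenic", "likely_pathogenic"))) {
      return(list(tier = 3L, subcategory = "G",
                  germline_therapeutic_flag = FALSE, rationale = ""))
    }
    hits <- kb_matches(kb, alt$gene, alt$alt_class)
    hits <- hits[hits$germline_risk != "NONE", , drop = FALSE]
    if (nrow(hits) == 0) {
      return(list(tier = 3L, subcategory = "G",
                  germline_therapeutic_flag = FALSE, rationale = ""))
    }
    cancer_risk <- hits$germline_risk %in%
      c("HIGH_PENETRANT", "MODERATE_PENETRANT", "AR_CANCER_RISK")
    if (any(cancer_risk)) {
      h <- hits[cancer_risk, , drop = FALSE]
      h <- h[order(!h$germline_therapeutic, h$entry_id), , drop = FALSE]
      return(list(tier = 1L, subcategory = "G",
                  germline_therapeutic_flag = isTRUE(h$germline_therapeutic[1]),
                  rationale = h$entry_id[1]))
    }
    # AR condition without cancer risk: reportable, no clinical action
    return(list(tier = 3L, subcategory = "G",
                germline_therapeutic_flag = FALSE,
                rationale = hits$entry_id[1]))
  }

  if (alt$alt_class == "diagnosis_marker") {
    if (isTRUE(diagnosis_changed)) {
      return(list(tier = 1L, subcategory = "D",
                  germline_therapeutic_flag = FALSE, rationale = ""))
    }
    return(list(tier = 3L, subcategory = "S",
                germline_therapeutic_flag = FALSE, rationale = ""))
  }

  hits <- kb_matches(kb, alt$gene, alt$alt_class)
  hits <- hits[hits$evidence != "NONE", , drop = FALSE]
  if (nrow(hits) == 0) {
    return(list(tier = 3L, subcategory = "S",
                germline_therapeutic_flag = FALSE, rationale = ""))
  }
  cand <- lapply(seq_len(nrow(hits)), function(i) {
    in_ctx <- hits$context[i] == "ANY" || hits$context[i] == ctype
    ts <- tier_of_entry(hits$evidence[i], in_ctx)
    if (is.null(ts)) return(NULL)
    list(tier = ts[[1]], subcategory = ts[[2]], entry_id = hits$entry_id[i])
  })
  cand <- Filter(Negate(is.null), cand)
  if (length(cand) == 0) {
    return(list(tier = 3L, subcategory = "S",
                germline_therapeutic_flag = FALSE, rationale = ""))
  }
  keys <- vapply(cand, function(cd) {
    sprintf("%d.%d.%s", cd$tier, SUBCAT_ORDER[[cd$subcategory]], cd$entry_id)
  }, character(1))
  best <- cand[[order(keys)[1]]]
  list(tier = best$tier, subcategory = best$subcategory,
       germline_therapeutic_flag = FALSE, rationale = best$entry_id)
}

#' Tier every alteration in a table
#'
#' Vector wrapper over [assign_tier()].
#'
#' @param alterations data frame of alterations (`patient_id`, `gene`,
#'   `alt_class`, `origin`, `pathogenicity`, `cancer_type`).
#' @param kb knowledge-base data frame.
#' @param diagnosis_changed logical, one value or one per patient (named by
#'   patient id).
#' @return the input with `tier`, `subcategory`,
#'   `germline_therapeutic_flag`, and `rationale` columns appended.
#' @export
assign_tiers <- function(alterations, kb, diagnosis_changed = FALSE) {
  dc <- diagnosis_changed
  res <- lapply(seq_len(nrow(alterations)), function(i) {
    alt <- as.list(alterations[i, ])
    dci <- if (length(dc) > 1L) isTRUE(dc[[alt$patient_id]]) else isTRUE(dc)
    assign_tier(alt, kb, dci)
  })
  alterations$tier <- vapply(res, `[[`, integer(1), "tier")
  alterations$subcategory <- vapply(res, `[[`, character(1), "subcategory")
  alterations$germline_therapeutic_flag <-
    vapply(res, `[[`, logical(1), "germline_therapeutic_flag")
  alterations$rationale <- vapply(res, `[[`, character(1), "rationale")
  alterations
}

#' Summarize cohort actionability
#'
#' A patient is potentially actionable when they harbor at least one tier-1
#' or tier-2 assignment. Counts are deduplicated at the patient level, so
#' duplicate alteration records never inflate them.
#'
#' @param assignments tiered alteration table from [assign_tiers()] (needs
#'   `patient_id`, `tier`, `subcategory`, `origin`).
#' @param cohort_size total patients sequenced (>= patients in the table);
#'   default: patients present in the table.
#' @return list of counts and round-half-up percentages: `n_cohort`,
#'   `n_actionable`, `actionable_pct`, `n_tier2_somatic`,
#'   `tier2_somatic_pct`.
#' @export
summarize_actionability <- function(assignments, cohort_size = NULL) {
  stop_if_not(nrow(assignments) > 0, "cohort must be non-empty")
  by_patient <- split(assignments, assignments$patient_id)
  n_in_table <- length(by_patient)
  cohort_size <- if (is.null(cohort_size)) n_in_table else
    check_count(cohort_size, "cohort_size")
  stop_if_not(cohort_size >= n_in_table,
              "`cohort_size` must be >= patients present in the table")
  actionable <- vapply(by_patient, function(d) any(d$tier <= 2L), logical(1))
  tier2s <- vapply(by_patient, function(d) {
    any(d$tier == 2L & d$subcategory == "S" & d$origin == "somatic")
  }, logical(1))
  list(n_cohort = cohort_size,
       n_actionable = sum(actionable),
       actionable_pct = pct(sum(actionable), cohort_size),
       n_tier2_somatic = sum(tier2s),
       tier2_somatic_pct = pct(sum(tier2s), cohort_size))
}
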