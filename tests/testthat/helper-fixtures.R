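# Shared fixtures, built once per test run and memoised. Training even the
# small ensemble costs a few seconds, so tests that only need predictions
# reuse these.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, expr, envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

tiny_corpus <- function() {
  memo("tiny_corpus",
       generate_expression_corpus(3, 2, 80, 8, noise_sd = 0.3, seed = 5))
}

tiny_ensemble <- function() {
  memo("tiny_ensemble",
       suppressWarnings(train_ensemble(tiny_corpus(), seed = 5)))
}

# The reference corpus for contamination-robustness checks: 5 tissues,
# 3 sites, 200 genes, 40 samples/tissue, log-sd 0.5.
standard_corpus <- function() {
  memo("standard_corpus",
       generate_expression_corpus(5, 3, 200, 40, noise_sd = 0.5, seed = 1))
}

# Split a corpus into train/test by taking the last `n_test` samples of
# each tissue as the held-out set.
split_corpus <- function(corpus, n_test) {
  idx <- split(seq_along(corpus$tissue), corpus$tissue)
  test_idx <- unlist(lapply(idx, function(ix) utils::tail(ix, n_test)))
  list(train = seqdirect:::subset_corpus(corpus, setdiff(unlist(idx), test_idx)),
       test = seqdirect:::subset_corpus(corpus, test_idx))
}

# Contaminate every column of a normalized profile matrix with its own
# site's normal vector at a fixed alpha.
contaminate_by_site <- function(profiles, sites, normal_panel, alpha) {
  norm_log <- normalize_profile(normal_panel)
  out <- profiles
  for (k in seq_len(ncol(profiles))) {
    out[, k] <- contaminate_profile(profiles[, k], norm_log[, sites[k]], alpha)
  }
  out
}

# A random probability vector on the k-simplex.
random_simplex <- function(k) {
  v <- stats::runif(k)
  v / sum(v)
}

# The paper-scale cohort count table used for printed-rate arithmetic.
reference_counts <- function() {
  list(n_cohort = 1015, n_actionable = 817, n_tier2_somatic = 713,
       n_sdt_patients = 132, n_benefit = 49, n_exceptional = 26,
       n_pgv_patients = 160, n_pgv_total = 169, n_pgv_unknown_before = 155,
       n_pgv_penetrant = 115, n_second_hit = 69, n_therapeutic_pgv = 49,
       n_therapeutic_second_hit = 42, n_cup = 55, n_cup_reclassified = 28,
       n_cup_sdt_instances = 13, n_cup_benefit_instances = 7)
}

random_alteration <- function(kb) {
  somatic_classes <- setdiff(seqdirect:::ALT_CLASSES,
                             c("diagnosis_marker", "loh"))
  genes <- c(unique(kb$gene), "NOVEL1", "NOVEL2")
  origin <- sample(c("somatic", "germline"), 1, prob = c(0.8, 0.2))
  list(
    patient_id = "PX",
    gene = sample(genes, 1),
    alt_class = if (origin == "germline") "mutation"
                else sample(somatic_classes, 1),
    origin = origin,
    pathogenicity = sample(c("pathogenic", "likely_pathogenic", "other"), 1),
    cancer_type = sample(c("lung", "breast", "prostate", "CUP", "melanoma"), 1))
}
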