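#' Build a validated pipeline run configuration
#'
#' @param seed master integer seed; every stage derives its own substream
#'   from it, so one seed reproduces the whole run.
#' @param out_dir output directory for reports.
#' @param corpus_params list for [generate_expression_corpus()].
#' @param clinical_params list for [generate_clinical_table()].
#' @param threshold tissue-of-origin confidence threshold.
#' @param alpha_sampler contamination-fraction sampler for training.
#' @param kb_path optional knowledge-base TSV; default the bundled one.
#' @param panel_path optional gene-panel TSV; default the bundled one.
#' @param censor_date censor date for ongoing therapy courses.
#' @return validated `run_config` list.
#' @export
run_config <- function(seed,
                       out_dir = tempfile("seqdirect_run_"),
                       corpus_params = list(n_tissues = 5, n_sites = 3,
                                            n_genes = 200, n_per_tissue = 40,
                                            noise_sd = 0.5),
                       clinical_params = list(n_patients = 200),
                       threshold = 0.6,
                       alpha_sampler = function(n) stats::runif(n, 0, 0.5),
                       kb_path = NULL,
                       panel_path = NULL,
                       censor_date = "2021-04-30") {
  stop_if_not(!missing(seed), "`seed` is mandatory")
  seed <- check_count(seed, "seed", min = 0L)
  for (p in c(kb_path, panel_path)) {
    stop_if_not(file.exists(p), paste("config path does not exist:", p))
  }
  kb <- if (is.null(kb_path)) default_knowledge_base() else
    read_knowledge_base(kb_path)
  panel <- if (is.null(panel_path)) default_gene_panel() else
    read_gene_panel(panel_path)
  structure(list(seed = seed, out_dir = out_dir,
                 corpus_params = corpus_params,
                 clinical_params = clinical_params,
                 threshold = check_fraction(threshold, "threshold"),
                 alpha_sampler = alpha_sampler, kb = kb, panel = panel,
                 censor_date = as.Date(censor_date)),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of [run_config()] can be supplied in a YAML file
#' (`seed`, `out_dir`, `threshold`, `censor_date`, `kb_path`, `panel_path`,
#' and the `corpus_params` / `clinical_params` blocks).
#'
#' @param path YAML file.
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y),
                                  names(formals(run_config)))])
}

#' Run the end-to-end synthetic cohort pipeline
#'
#' Generates a synthetic expression corpus and clinical table, trains the
#' tissue-of-origin ensemble and classifies held-out contaminated profiles,
#' tiers every alteration against the knowledge base, categorises PGVs and
#' calls second hits, classifies therapy courses, and assembles the
#' per-patient report and cohort summary. Deterministic given the config
#' seed; the manifest records the seed and parameters.
#'
#' @param config a `run_config`.
#' @return list with `per_patient` (data frame), `cohort` (named rates and
#'   counts), `too` (tissue-of-origin report), and `files` (paths written:
#'   per-patient TSV, cohort JSON, manifest JSON).
#' @export
run_pipeline <- function(config) {
  stop_if_not(inherits(config, "run_config"), "`config` must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  message("[simulate] generating corpus and clinical table")
  corpus <- do.call(generate_expression_corpus,
                    c(config$corpus_params,
                      list(seed = derive_seed(config$seed, 100L))))
  clin <- do.call(generate_clinical_table,
                  c(config$clinical_params,
                    list(seed = derive_seed(config$seed, 200L))))

  message("[toO] training ensemble and classifying held-out profiles")
  samples <- colnames(corpus$expression)
  test_idx <- unlist(lapply(split(seq_along(samples), corpus$tissue),
                            function(ix) utils::tail(ix, 5)))
  train <- subset_corpus(corpus, setdiff(seq_along(samples), test_idx))
  test <- subset_corpus(corpus, test_idx)
  model <- train_ensemble(train, alpha_sampler = config$alpha_sampler,
                          threshold = config$threshold,
                          seed = derive_seed(config$seed, 300L))
  test_prof <- normalize_profile(test$expression)
  too <- classify_cohort(model, test_prof,
                         prior_diagnosis = rep("CUP", ncol(test_prof)))
  too$cases$true_tissue <- unname(test$tissue)

  message("[tier] assigning actionability tiers")
  tiers <- assign_tiers(clin$alterations, config$kb)
  act <- summarize_actionability(tiers, cohort_size = nrow(clin$patients))

  message("[germline] categorising PGVs and calling second hits")
  pgvs <- detect_second_hits(clin$pgvs, clin$alterations)
  germ <- summarize_pgvs(pgvs, cohort_size = nrow(clin$patients),
                         panel = config$panel)

  message("[outcomes] classifying therapy courses")
  sdt_courses <- clin$courses[clin$courses$sdt, , drop = FALSE]
  outcomes <- if (nrow(sdt_courses)) {
    classify_course(sdt_courses, censor_date = config$censor_date)
  } else sdt_courses

  per_patient <- clin$patients
  per_patient$n_alterations <-
    as.integer(table(factor(tiers$patient_id,
                            levels = per_patient$patient_id)))
  pt_tier <- vapply(split(tiers$tier, factor(tiers$patient_id,
                                             levels = per_patient$patient_id)),
                    function(tt) if (length(tt)) min(tt) else NA_integer_,
                    integer(1))
  per_patient$best_tier <- pt_tier
  per_patient$actionable <- !is.na(pt_tier) & pt_tier <= 2L
  per_patient$has_pgv <- per_patient$patient_id %in% pgvs$patient_id
  per_patient$sdt <- per_patient$patient_id %in% sdt_courses$patient_id
  per_patient$benefit <- per_patient$patient_id %in%
    outcomes$patient_id[outcomes$benefit]

  cohort <- list(
    n_cohort = nrow(per_patient),
    actionable = act,
    germline = germ,
    sdt = list(
      n_sdt_patients = length(unique(sdt_courses$patient_id)),
      benefit_rate_pct = if (nrow(sdt_courses))
        clinical_benefit_rate(outcomes, "patient") else 0,
      exceptional_pct = if (nrow(sdt_courses))
        pct(length(unique(outcomes$patient_id[outcomes$exceptional])),
            length(unique(outcomes$patient_id))) else 0),
    too = list(
      n_cases = nrow(too$cases),
      reclassified_count = too$reclassified_count,
      reclassified_pct = pct(too$reclassified_count, nrow(too$cases)),
      accuracy = mean(too$cases$label == too$cases$true_tissue)))

  f_pat <- file.path(config$out_dir, "per_patient.tsv")
  f_sum <- file.path(config$out_dir, "cohort_summary.json")
  f_man <- file.path(config$out_dir, "manifest.json")
  utils::write.table(per_patient, f_pat, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(cohort, f_sum, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  jsonlite::write_json(list(
    seed = config$seed,
    corpus_params = config$corpus_params,
    clinical_params = config$clinical_params,
    threshold = config$threshold,
    censor_date = as.character(config$censor_date),
    package_version = as.character(utils::packageVersion("seqdirect"))),
    f_man, auto_unbox = TRUE, pretty = TRUE)

  list(per_patient = per_patient, cohort = cohort, too = too,
       tiers = tiers, pgvs = pgvs, outcomes = outcomes,
       files = c(per_patient = f_pat, cohort_summary = f_sum,
                 manifest = f_man))
}
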