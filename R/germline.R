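#' Read a germline gene panel from TSV
#'
#' Columns: `gene`, `category` (HIGH_PENETRANT, MODERATE_PENETRANT,
#' AR_CANCER_RISK, AR_NONCANCER), `therapeutic_target` (logical). Genes in
#' the double-strand-break repair set (BRCA1, BRCA2, ATM, PALB2, BRIP1) or
#' the mismatch-repair set (MLH1, MSH2, PMS2) must be flagged
#' `therapeutic_target` (PARP-inhibitor and immune-checkpoint-inhibitor
#' implications respectively); the reader enforces this.
#'
#' @param path TSV file path.
#' @return validated panel data frame.
#' @export
read_gene_panel <- function(path) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene", "category", "therapeutic_target")
  missing <- setdiff(required, names(panel))
  stop_if_not(length(missing) == 0,
              paste("gene panel lacks column(s):",
                    paste(missing, collapse = ", ")))
  stop_if_not(!anyDuplicated(panel$gene), "gene panel has duplicate genes")
  stop_if_not(all(panel$category %in% GERMLINE_RISKS),
              "gene panel contains unknown categories")
  panel$therapeutic_target <- as.logical(panel$therapeutic_target)
  target_sets <- c(DSB_REPAIR_GENES, MMR_GENES)
  present <- intersect(target_sets, panel$gene)
  ok <- panel$therapeutic_target[match(present, panel$gene)]
  stop_if_not(all(ok),
              "DSB-repair and MMR genes must be flagged therapeutic_target")
  panel
}

#' Double-strand-break repair and mismatch-repair gene sets
#'
#' The germline therapeutic-target gene sets: defects in double-strand DNA
#' repair are candidates for PARP inhibition; mismatch-repair defects for
#' immune checkpoint inhibition.
#' @export
DSB_REPAIR_GENES <- c("BRCA1", "BRCA2", "ATM", "PALB2", "BRIP1")

#' @rdname DSB_REPAIR_GENES
#' @export
MMR_GENES <- c("MLH1", "MSH2", "PMS2")

#' Bundled germline gene panel
#'
#' Seeded from the highly penetrant, moderately penetrant, autosomal
#' recessive cancer-risk and autosomal recessive non-cancer gene groups a
#' clinical panel distinguishes; user-extensible by editing a copy of the
#' TSV and loading it with [read_gene_panel()].
#'
#' @return panel data frame.
#' @export
default_gene_panel <- function() {
  read_gene_panel(system.file("extdata", "gene_panel.tsv",
                              package = "seqdirect", mustWork = TRUE))
}

#' Categorize a pathogenic germline variant by gene
#'
#' @param gene gene symbol.
#' @param panel gene panel data frame (default the bundled panel).
#' @param unknown what to do for genes not on the panel: `"error"` (default)
#'   or `"none"` (return category `"NONE"` with a warning).
#' @return list with `category` and `therapeutic_target`.
#' @export
categorize_pgv <- function(gene, panel = default_gene_panel(),
                           unknown = c("error", "none")) {
  unknown <- match.arg(unknown)
  i <- match(gene, panel$gene)
  if (is.na(i)) {
    if (unknown == "error") {
      stop(sprintf("gene %s is not on the germline panel", gene),
           call. = FALSE)
    }
    warning(sprintf("gene %s is not on the germline panel", gene))
    return(list(category = "NONE", therapeutic_target = FALSE))
  }
  list(category = panel$category[i],
       therapeutic_target = panel$therapeutic_target[i])
}

SECOND_HIT_CLASSES <- c("mutation", "homozygous_deletion", "loh")

#' Detect a somatic second hit for a germline variant
#'
#' Under the two-hit model, a germline variant's remaining allele can be
#' inactivated somatically. The call is TRUE iff the patient's somatic
#' events include at least one event in the same gene of class mutation,
#' homozygous deletion, or loss of heterozygosity. The call is invariant to
#' the order of the somatic events, and events in other genes never affect
#' it.
#'
#' @param pgv list or one-row data frame with `patient_id` and `gene`.
#' @param somatic_events data frame of the patient's somatic alterations
#'   (`patient_id`, `gene`, `alt_class`, `origin`).
#' @return logical.
#' @export
detect_second_hit <- function(pgv, somatic_events) {
  if (is.data.frame(pgv)) pgv <- as.list(pgv[1, ])
  if (nrow(somatic_events) == 0) return(FALSE)
  stop_if_not(all(somatic_events$patient_id == pgv$patient_id),
              "somatic events must all belong to the variant's patient")
  som <- somatic_events[somatic_events$origin == "somatic", , drop = FALSE]
  any(som$gene == pgv$gene & som$alt_class %in% SECOND_HIT_CLASSES)
}

#' Call second hits for a whole PGV table
#'
#' @param pgvs PGV data frame (`patient_id`, `gene`, ...).
#' @param alterations cohort alteration table; only each variant's own
#'   patient's somatic events are consulted.
#' @return `pgvs` with a logical `second_hit` column appended.
#' @export
detect_second_hits <- function(pgvs, alterations) {
  som <- alterations[alterations$origin == "somatic", , drop = FALSE]
  pgvs$second_hit <- vapply(seq_len(nrow(pgvs)), function(i) {
    ev <- som[som$patient_id == pgvs$patient_id[i], , drop = FALSE]
    detect_second_hit(as.list(pgvs[i, ]), ev)
  }, logical(1))
  pgvs
}

#' Summarize a cohort's pathogenic germline variants
#'
#' Emits the germline headline statistics: total PGVs, unique carriers and
#' their percent of cohort, counts per category, penetrant-syndrome share
#' (highly + moderately penetrant), second-hit rate, therapeutic-target
#' count with its own second-hit rate, and the share of PGVs unknown before
#' enrollment. Percentages use round-half-up to one decimal. An empty
#' record set yields an all-zero summary.
#'
#' @param records PGV data frame with `patient_id`, `gene`, and optionally
#'   `second_hit` and `known_before_enrollment`; categories are looked up in
#'   `panel`.
#' @param cohort_size patients sequenced (>= unique carriers).
#' @param panel gene panel for categorisation.
#' @return named list of counts and percentages.
#' @export
summarize_pgvs <- function(records, cohort_size,
                           panel = default_gene_panel()) {
  cohort_size <- check_count(cohort_size, "cohort_size")
  n_total <- nrow(records)
  if (n_total == 0) {
    return(list(n_pgvs = 0L, n_patients = 0L, patient_pct = 0,
                category_counts = stats::setNames(integer(4), GERMLINE_RISKS[1:4]),
                penetrant_pct = 0, second_hit_pct = 0,
                n_therapeutic = 0L, therapeutic_second_hit_pct = 0,
                unknown_before_pct = 0))
  }
  n_patients <- length(unique(records$patient_id))
  stop_if_not(cohort_size >= n_patients,
              "`cohort_size` must be >= unique patients in records")
  cats <- vapply(records$gene, function(g) {
    categorize_pgv(g, panel, unknown = "none")$category
  }, character(1))
  targets <- vapply(records$gene, function(g) {
    categorize_pgv(g, panel, unknown = "none")$therapeutic_target
  }, logical(1))
  category_counts <- vapply(GERMLINE_RISKS[1:4], function(cc) sum(cats == cc),
                            integer(1))
  second_hit <- if ("second_hit" %in% names(records)) records$second_hit
                else rep(NA, n_total)
  known <- if ("known_before_enrollment" %in% names(records)) {
    records$known_before_enrollment
  } else rep(FALSE, n_total)
  list(
    n_pgvs = n_total,
    n_patients = n_patients,
    patient_pct = pct(n_patients, cohort_size),
    category_counts = category_counts,
    penetrant_pct = pct(sum(cats %in% c("HIGH_PENETRANT", "MODERATE_PENETRANT")),
                        n_total),
    second_hit_pct = pct(sum(second_hit, na.rm = TRUE), n_total),
    n_therapeutic = sum(targets),
    therapeutic_second_hit_pct = pct(sum(second_hit & targets, na.rm = TRUE),
                                     sum(targets)),
    unknown_before_pct = pct(sum(!known), n_total))
}
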