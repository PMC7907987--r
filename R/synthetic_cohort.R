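#' Generate a synthetic labeled expression corpus
#'
#' Builds a seeded tissue-labeled gene-by-sample expression matrix with the
#' statistical structure the tissue-of-origin classifier assumes: each tissue
#' class up-regulates a disjoint block of marker genes on top of a shared
#' baseline, log-scale expression is Gaussian around the tissue mean and then
#' exponentiated (log-normal abundances, hence nonnegative and right-skewed),
#' and every biopsy site contributes a normal-tissue expression vector built
#' from dedicated normal draws with the site's own marker block. The normal
#' panel is what the contamination schemes admix into training profiles.
#'
#' @param n_tissues number of tumor tissue classes.
#' @param n_sites number of biopsy sites.
#' @param n_genes number of genes; must accommodate one disjoint marker block
#'   per tissue (and, when room allows, per site).
#' @param n_per_tissue samples per tissue; must be >= `n_sites` so every
#'   tissue is observed at every site.
#' @param noise_sd log-scale Gaussian dispersion of sample expression around
#'   the tissue mean.
#' @param seed integer seed; the corpus is a pure function of the arguments.
#' @param marker_block genes per tissue marker block; defaults to 10,
#'   shrunk to `floor(n_genes / n_tissues)` when the gene space is too
#'   small to hold disjoint size-10 blocks.
#' @param marker_effect additive log-scale up-regulation of marker genes
#'   (default 2.0 log units).
#' @param n_normal_draws normal-tissue replicates averaged (linear scale)
#'   into each site's normal panel vector.
#' @return an object of class `synthetic_corpus`: list with `expression`
#'   (linear-scale gene x sample matrix), `tissue` and `site` (per-sample
#'   labels), `normal_panel` (gene x site matrix, linear scale),
#'   `tissue_specs`, `seed`, and `params`.
#' @export
generate_expression_corpus <- function(n_tissues, n_sites, n_genes,
                                       n_per_tissue, noise_sd, seed,
                                       marker_block = NULL,
                                       marker_effect = 2.0,
                                       n_normal_draws = 25L) {
  n_tissues <- check_count(n_tissues, "n_tissues")
  n_sites <- check_count(n_sites, "n_sites")
  n_genes <- check_count(n_genes, "n_genes")
  n_per_tissue <- check_count(n_per_tissue, "n_per_tissue")
  if (is.null(marker_block)) marker_block <- min(10L, n_genes %/% n_tissues)
  marker_block <- check_count(marker_block, "marker_block")
  stop_if_not(is.numeric(noise_sd) && length(noise_sd) == 1L && noise_sd >= 0,
              "`noise_sd` must be a single nonnegative number")
  stop_if_not(marker_effect > 0, "`marker_effect` must be > 0")
  stop_if_not(n_genes >= n_tissues * marker_block,
              "`n_genes` must be >= n_tissues * marker_block")
  stop_if_not(n_per_tissue >= n_sites,
              "`n_per_tissue` must be >= `n_sites` so each tissue is seen at every site")

  genes <- sprintf("g%04d", seq_len(n_genes))
  tissues <- sprintf("tissue%02d", seq_len(n_tissues))
  sites <- sprintf("site%02d", seq_len(n_sites))

  with_seed(derive_seed(seed, 1L), {
    baseline <- stats::runif(n_genes, 0.5, 3)

    tissue_specs <- lapply(seq_len(n_tissues), function(i) {
      idx <- ((i - 1L) * marker_block + 1L):(i * marker_block)
      list(label = tissues[i], marker_genes = idx,
           baseline_mean = baseline, marker_effect = marker_effect)
    })
    names(tissue_specs) <- tissues

    # Site marker blocks come after the tissue blocks when the gene space has
    # room; otherwise sites differ only through their own baseline shift.
    site_specs <- lapply(seq_len(n_sites), function(j) {
      start <- n_tissues * marker_block + (j - 1L) * marker_block
      idx <- if (start + marker_block <= n_genes) {
        (start + 1L):(start + marker_block)
      } else integer(0)
      list(label = sites[j], marker_genes = idx,
           shift = stats::runif(1, -0.5, 0.5))
    })
    names(site_specs) <- sites

    n_samples <- n_tissues * n_per_tissue
    tissue_lab <- rep(tissues, each = n_per_tissue)
    site_lab <- rep(rep(sites, length.out = n_per_tissue), times = n_tissues)

    expr <- matrix(0, n_genes, n_samples,
                   dimnames = list(genes, sprintf("s%04d", seq_len(n_samples))))
    for (k in seq_len(n_samples)) {
      spec <- tissue_specs[[tissue_lab[k]]]
      mu <- baseline
      mu[spec$marker_genes] <- mu[spec$marker_genes] + marker_effect
      logv <- if (noise_sd > 0) mu + stats::rnorm(n_genes, 0, noise_sd) else mu
      expr[, k] <- exp(logv)
    }

    normal_panel <- matrix(0, n_genes, n_sites,
                           dimnames = list(genes, sites))
    for (j in seq_len(n_sites)) {
      sp <- site_specs[[j]]
      mu <- baseline + sp$shift
      mu[sp$marker_genes] <- mu[sp$marker_genes] + marker_effect
      draws <- vapply(seq_len(n_normal_draws), function(d) {
        logv <- if (noise_sd > 0) mu + stats::rnorm(n_genes, 0, noise_sd) else mu
        exp(logv)
      }, numeric(n_genes))
      normal_panel[, j] <- rowMeans(draws)
    }

    structure(list(
      expression = expr,
      tissue = stats::setNames(tissue_lab, colnames(expr)),
      site = stats::setNames(site_lab, colnames(expr)),
      normal_panel = normal_panel,
      tissue_specs = tissue_specs,
      site_specs = site_specs,
      seed = as.integer(seed),
      params = list(n_tissues = n_tissues, n_sites = n_sites,
                    n_genes = n_genes, n_per_tissue = n_per_tissue,
                    noise_sd = noise_sd, marker_block = marker_block,
                    marker_effect = marker_effect)
    ), class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "synthetic_corpus: %d genes x %d samples, %d tissues, %d sites (seed %d)\n",
    nrow(x$expression), ncol(x$expression),
    length(unique(x$tissue)), length(unique(x$site)), x$seed))
  invisible(x)
}

# Subset a corpus by sample index/names, keeping the normal panel and specs.
subset_corpus <- function(corpus, samples) {
  out <- corpus
  out$expression <- corpus$expression[, samples, drop = FALSE]
  out$tissue <- corpus$tissue[samples]
  out$site <- corpus$site[samples]
  out
}

#' Generate a synthetic clinical table
#'
#' Produces per-patient alteration, pathogenic-germline-variant (PGV) and
#' therapy-course tables with planted ground truth recorded alongside the
#' observable fields, so tiering, second-hit detection and outcome statistics
#' can be validated by planted-truth recovery. Alterations planted as tier 1
#' or 2 use gene/class/context combinations that the bundled knowledge base
#' resolves to that tier; PGV genes come from the bundled gene panel; therapy
#' durations are drawn from a two-component mixture (short exponential
#' non-responders, long uniform responders) so both benefit classes occur.
#'
#' @param n_patients cohort size.
#' @param actionable_fraction expected proportion of patients carrying at
#'   least one tier-1/2 (actionable) alteration.
#' @param pgv_fraction expected proportion of patients carrying a PGV.
#' @param second_hit_fraction expected proportion of PGVs with a somatic
#'   second hit planted in the same gene.
#' @param benefit_duration_dist parameters of the therapy-duration mixture:
#'   list with `p_responder`, `nonresponder_mean` (months, exponential),
#'   `responder_min`, `responder_max` (months, uniform).
#' @param seed integer seed.
#' @param sdt_fraction proportion of actionable patients starting a
#'   sequencing-directed therapy (SDT) course.
#' @return an object of class `synthetic_clinical`: list with `patients`,
#'   `alterations`, `pgvs`, `courses` data frames and `seed`. Planted truths
#'   live in `true_*` columns.
#' @export
generate_clinical_table <- function(n_patients,
                                    actionable_fraction = 0.805,
                                    pgv_fraction = 0.158,
                                    second_hit_fraction = 0.408,
                                    benefit_duration_dist = list(
                                      p_responder = 0.37,
                                      nonresponder_mean = 2.5,
                                      responder_min = 6,
                                      responder_max = 30),
                                    seed = 1L,
                                    sdt_fraction = 0.162) {
  n_patients <- check_count(n_patients, "n_patients")
  actionable_fraction <- check_fraction(actionable_fraction, "actionable_fraction")
  pgv_fraction <- check_fraction(pgv_fraction, "pgv_fraction")
  second_hit_fraction <- check_fraction(second_hit_fraction, "second_hit_fraction")
  sdt_fraction <- check_fraction(sdt_fraction, "sdt_fraction")
  dd <- benefit_duration_dist

  kb <- default_knowledge_base()
  panel <- default_gene_panel()
  cancer_types <- c("prostate", "breast", "sarcoma", "lung", "CUP")

  # gene/class/context templates that the bundled kb resolves to each tier
  tier1_templates <- kb[kb$evidence %in%
                          c("FDA_APPROVED_BENEFIT", "FDA_APPROVED_RESISTANCE") &
                          kb$context != "ANY", , drop = FALSE]
  tier2_templates <- kb[kb$evidence == "INVESTIGATIONAL_OR_OFF_LABEL", , drop = FALSE]
  tier3_templates <- kb[kb$evidence == "BIOLOGICAL_ONLY", , drop = FALSE]

  with_seed(derive_seed(seed, 2L), {
    patients <- sprintf("P%05d", seq_len(n_patients))
    cancer_type <- sample(cancer_types, n_patients, replace = TRUE)
    actionable <- stats::runif(n_patients) < actionable_fraction
    has_pgv <- stats::runif(n_patients) < pgv_fraction

    alt_list <- list()
    # a tier-2 plant must not sit in a context where an FDA-approved entry
    # for the same gene would promote it to tier 1
    fda_blocked <- function(gene) {
      kb$context[kb$gene == gene &
                   kb$evidence %in% c("FDA_APPROVED_BENEFIT",
                                      "FDA_APPROVED_RESISTANCE")]
    }
    plant_alt <- function(pid, ctype, tmpl, true_tier) {
      cls <- strsplit(tmpl$alt_pattern, "|", fixed = TRUE)[[1]][1]
      ctx <- if (tmpl$context == "ANY") ctype else tmpl$context
      if (!is.na(true_tier) && true_tier >= 2L) {
        allowed <- setdiff(cancer_types, fda_blocked(tmpl$gene))
        if (!(ctx %in% allowed)) ctx <- allowed[1]
      }
      data.frame(patient_id = pid, gene = tmpl$gene, alt_class = cls,
                 origin = "somatic", pathogenicity = "other",
                 cancer_type = ctx, true_tier = true_tier,
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_patients)) {
      if (actionable[i]) {
        use_t1 <- stats::runif(1) < 0.5
        tmpl_df <- if (use_t1) tier1_templates else tier2_templates
        tmpl <- tmpl_df[sample.int(nrow(tmpl_df), 1L), ]
        alt_list[[length(alt_list) + 1L]] <-
          plant_alt(patients[i], cancer_type[i], tmpl, if (use_t1) 1L else 2L)
      }
      # every patient also carries a biologically relevant (tier 3) event
      tmpl <- tier3_templates[sample.int(nrow(tier3_templates), 1L), ]
      alt_list[[length(alt_list) + 1L]] <-
        plant_alt(patients[i], cancer_type[i], tmpl, 3L)
    }

    pgv_idx <- which(has_pgv)
    pgvs <- if (length(pgv_idx)) {
      genes <- sample(panel$gene, length(pgv_idx), replace = TRUE)
      hit <- stats::runif(length(pgv_idx)) < second_hit_fraction
      data.frame(
        patient_id = patients[pgv_idx],
        gene = genes,
        pathogenicity = sample(c("pathogenic", "likely_pathogenic"),
                               length(pgv_idx), replace = TRUE),
        known_before_enrollment = stats::runif(length(pgv_idx)) < 0.083,
        true_second_hit = hit,
        stringsAsFactors = FALSE)
    } else {
      data.frame(patient_id = character(0), gene = character(0),
                 pathogenicity = character(0),
                 known_before_enrollment = logical(0),
                 true_second_hit = logical(0))
    }
    # plant the observable somatic second-hit events
    if (any(pgvs$true_second_hit)) {
      hits <- pgvs[pgvs$true_second_hit, ]
      cls <- sample(c("mutation", "homozygous_deletion", "loh"),
                    nrow(hits), replace = TRUE)
      alt_list[[length(alt_list) + 1L]] <- data.frame(
        patient_id = hits$patient_id, gene = hits$gene, alt_class = cls,
        origin = "somatic", pathogenicity = "other",
        cancer_type = cancer_type[match(hits$patient_id, patients)],
        true_tier = NA_integer_, stringsAsFactors = FALSE)
    }
    alterations <- do.call(rbind, alt_list)
    alterations <- alterations[order(alterations$patient_id), , drop = FALSE]
    rownames(alterations) <- NULL

    # therapy courses: actionable patients may start SDT
    sdt <- actionable & (stats::runif(n_patients) < sdt_fraction)
    responder <- stats::runif(n_patients) < dd$p_responder
    months <- ifelse(responder,
                     stats::runif(n_patients, dd$responder_min, dd$responder_max),
                     stats::rexp(n_patients, 1 / dd$nonresponder_mean))
    start <- as.Date("2015-01-01") + sample.int(2000L, n_patients, replace = TRUE)
    stop <- start + round(months * 30.4375)
    courses <- data.frame(
      patient_id = patients,
      therapy = ifelse(sdt, "targeted_agent", "standard_chemo"),
      sdt = sdt,
      setting = sample(c("trial", "off_label", "on_label"), n_patients,
                       replace = TRUE, prob = c(0.56, 0.33, 0.11)),
      start = start,
      stop = stop,
      best_response = ifelse(responder,
                             sample(c("CR", "PR", "SD"), n_patients,
                                    replace = TRUE, prob = c(0.1, 0.5, 0.4)),
                             sample(c("PD", "SD", "NE"), n_patients,
                                    replace = TRUE, prob = c(0.7, 0.2, 0.1))),
      true_duration_months = months,
      stringsAsFactors = FALSE)

    structure(list(
      patients = data.frame(patient_id = patients, cancer_type = cancer_type,
                            true_actionable = actionable,
                            stringsAsFactors = FALSE),
      alterations = alterations,
      pgvs = pgvs,
      courses = courses,
      seed = as.integer(seed)
    ), class = "synthetic_clinical")
  })
}

#' @export
print.synthetic_clinical <- function(x, ...) {
  cat(sprintf(
    "synthetic_clinical: %d patients, %d alterations, %d PGVs, %d courses (seed %d)\n",
    nrow(x$patients), nrow(x$alterations), nrow(x$pgvs), nrow(x$courses),
    x$seed))
  invisible(x)
}

#' Write a synthetic corpus to TSV files with a manifest
#'
#' Writes the expression matrix (rows = genes, columns = samples), the sample
#' labels (sample, tissue, site), the normal panel (gene x site) and a JSON
#' manifest recording seed and generator parameters.
#'
#' @param corpus a `synthetic_corpus`.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_corpus <- function(corpus, dir) {
  stop_if_not(inherits(corpus, "synthetic_corpus"),
              "`corpus` must be a synthetic_corpus")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f_expr <- file.path(dir, "expression.tsv")
  f_lab <- file.path(dir, "labels.tsv")
  f_norm <- file.path(dir, "normal_panel.tsv")
  f_man <- file.path(dir, "manifest.json")
  utils::write.table(data.frame(gene = rownames(corpus$expression),
                                corpus$expression, check.names = FALSE),
                     f_expr, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(corpus$tissue),
                                tissue = unname(corpus$tissue),
                                site = unname(corpus$site)),
                     f_lab, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(corpus$normal_panel),
                                corpus$normal_panel, check.names = FALSE),
                     f_norm, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = corpus$seed, params = corpus$params),
                       f_man, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(f_expr, f_lab, f_norm, f_man))
}

#' Read a corpus written by [write_corpus()]
#'
#' @param dir directory containing expression.tsv, labels.tsv,
#'   normal_panel.tsv and manifest.json.
#' @return a `synthetic_corpus` (without tissue/site specs, which are
#'   generator internals).
#' @export
read_corpus <- function(dir) {
  expr_df <- utils::read.delim(file.path(dir, "expression.tsv"),
                               check.names = FALSE)
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df$gene
  lab <- utils::read.delim(file.path(dir, "labels.tsv"))
  norm_df <- utils::read.delim(file.path(dir, "normal_panel.tsv"),
                               check.names = FALSE)
  normal <- as.matrix(norm_df[, -1, drop = FALSE])
  rownames(normal) <- norm_df$gene
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  structure(list(
    expression = expr,
    tissue = stats::setNames(lab$tissue, lab$sample),
    site = stats::setNames(lab$site, lab$sample),
    normal_panel = normal,
    seed = man$seed,
    params = man$params
  ), class = "synthetic_corpus")
}

#' Write a synthetic clinical table to TSV files with a manifest
#'
#' @param clin a `synthetic_clinical`.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_clinical_table <- function(clin, dir) {
  stop_if_not(inherits(clin, "synthetic_clinical"),
              "`clin` must be a synthetic_clinical")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in c("patients", "alterations", "pgvs", "courses")) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(clin[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  f_man <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = clin$seed, n_patients = nrow(clin$patients)),
                       f_man, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, f_man))
}
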