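#' Normalize raw abundances to a log-scale expression profile
#'
#' Library-size scales each sample to a fixed total, then applies log1p.
#' Works on a single profile (numeric vector) or a gene x sample matrix
#' (columns are samples, each scaled independently). An all-zero sample is
#' returned as all zeros.
#'
#' @param raw_counts nonnegative abundances; vector or gene x sample matrix.
#' @param total library-size target after scaling (default 1e4).
#' @return log-scale profile(s), same shape and dimnames as the input.
#' @export
normalize_profile <- function(raw_counts, total = 1e4) {
  if (any(is.na(raw_counts)) || any(raw_counts < 0)) {
    stop("abundances must be nonnegative and non-missing", call. = FALSE)
  }
  scale1 <- function(v) {
    s <- sum(v)
    if (s == 0) return(v)
    log1p(v * (total / s))
  }
  if (is.matrix(raw_counts)) {
    out <- apply(raw_counts, 2L, scale1)
    dimnames(out) <- dimnames(raw_counts)
    out
  } else {
    scale1(raw_counts)
  }
}

#' Admix normal-tissue signal into a tumor profile
#'
#' Contamination is a physical mixture of transcripts, so mixing is done in
#' linear space: both log-scale profiles are de-logged (expm1), combined as
#' (1 - alpha) * tumor + alpha * normal, and re-logged (log1p). alpha = 0
#' returns the tumor profile exactly; alpha = 1 the normal profile.
#'
#' @param tumor log-scale tumor profile (named numeric vector or gene x
#'   sample matrix).
#' @param normal log-scale normal profile over the same genes.
#' @param alpha mixture fraction of normal signal, in `[0, 1]`.
#' @return contaminated log-scale profile, same shape as `tumor`.
#' @export
contaminate_profile <- function(tumor, normal, alpha) {
  alpha <- check_fraction(alpha, "alpha")
  tg <- if (is.matrix(tumor)) rownames(tumor) else names(tumor)
  ng <- if (is.matrix(normal)) rownames(normal) else names(normal)
  if (!is.null(tg) || !is.null(ng)) {
    stop_if_not(identical(tg, ng),
                "tumor and normal profiles must share the same genes in the same order")
  }
  stop_if_not(NROW(tumor) == NROW(normal),
              "tumor and normal profiles must have the same length")
  if (alpha == 0) return(tumor)
  if (alpha == 1 && identical(dim(tumor), dim(normal))) return(normal)
  mix <- (1 - alpha) * expm1(tumor) + alpha * expm1(normal)
  log1p(mix)
}

#' Contamination schemes for training-set construction
#'
#' The three ways of admixing normal-tissue expression into training
#' examples: `NONE` (unmodified), `BIOPSY_SITE` (each sample mixed with the
#' normal vector of its own biopsy site), and `MEAN_ALL_SITES` (mixed with
#' the unweighted mean, in linear space, of all sites' normal vectors).
#'
#' @export
CONTAMINATION_SCHEMES <- c("NONE", "BIOPSY_SITE", "MEAN_ALL_SITES")

#' Build a (possibly contaminated) labeled training set from a corpus
#'
#' Normalizes the corpus and, under the chosen scheme, admixes a normal
#' profile into each training sample at a fraction drawn from
#' `alpha_sampler`. Tissue labels are preserved.
#'
#' @param corpus a `synthetic_corpus` (or compatible list with `expression`,
#'   `tissue`, `site`, `normal_panel`).
#' @param scheme one of [CONTAMINATION_SCHEMES].
#' @param alpha_sampler function(n) returning n mixture fractions in `[0,1]`;
#'   default uniform on `[0, 0.5]`. Use `function(n) rep(a, n)` for a fixed
#'   alpha.
#' @param seed integer seed for the alpha draws.
#' @return list with `x` (sample x gene log-scale matrix), `y` (factor of
#'   tissue labels), `alphas`, `scheme`, and `gene_ids`.
#' @export
build_training_set <- function(corpus, scheme = c("NONE", "BIOPSY_SITE",
                                                  "MEAN_ALL_SITES"),
                               alpha_sampler = function(n) stats::runif(n, 0, 0.5),
                               seed = 1L) {
  scheme <- match.arg(scheme)
  prof <- normalize_profile(corpus$expression)
  n <- ncol(prof)
  alphas <- rep(0, n)
  if (scheme != "NONE") {
    sites_present <- unique(corpus$site)
    missing <- setdiff(sites_present, colnames(corpus$normal_panel))
    if (length(missing)) {
      stop("normal panel lacks site(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    norm_log <- normalize_profile(corpus$normal_panel)
    alphas <- with_seed(derive_seed(seed, 3L), alpha_sampler(n))
    stop_if_not(all(alphas >= 0 & alphas <= 1),
                "alpha_sampler must return fractions in [0, 1]")
    if (scheme == "BIOPSY_SITE") {
      for (k in seq_len(n)) {
        prof[, k] <- contaminate_profile(prof[, k],
                                         norm_log[, corpus$site[k]],
                                         alphas[k])
      }
    } else {
      # mean model of expression across all sites, mixed identically for
      # every sample; the mean is taken in linear space
      mean_norm <- log1p(rowMeans(expm1(norm_log)))
      for (k in seq_len(n)) {
        prof[, k] <- contaminate_profile(prof[, k], mean_norm, alphas[k])
      }
    }
  }
  list(x = t(prof), y = factor(unname(corpus$tissue)), alphas = alphas,
       scheme = scheme, gene_ids = rownames(corpus$expression))
}
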