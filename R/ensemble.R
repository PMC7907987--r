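#' Train one base tissue classifier
#'
#' Fits one of the two learner families used by the tissue-of-origin
#' ensemble on a labeled (possibly contamination-augmented) training set:
#'
#' * `NU_SUPPORT_VECTOR`: a nu-parameterised support vector machine
#'   (linear kernel) with Platt-scaled class probabilities fitted on
#'   internal cross-validation folds, via \pkg{e1071}.
#' * `MULTINOMIAL_LASSO`: L1-penalised multinomial logistic regression via
#'   \pkg{glmnet}, penalty chosen by internal cross-validation (or fixed via
#'   `hyperparams$lambda`).
#'
#' @param learner `"NU_SUPPORT_VECTOR"` or `"MULTINOMIAL_LASSO"`.
#' @param training list with `x` (sample x gene matrix) and `y` (factor), as
#'   returned by [build_training_set()].
#' @param hyperparams list; recognised entries: `nu` (default 0.25),
#'   `lambda` (fixed lasso penalty; default NULL = cross-validated),
#'   `nfolds` (default 5), `seed` (default 1).
#' @return an object of class `base_model` with `learner`, `scheme`,
#'   `fit`, and `class_labels`.
#' @export
train_base_model <- function(learner = c("NU_SUPPORT_VECTOR",
                                         "MULTINOMIAL_LASSO"),
                             training, hyperparams = list()) {
  learner <- match.arg(learner)
  x <- training$x
  y <- droplevels(as.factor(training$y))
  stop_if_not(nlevels(y) >= 2, "training set must contain >= 2 tissue classes")
  stop_if_not(min(table(y)) >= 2, "every class needs >= 2 training samples")
  hp <- utils::modifyList(list(nu = 0.25, lambda = NULL, nfolds = 5L,
                               seed = 1L), hyperparams)
  # sort by label then sample name so the fit is invariant to input order
  ord <- order(as.integer(y), rownames(x) %||% seq_len(nrow(x)))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]

  fit <- with_seed(derive_seed(hp$seed, 11L), {
    if (learner == "NU_SUPPORT_VECTOR") {
      e1071::svm(x, y, type = "nu-classification", kernel = "linear",
                 nu = hp$nu, probability = TRUE, scale = FALSE)
    } else {
      if (is.null(hp$lambda)) {
        nf <- max(3L, min(hp$nfolds, floor(nrow(x) / 2)))
        cv <- glmnet::cv.glmnet(x, y, family = "multinomial", nfolds = nf)
        glmnet::glmnet(x, y, family = "multinomial", lambda = cv$lambda.min)
      } else {
        glmnet::glmnet(x, y, family = "multinomial", lambda = hp$lambda)
      }
    }
  })
  structure(list(learner = learner, scheme = training$scheme %||% "NONE",
                 fit = fit, class_labels = levels(y),
                 gene_ids = training$gene_ids %||% colnames(x)),
            class = "base_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Class probabilities from one base model
#'
#' @param model a `base_model`.
#' @param x sample x gene matrix of log-scale profiles in training gene
#'   order.
#' @return sample x class probability matrix, columns in `class_labels`
#'   order, each row summing to 1.
#' @export
predict_base <- function(model, x) {
  stop_if_not(inherits(model, "base_model"), "`model` must be a base_model")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (!is.null(colnames(x)) && !identical(colnames(x), model$gene_ids)) {
    stop("profile genes do not match the model's training gene order",
         call. = FALSE)
  }
  if (model$learner == "NU_SUPPORT_VECTOR") {
    pr <- attr(stats::predict(model$fit, x, probability = TRUE),
               "probabilities")
    pr <- pr[, model$class_labels, drop = FALSE]
  } else {
    pr <- stats::predict(model$fit, newx = x, type = "response")[, , 1]
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
    pr <- pr[, model$class_labels, drop = FALSE]
  }
  # guard against tiny numerical drift off the simplex
  pr / rowSums(pr)
}

#' Equal-weight aggregation of member probability vectors
#'
#' The ensemble combines its members by bootstrap-aggregation-style
#' averaging with equal weights: the aggregated probability vector is the
#' element-wise arithmetic mean of the member vectors.
#'
#' @param member_probs member x class matrix: one probability vector per row.
#' @return aggregated probability vector (named by class).
#' @export
aggregate_probabilities <- function(member_probs) {
  stop_if_not(is.matrix(member_probs) && nrow(member_probs) >= 1,
              "`member_probs` must be a member x class matrix")
  colMeans(member_probs)
}

#' Train the 6-member tissue-of-origin ensemble
#'
#' Fits one model per (learner, contamination scheme) pair: {nu-SVM,
#' multinomial lasso} x {NONE, BIOPSY_SITE, MEAN_ALL_SITES} = 6 members,
#' each with equal weight at prediction time.
#'
#' @param corpus a `synthetic_corpus` (or compatible) with >= 2 tissue
#'   classes.
#' @param alpha_sampler contamination-fraction sampler passed to
#'   [build_training_set()]; default uniform on `[0, 0.5]`.
#' @param hyperparams shared learner settings (see [train_base_model()]).
#' @param threshold confidence threshold below which a prediction is
#'   reported as `UNCLASSIFIED` (default 0.6).
#' @param seed integer seed governing contamination draws and learner
#'   internals.
#' @return an object of class `ensemble_model`.
#' @export
train_ensemble <- function(corpus,
                           alpha_sampler = function(n) stats::runif(n, 0, 0.5),
                           hyperparams = list(), threshold = 0.6,
                           seed = 1L) {
  stop_if_not(length(unique(corpus$tissue)) >= 2,
              "corpus must contain >= 2 tissue classes")
  threshold <- check_fraction(threshold, "threshold")
  learners <- c("NU_SUPPORT_VECTOR", "MULTINOMIAL_LASSO")
  members <- list()
  class_labels <- NULL
  for (si in seq_along(CONTAMINATION_SCHEMES)) {
    scheme <- CONTAMINATION_SCHEMES[si]
    training <- build_training_set(corpus, scheme, alpha_sampler,
                                   seed = derive_seed(seed, 20L + si))
    for (li in seq_along(learners)) {
      # the learner seed depends on the learner only, not the scheme, so
      # identical training data (e.g. a degenerate alpha sampler at 0)
      # yields identical member fits across schemes
      hp <- utils::modifyList(hyperparams,
                              list(seed = derive_seed(seed, 30L + li)))
      m <- tryCatch(
        train_base_model(learners[li], training, hp),
        error = function(e) stop(sprintf("member (%s, %s): %s",
                                         learners[li], scheme,
                                         conditionMessage(e)), call. = FALSE))
      if (is.null(class_labels)) class_labels <- m$class_labels
      stop_if_not(identical(class_labels, m$class_labels),
                  "all members must share the same class labels")
      members[[paste(learners[li], scheme, sep = ".")]] <- m
    }
  }
  structure(list(members = members, class_labels = class_labels,
                 confidence_threshold = threshold,
                 gene_ids = rownames(corpus$expression), seed = as.integer(seed)),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf(
    "ensemble_model: %d members, %d tissue classes, confidence threshold %.2f\n",
    length(x$members), length(x$class_labels), x$confidence_threshold))
  invisible(x)
}

#' Predict tissue of origin with the ensemble
#'
#' Aggregated probabilities are the unweighted mean of the members'
#' probability vectors. The reported label is the arg-max class (ties broken
#' by lexicographic class name); when the top mean probability falls below
#' the ensemble's confidence threshold the label is `UNCLASSIFIED`.
#'
#' @param model an `ensemble_model` (optionally with members subset — see
#'   [subset_members()]).
#' @param profiles a single log-scale profile (named numeric vector) or a
#'   gene x sample matrix in training gene order.
#' @return data frame with one row per sample: `label`, `confidence`, and
#'   one `p.<class>` column per tissue class.
#' @export
predict_tissue <- function(model, profiles) {
  stop_if_not(inherits(model, "ensemble_model"),
              "`model` must be an ensemble_model")
  if (is.null(dim(profiles))) {
    profiles <- matrix(profiles, ncol = 1,
                       dimnames = list(names(profiles), "sample1"))
  }
  if (!is.null(rownames(profiles)) &&
      !identical(rownames(profiles), model$gene_ids)) {
    stop("profile genes do not match the ensemble's training gene order",
         call. = FALSE)
  }
  x <- t(profiles)
  member_probs <- lapply(model$members, predict_base, x = x)
  k <- length(model$class_labels)
  n <- nrow(x)
  agg <- matrix(0, n, k, dimnames = list(colnames(profiles),
                                         model$class_labels))
  for (i in seq_len(n)) {
    mp <- do.call(rbind, lapply(member_probs, function(p) p[i, ]))
    agg[i, ] <- aggregate_probabilities(mp)
  }
  # arg-max with lexicographic tie-break: classes are scanned in sorted
  # label order and the first maximum wins
  ord <- order(model$class_labels)
  labels <- apply(agg, 1L, function(p) {
    po <- p[ord]
    names(po)[which.max(po)]
  })
  conf <- apply(agg, 1L, max)
  labels[conf < model$confidence_threshold] <- "UNCLASSIFIED"
  out <- data.frame(sample = colnames(profiles), label = unname(labels),
                    confidence = unname(conf), stringsAsFactors = FALSE)
  colnames(agg) <- paste0("p.", colnames(agg))
  rownames(agg) <- NULL
  cbind(out, as.data.frame(agg))
}

#' Subset the members of an ensemble
#'
#' Returns an ensemble containing only the named members (e.g. the two
#' NONE-scheme models, for comparing against contamination-augmented
#' training). Aggregation still averages with equal weights over the
#' retained members.
#'
#' @param model an `ensemble_model`.
#' @param names member names to keep (`"<LEARNER>.<SCHEME>"`), or a scheme
#'   name to keep both learners of that scheme.
#' @return an `ensemble_model` with the chosen members.
#' @export
subset_members <- function(model, names) {
  if (length(names) == 1L && names %in% CONTAMINATION_SCHEMES) {
    names <- grep(paste0("\\.", names, "$"), base::names(model$members),
                  value = TRUE)
  }
  missing <- setdiff(names, base::names(model$members))
  stop_if_not(length(missing) == 0,
              paste("unknown member(s):", paste(missing, collapse = ", ")))
  out <- model
  out$members <- model$members[names]
  out
}

#' Classify a cohort and report reclassifications
#'
#' Runs the ensemble over a set of cases carrying a prior diagnosis and
#' flags each case as reclassified when the prediction is definitive (not
#' `UNCLASSIFIED`) and either the prior diagnosis is `"CUP"` or differs from
#' the predicted label.
#'
#' @param model an `ensemble_model`.
#' @param profiles gene x sample log-scale matrix.
#' @param prior_diagnosis character vector, one per sample; `"CUP"` marks
#'   carcinoma of unknown primary.
#' @return list with `cases` (per-case data frame including `reclassified`)
#'   and `reclassified_fraction`.
#' @export
classify_cohort <- function(model, profiles, prior_diagnosis) {
  stop_if_not(NCOL(profiles) >= 1, "case set must be non-empty")
  stop_if_not(length(prior_diagnosis) == NCOL(profiles),
              "one prior diagnosis per case is required")
  pred <- predict_tissue(model, profiles)
  pred$prior_diagnosis <- prior_diagnosis
  pred$reclassified <- pred$label != "UNCLASSIFIED" &
    (prior_diagnosis == "CUP" | prior_diagnosis != pred$label)
  list(cases = pred,
       reclassified_count = sum(pred$reclassified),
       reclassified_fraction = mean(pred$reclassified))
}
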