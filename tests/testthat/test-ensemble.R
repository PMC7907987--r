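test_that("both learners separate a linearly separable toy problem", {
  x <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 4, 0.1), 10))
  colnames(x) <- c("gA", "gB")
  rownames(x) <- sprintf("s%02d", 1:20)
  training <- list(x = x, y = factor(rep(c("a", "b"), each = 10)),
                   gene_ids = colnames(x))
  for (learner in c("NU_SUPPORT_VECTOR", "MULTINOMIAL_LASSO")) {
    m <- suppressWarnings(train_base_model(learner, training))
    pr <- predict_base(m, x)
    expect_equal(unname(rowSums(pr)), rep(1, 20), tolerance = 1e-9)
    acc <- mean(m$class_labels[max.col(pr)] == training$y)
    expect_equal(acc, 1.0)
  }
})

test_that("base model training is invariant to sample order", {
  set.seed(31)
  x <- rbind(matrix(rnorm(60, 0, 0.5), 10), matrix(rnorm(60, 2, 0.5), 10))
  colnames(x) <- sprintf("g%d", 1:6)
  rownames(x) <- sprintf("s%02d", 1:20)
  y <- factor(rep(c("a", "b"), each = 10))
  perm <- sample(20)
  for (learner in c("NU_SUPPORT_VECTOR", "MULTINOMIAL_LASSO")) {
    m1 <- suppressWarnings(train_base_model(
      learner, list(x = x, y = y, gene_ids = colnames(x))))
    m2 <- suppressWarnings(train_base_model(
      learner, list(x = x[perm, ], y = y[perm], gene_ids = colnames(x))))
    expect_equal(predict_base(m1, x), predict_base(m2, x), tolerance = 1e-6)
  }
})

test_that("single-class training input is rejected", {
  x <- matrix(rnorm(20), 10)
  colnames(x) <- c("gA", "gB")
  training <- list(x = x, y = factor(rep("a", 10)))
  expect_error(train_base_model("NU_SUPPORT_VECTOR", training), "2 tissue classes")
  expect_error(suppressWarnings(train_ensemble(
    generate_expression_corpus(1, 1, 20, 4, 0.1, seed = 1))), "2 tissue classes")
})

test_that("the ensemble has exactly the 6 learner-by-scheme members", {
  m <- tiny_ensemble()
  expect_length(m$members, 6L)
  got <- sort(names(m$members))
  want <- sort(as.vector(outer(c("NU_SUPPORT_VECTOR", "MULTINOMIAL_LASSO"),
                               CONTAMINATION_SCHEMES, paste, sep = ".")))
  expect_equal(got, want)
  schemes <- vapply(m$members, `[[`, character(1), "scheme")
  learners <- vapply(m$members, `[[`, character(1), "learner")
  expect_false(any(duplicated(paste(schemes, learners))))
  for (mem in m$members) expect_equal(mem$class_labels, m$class_labels)
})

test_that("ensemble training is deterministic given the seed", {
  co <- generate_expression_corpus(2, 2, 40, 6, 0.3, seed = 13)
  m1 <- suppressWarnings(train_ensemble(co, seed = 99))
  m2 <- suppressWarnings(train_ensemble(co, seed = 99))
  probe <- normalize_profile(co$expression[, 1])
  expect_identical(predict_tissue(m1, probe), predict_tissue(m2, probe))
})

test_that("aggregation is the arithmetic mean and unanimous members give confidence 1", {
  m <- tiny_ensemble()
  k <- length(m$class_labels)
  unanimous <- matrix(rep(c(1, rep(0, k - 1)), 6), nrow = 6, byrow = TRUE,
                      dimnames = list(NULL, m$class_labels))
  agg <- aggregate_probabilities(unanimous)
  expect_equal(unname(agg[1]), 1)
  expect_equal(sum(agg), 1)
})

test_that("a symmetric 3-vs-3 member split ties and breaks lexicographically", {
  p1 <- c(a = 0.9, b = 0.1)
  p2 <- c(a = 0.1, b = 0.9)
  probs <- rbind(p1, p1, p1, p2, p2, p2)
  agg <- aggregate_probabilities(probs)
  expect_equal(unname(agg["a"]), unname(agg["b"]))
  # lexicographic tie-break: first class name in sorted order wins
  ord <- order(names(agg))
  expect_equal(names(agg[ord])[which.max(agg[ord])], "a")
})

test_that("ensemble predictions stay on the probability simplex", {
  m <- tiny_ensemble()
  co <- tiny_corpus()
  pred <- predict_tissue(m, normalize_profile(co$expression))
  p <- as.matrix(pred[, grep("^p\\.", names(pred))])
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
  expect_equal(pred$confidence, apply(p, 1, max))
  # label is UNCLASSIFIED exactly when confidence < threshold
  expect_equal(pred$label == "UNCLASSIFIED",
               pred$confidence < m$confidence_threshold)
})

test_that("gene-space mismatches are hard errors", {
  m <- tiny_ensemble()
  co <- tiny_corpus()
  prof <- normalize_profile(co$expression[, 1])
  shuffled <- prof[rev(seq_along(prof))]
  expect_error(predict_tissue(m, shuffled), "gene order")
  expect_error(predict_tissue(m, prof[-1]), "gene order")
})

test_that("degenerate alpha samplers make every scheme reproduce the NONE models", {
  co <- tiny_corpus()
  m0 <- suppressWarnings(train_ensemble(
    co, alpha_sampler = function(n) rep(0, n), seed = 5))
  prof <- normalize_profile(co$expression)
  base <- predict_tissue(subset_members(m0, "NONE"), prof)
  for (scheme in c("BIOPSY_SITE", "MEAN_ALL_SITES")) {
    alt <- predict_tissue(subset_members(m0, scheme), prof)
    expect_equal(alt, base, tolerance = 1e-6)
  }
})

test_that("cohort classification counts reclassified CUP cases correctly", {
  m <- tiny_ensemble()
  co <- tiny_corpus()
  prof <- normalize_profile(co$expression[, 1:6])
  pred <- predict_tissue(m, prof)
  # prior diagnosis equal to the prediction is never 'reclassified'
  rep1 <- classify_cohort(m, prof, prior_diagnosis = pred$label)
  expect_equal(rep1$reclassified_count, 0L)
  # CUP priors count whenever the prediction is definitive
  rep2 <- classify_cohort(m, prof, prior_diagnosis = rep("CUP", 6))
  expect_equal(rep2$reclassified_count,
               sum(pred$label != "UNCLASSIFIED"))
  expect_error(classify_cohort(m, prof[, 0], character(0)), "non-empty")
})

test_that("resolvable CUP profiles are reclassified and ambiguous ones are not", {
  m <- tiny_ensemble()
  co <- tiny_corpus()
  prof <- normalize_profile(co$expression)
  # ambiguous profile: equal linear-space mixture of all tissue centroids
  centroids <- vapply(split(as.data.frame(t(expm1(prof))), co$tissue),
                      colMeans, numeric(nrow(prof)))
  ambiguous <- log1p(rowMeans(centroids))
  n_clear <- 8L
  n_amb <- 5L
  cases <- cbind(prof[, seq_len(n_clear)],
                 matrix(ambiguous, nrow(prof), n_amb,
                        dimnames = list(rownames(prof),
                                        sprintf("amb%d", seq_len(n_amb)))))
  rep <- classify_cohort(m, cases, prior_diagnosis = rep("CUP", n_clear + n_amb))
  expect_equal(rep$reclassified_count, n_clear)
  expect_true(all(rep$cases$label[(n_clear + 1):(n_clear + n_amb)] ==
                    "UNCLASSIFIED"))
})
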