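make_signal_data <- function(n = 40, p = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- 2 * x[, 1] - 1.5 * x[, 2] + rnorm(n, 0, 0.3)
  list(x = x, y = y)
}

test_that("the learning curve covers every candidate subset size", {
  d <- make_signal_data(n = 30, p = 5)
  r <- rfe_cv(d$x, d$y, folds = 5, seed = 1, num_trees = 100)
  expect_equal(r$learning_curve$n_features, 1:5)
  expect_equal(nrow(r$ranking), 5)
  expect_setequal(r$ranking$feature, colnames(d$x))
  expect_length(r$optimal_set, r$optimal_n)
  expect_true(all(r$optimal_set %in% colnames(d$x)))
})

test_that("an informative column beats pure noise almost surely", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(s)
    n <- 30
    y <- rnorm(n)
    x <- cbind(signal = y, noise = rnorm(n))
    r <- rfe_cv(x, y, folds = 5, seed = s, num_trees = 100)
    if ("signal" %in% r$optimal_set) hits <- hits + 1L
  }
  expect_gte(hits, 49L)
})

test_that("the full-set curve point equals plain CV of the estimator", {
  d <- make_signal_data(n = 30, p = 4, seed = 2)
  r <- rfe_cv(d$x, d$y, folds = 5, seed = 7, num_trees = 100)
  # recompute 5-fold CV R2 directly with ranger under the same fold/seed scheme
  folds <- make_folds(30, 5, seed = 7)
  scores <- vapply(seq_along(folds), function(f) {
    test <- folds[[f]]
    xtr <- scale(d$x[-test, ])
    xte <- scale(d$x[test, ], center = attr(xtr, "scaled:center"),
                 scale = attr(xtr, "scaled:scale"))
    fit <- ranger::ranger(x = xtr, y = d$y[-test], num.trees = 100,
                          seed = 7 + 4 * 100 + f, num.threads = 1)
    pred <- predict(fit, data = xte, num.threads = 1)$predictions
    1 - sum((d$y[test] - pred)^2) / sum((d$y[test] - mean(d$y[test]))^2)
  }, numeric(1))
  expect_equal(r$learning_curve$mean_score[4], mean(scores))
})

test_that("optimal-size selection follows argmax with smallest-n ties", {
  inc <- data.frame(n_features = 1:6, mean_score = seq(0.1, 0.6, 0.1),
                    sd_score = 0.01)
  expect_equal(choose_optimal_n(inc), 6)
  tie <- data.frame(n_features = 1:10,
                    mean_score = c(0.1, 0.2, 0.3, 0.4, 0.9, 0.5, 0.5, 0.6, 0.9, 0.7),
                    sd_score = 0.02)
  expect_equal(choose_optimal_n(tie), 5)
  uni <- data.frame(n_features = 1:20,
                    mean_score = -abs(1:20 - 13), sd_score = 0.1)
  expect_equal(choose_optimal_n(uni), which.max(-abs(1:20 - 13)))
  # one-standard-error rule reaches back to the smallest adequate size
  se <- data.frame(n_features = 1:5,
                   mean_score = c(0.70, 0.78, 0.80, 0.805, 0.81),
                   sd_score = c(0.05, 0.05, 0.05, 0.05, 0.05))
  expect_equal(choose_optimal_n(se, rule = "onese"), 2)
  expect_error(choose_optimal_n(se[0, ]), "empty")
})

test_that("RFE is bit-stable under a fixed seed", {
  d <- make_signal_data(n = 25, p = 5, seed = 3)
  a <- rfe_cv(d$x, d$y, seed = 11, num_trees = 100)
  b <- rfe_cv(d$x, d$y, seed = 11, num_trees = 100)
  expect_identical(a$learning_curve, b$learning_curve)
  expect_identical(a$ranking, b$ranking)
})

test_that("a perfectly collinear duplicate barely moves the best CV score", {
  d <- make_signal_data(n = 40, p = 4, seed = 5)
  r1 <- rfe_cv(d$x, d$y, seed = 2, num_trees = 200)
  xdup <- cbind(d$x, f1_copy = d$x[, 1])
  r2 <- rfe_cv(xdup, d$y, seed = 2, num_trees = 200)
  expect_lt(abs(max(r1$learning_curve$mean_score) -
                  max(r2$learning_curve$mean_score)), 0.15)
})

test_that("degenerate RFE inputs are rejected", {
  d <- make_signal_data(n = 10, p = 3)
  expect_error(rfe_cv(d$x[1:3, ], d$y[1:3], folds = 5), "fewer rows")
  expect_error(rfe_cv(d$x, rep(1, 10)), "constant")
  expect_error(rfe_cv(d$x[, 1, drop = FALSE], d$y), "2 feature")
})

test_that("RFE output files are written and reloadable", {
  d <- make_signal_data(n = 25, p = 4)
  r <- rfe_cv(d$x, d$y, seed = 1, num_trees = 100)
  dir <- withr::local_tempdir()
  paths <- write_rfe_results(r, dir, prefix = "cell")
  expect_true(all(file.exists(paths)))
  sel <- jsonlite::read_json(paths[["selected"]], simplifyVector = TRUE)
  expect_equal(sel$optimal_n, r$optimal_n)
})
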