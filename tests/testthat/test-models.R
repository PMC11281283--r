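lin_data <- function(n = 40, p = 4, seed = 1, noise = 0) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  beta <- seq_len(p)
  y <- 40 + as.vector(x %*% beta) + rnorm(n, 0, noise)
  list(x = x, y = y)
}

test_that("the 8:2 split gives 58/14 on 72 plots and is a seeded partition", {
  s <- split_dataset(72, seed = 1)
  expect_length(s$train, 58)
  expect_length(s$test, 14)
  expect_setequal(c(s$train, s$test), 1:72)
  expect_length(intersect(s$train, s$test), 0)
  expect_identical(split_dataset(72, seed = 9), split_dataset(72, seed = 9))
  expect_false(identical(split_dataset(72, seed = 1), split_dataset(72, seed = 2)))
  expect_error(split_dataset(3), "too few")
  expect_error(split_dataset(72, train_fraction = 1), "in \\(0, 1\\)")
})

test_that("ridge on exactly linear data matches the closed-form solution", {
  d <- lin_data(n = 50, p = 3)
  m <- train_model(d$x, d$y, "ridge", folds = 5, seed = 1)
  pred <- predict(m, d$x)
  expect_gte(1 - sum((d$y - pred)^2) / sum((d$y - mean(d$y))^2), 0.999)
  # normal-equations oracle under glmnet's objective at the chosen penalty
  # (glmnet standardizes the response internally, so the effective ridge
  # penalty is lambda / sd_pop(y)):
  # beta = (Z'Z/n + lambda/sd_pop(y) I)^-1 Z'yc/n on standardized data
  lam <- m$best_params$lambda
  z <- scale(d$x, center = m$standardization$center,
             scale = m$standardization$scale)
  yc <- d$y - mean(d$y)
  lam_eff <- lam / sqrt(mean(yc^2))
  beta <- solve(crossprod(z) / nrow(z) + diag(lam_eff, ncol(z)),
                crossprod(z, yc) / nrow(z))
  oracle <- mean(d$y) + as.vector(z %*% beta)
  expect_lt(max(abs(pred - oracle)), 1e-6)
})

test_that("a constant target gives constant random-forest predictions", {
  d <- lin_data(n = 20, p = 3)
  m <- train_model(d$x, rep(42, 20), "rf",
                   grid = list(num_trees = 100, max_depth = 0), seed = 1)
  expect_true(all(predict(m, d$x) == 42))
})

test_that("chosen hyperparameters are always members of the supplied grid", {
  d <- lin_data(n = 30, p = 3, noise = 1)
  grids <- list(
    ridge = list(lambda = c(0.01, 1)),
    rf = list(num_trees = c(100, 200), max_depth = c(0, 5)),
    svr = list(cost = c(1, 10), gamma_mult = 1, epsilon = c(0.1, 0.5)),
    bpnn = list(size = c(4, 8), decay = 0.01)
  )
  for (fam in names(grids)) {
    m <- train_model(d$x, d$y, fam, grid = grids[[fam]], seed = 2)
    for (nm in names(grids[[fam]])) {
      expect_true(m$best_params[[nm]] %in% grids[[fam]][[nm]])
    }
  }
})

test_that("all four families are deterministic under a fixed seed", {
  d <- lin_data(n = 30, p = 3, noise = 1)
  grids <- list(
    ridge = NULL,
    rf = list(num_trees = 100, max_depth = 0),
    svr = list(cost = 1, gamma_mult = 1, epsilon = 0.1),
    bpnn = list(size = 6, decay = 0.01)
  )
  for (fam in names(grids)) {
    m1 <- train_model(d$x, d$y, fam, grid = grids[[fam]], seed = 5)
    m2 <- train_model(d$x, d$y, fam, grid = grids[[fam]], seed = 5)
    expect_identical(predict(m1, d$x), predict(m2, d$x))
  }
})

test_that("prediction is row-independent and validates columns", {
  d <- lin_data(n = 30, p = 3, noise = 0.5)
  m <- train_model(d$x, d$y, "svr",
                   grid = list(cost = 1, gamma_mult = 1, epsilon = 0.1),
                   seed = 1)
  pred <- predict(m, d$x)
  perm <- sample(30)
  expect_equal(predict(m, d$x[perm, ]), pred[perm])
  expect_length(predict(m, d$x[1, , drop = FALSE]), 1)
  bad <- d$x; colnames(bad) <- c("a", "b", "c")
  expect_error(predict(m, bad), "columns")
  # extra columns are tolerated as long as the training ones are present
  wide <- cbind(d$x[, 3, drop = FALSE], d$x[, 1:2], junk = 1)
  expect_equal(predict(m, wide), pred)
})

test_that("training never touches held-out rows (leakage canary)", {
  d <- lin_data(n = 40, p = 3, noise = 1)
  tr <- 1:30; te <- 31:40
  m1 <- train_model(d$x[tr, ], d$y[tr], "ridge", seed = 3)
  y_corrupt <- d$y; y_corrupt[te] <- -999
  m2 <- train_model(d$x[tr, ], y_corrupt[tr], "ridge", seed = 3)
  expect_identical(predict(m1, d$x[te, ]), predict(m2, d$x[te, ]))
  expect_identical(m1$best_params, m2$best_params)
})

test_that("invalid training inputs are rejected", {
  d <- lin_data(n = 20, p = 2)
  xb <- d$x; xb[1, 1] <- NA
  expect_error(train_model(xb, d$y, "ridge"), "finite")
  expect_error(train_model(d$x, rep(5, 20), "svr"), "constant")
  expect_error(train_model(d$x, d$y, "ridge", grid = list(lambda = numeric(0))),
               "empty grid")
})
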