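#' Split plots into training and testing sets (8:2)
#'
#' Seeded shuffle; the test size is `round-half-up((1 - train_fraction) * n)`
#' so 72 plots give 58 training and 14 testing plots.
#'
#' @param n_plots Number of rows.
#' @param train_fraction Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return List with sorted integer vectors `train` and `test`.
#' @export
split_dataset <- function(n_plots, train_fraction = 0.8, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  n_test <- floor((1 - train_fraction) * n_plots + 0.5)
  # the training side must at least support the downstream 5-fold CV
  if (n_test < 1 || n_plots - n_test < 5) {
    stop("too few plots to split", call. = FALSE)
  }
  perm <- with_local_seed(seed, sample.int(n_plots))
  list(train = sort(perm[seq_len(n_plots - n_test)]),
       test = sort(perm[(n_plots - n_test + 1):n_plots]))
}

#' Default hyperparameter grid for a model family
#'
#' Ridge: penalty `lambda` on a log ladder 1e-3..1e3. Random forest:
#' `num_trees` 100/300/500 by `max_depth` 0 (unlimited)/5/10. SVR (radial):
#' `cost` 0.1..100, `gamma_mult` scaling the 1/p kernel-width heuristic by
#' 0.1/1/10, tube `epsilon` 0.01/0.1/0.5. BPNN: one hidden layer of
#' `size` 8/16/32 logistic units with weight `decay` 1e-3/1e-2/1e-1
#' (linear output, 2000 iteration cap).
#'
#' @param family `"ridge"`, `"rf"`, `"svr"` or `"bpnn"`.
#' @return Named list of candidate values, crossed exhaustively by
#'   [train_model()].
#' @export
default_grid <- function(family = c("ridge", "rf", "svr", "bpnn")) {
  switch(match.arg(family),
    ridge = list(lambda = 10^seq(-3, 3)),
    rf = list(num_trees = c(100, 300, 500), max_depth = c(0, 5, 10)),
    svr = list(cost = c(0.1, 1, 10, 100), gamma_mult = c(0.1, 1, 10),
               epsilon = c(0.01, 0.1, 0.5)),
    bpnn = list(size = c(8, 16, 32), decay = c(1e-3, 1e-2, 1e-1))
  )
}

# gamma heuristic: 1 / (p * mean feature variance), on standardized data ~ 1/p
gamma_scale <- function(x) {
  v <- mean(apply(x, 2L, var))
  if (!is.finite(v) || v == 0) v <- 1
  1 / (ncol(x) * v)
}

fit_family <- function(family, x, y, params, seed) {
  switch(family,
    ridge = {
      xm <- if (ncol(x) == 1L) cbind(x, `.dummy` = 0) else x
      glmnet::glmnet(xm, y, alpha = 0, lambda = sort(10^seq(-3, 3),
                                                     decreasing = TRUE),
                     standardize = FALSE, thresh = 1e-9)
    },
    rf = ranger::ranger(
      x = x, y = y, num.trees = params$num_trees,
      max.depth = params$max_depth, seed = seed, num.threads = 1L
    ),
    svr = e1071::svm(
      x = x, y = y, type = "eps-regression", kernel = "radial",
      cost = params$cost, gamma = params$gamma_mult * gamma_scale(x),
      epsilon = params$epsilon, scale = FALSE
    ),
    bpnn = with_local_seed(seed, nnet::nnet(
      x = x, y = y, size = params$size, decay = params$decay,
      linout = TRUE, maxit = 2000, trace = FALSE, MaxNWts = 10000
    ))
  )
}

predict_family <- function(family, fit, x, params) {
  switch(family,
    ridge = {
      xm <- if (ncol(x) == 1L) cbind(x, `.dummy` = 0) else x
      as.vector(predict(fit, newx = xm, s = params$lambda, exact = FALSE))
    },
    rf = predict(fit, data = x, num.threads = 1L)$predictions,
    svr = as.vector(predict(fit, newdata = x)),
    bpnn = as.vector(predict(fit, x))
  )
}

#' Train a SPAD regression model with grid-searched hyperparameters
#'
#' Performs an exhaustive grid search scored by mean `folds`-fold
#' cross-validated R2 on the training data, then refits the best combination
#' on the full training set. Features are z-scored for ridge, SVR and BPNN
#' (statistics fitted on training folds only during CV, and on the full
#' training set for the final fit); the random forest consumes raw features.
#'
#' @param x Training feature matrix or data.frame (finite values).
#' @param y Training target (measured SPAD), non-constant for families that
#'   require variance.
#' @param family `"ridge"`, `"rf"`, `"svr"` or `"bpnn"`.
#' @param grid Named list of candidate values; see [default_grid()].
#' @param folds CV folds for the grid search.
#' @param seed Integer seed (folds, forest and network initialization).
#' @return Object of class `spad_model` with the chosen hyperparameters
#'   (always members of the grid), CV results and the fitted predictor.
#' @export
train_model <- function(x, y, family = c("ridge", "rf", "svr", "bpnn"),
                        grid = NULL, folds = 5, seed = 1) {
  family <- match.arg(family)
  x <- as.matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("features and target must be finite", call. = FALSE)
  }
  if (nrow(x) < folds) stop("fewer rows than folds", call. = FALSE)
  if (family != "rf" && sd(y) == 0) {
    stop("constant target for family ", family, call. = FALSE)
  }
  grid <- grid %||% default_grid(family)
  if (!length(grid) || !all(lengths(grid) > 0)) stop("empty grid", call. = FALSE)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  fold_idx <- make_folds(nrow(x), folds, seed)
  use_scaling <- family != "rf"

  cv_scores <- vapply(seq_len(nrow(combos)), function(ci) {
    params <- as.list(combos[ci, , drop = FALSE])
    mean(vapply(seq_along(fold_idx), function(f) {
      test <- fold_idx[[f]]
      xtr <- x[-test, , drop = FALSE]
      xte <- x[test, , drop = FALSE]
      if (use_scaling) {
        st <- standardize_fit(xtr)
        xtr <- standardize_apply(xtr, st)
        xte <- standardize_apply(xte, st)
      }
      fit <- fit_family(family, xtr, y[-test], params, seed = seed + ci * 37L + f)
      r2_score(y[test], predict_family(family, fit, xte, params))
    }, numeric(1)))
  }, numeric(1))

  # a constant target makes fold R2 undefined (NaN); fall back to the first
  # grid point, which is exact anyway for families that tolerate it
  best <- if (any(is.finite(cv_scores))) which.max(cv_scores) else 1L
  best_params <- as.list(combos[best, , drop = FALSE])
  st <- if (use_scaling) standardize_fit(x) else NULL
  xfit <- if (use_scaling) standardize_apply(x, st) else x
  fit <- fit_family(family, xfit, y, best_params, seed = seed)

  structure(
    list(
      family = family,
      best_params = best_params,
      cv_results = cbind(combos, cv_r2 = cv_scores),
      standardization = st,
      fit = fit,
      feature_names = colnames(x),
      seed = seed
    ),
    class = "spad_model"
  )
}

#' Predict SPAD values from a trained model
#'
#' @param object A `spad_model` from [train_model()].
#' @param newdata Matrix or data.frame whose columns match the training
#'   features.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per row.
#' @export
predict.spad_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) ||
      !identical(colnames(newdata), object$feature_names)) {
    if (!is.null(colnames(newdata)) &&
        all(object$feature_names %in% colnames(newdata))) {
      newdata <- newdata[, object$feature_names, drop = FALSE]
    } else {
      stop("newdata columns do not match the training features", call. = FALSE)
    }
  }
  if (!is.null(object$standardization)) {
    newdata <- standardize_apply(newdata, object$standardization)
  }
  predict_family(object$family, object$fit, newdata, object$best_params)
}

#' @export
print.spad_model <- function(x, ...) {
  cat(sprintf("spad_model (%s): %d features, best CV R2 = %.4f\n",
              x$family, length(x$feature_names), max(x$cv_results$cv_r2)))
  cat("chosen:", paste(names(x$best_params), unlist(x$best_params),
                       sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
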