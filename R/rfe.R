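#' Deterministic cross-validation folds
#'
#' Shuffles `1:n` with the seed and deals the indices into `k` near-equal
#' folds.
#'
#' @param n Number of rows.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` integer vectors (held-out indices per fold).
#' @export
make_folds <- function(n, k = 5, seed = 1) {
  if (n < k) stop("fewer rows than folds", call. = FALSE)
  perm <- with_local_seed(seed, sample.int(n))
  split(perm, rep_len(seq_len(k), n))
}

# z-score columns by training statistics; zero-variance columns pass through
standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(x, st) {
  scale(x, center = st$center, scale = st$scale)
}

# conventional R2 of predictions on held-out data
r2_score <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  1 - sum((y - yhat)^2) / sst
}

# mean/SD of per-fold CV R2 for a random-forest regressor on x[, cols]
rf_cv_score <- function(x, y, cols, folds, seed, num_trees = 500) {
  scores <- vapply(seq_along(folds), function(f) {
    test <- folds[[f]]
    st <- standardize_fit(x[-test, cols, drop = FALSE])
    xtr <- standardize_apply(x[-test, cols, drop = FALSE], st)
    xte <- standardize_apply(x[test, cols, drop = FALSE], st)
    fit <- ranger::ranger(
      x = xtr, y = y[-test], num.trees = num_trees,
      seed = seed + f, num.threads = 1L
    )
    r2_score(y[test], predict(fit, data = xte, num.threads = 1L)$predictions)
  }, numeric(1))
  c(mean = mean(scores), sd = sd(scores))
}

#' Cross-validated recursive feature elimination with a random-forest
#' estimator
#'
#' Starting from all columns, features are removed one per step: the current
#' subset is scored by `folds`-fold cross-validated R2 of a random-forest
#' regressor, then a forest fitted on all rows of the current subset ranks
#' the features by impurity importance and the least important one is
#' dropped (ties toward the first column). The learning curve holds one entry
#' per subset size from `ncol(x)` down to 1; the optimal size is chosen by
#' [choose_optimal_n()].
#'
#' @param x Numeric feature matrix (or data.frame) with unique column names.
#' @param y Numeric target (measured SPAD), non-constant.
#' @param folds Number of CV folds.
#' @param seed Integer seed; the result is fully reproducible from it.
#' @param num_trees Forest size for both scoring and importance.
#' @param rule Optimal-size rule passed to [choose_optimal_n()].
#' @return Object of class `rfe_result`: `learning_curve` (`n_features`,
#'   `mean_score`, `sd_score`), `ranking` (`feature`, `elimination_order`,
#'   `rank`; rank 1 = retained longest), `optimal_n`, `optimal_set`.
#' @export
rfe_cv <- function(x, y, folds = 5, seed = 1, num_trees = 500,
                   rule = c("argmax", "onese")) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 feature columns", call. = FALSE)
  if (nrow(x) < folds) stop("fewer rows than folds", call. = FALSE)
  if (sd(y) == 0) stop("constant target", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("column names must be unique", call. = FALSE)
  rule <- match.arg(rule)

  fold_idx <- make_folds(nrow(x), folds, seed)
  p <- ncol(x)
  current <- colnames(x)
  curve <- matrix(NA_real_, p, 2, dimnames = list(NULL, c("mean", "sd")))
  elim_order <- integer(p)
  names(elim_order) <- colnames(x)

  for (size in p:1) {
    curve[size, ] <- rf_cv_score(x, y, current, fold_idx,
                                 seed = seed + size * 100L,
                                 num_trees = num_trees)
    if (size > 1) {
      st <- standardize_fit(x[, current, drop = FALSE])
      fit <- ranger::ranger(
        x = standardize_apply(x[, current, drop = FALSE], st), y = y,
        num.trees = num_trees, importance = "impurity",
        seed = seed + size, num.threads = 1L
      )
      imp <- fit$variable.importance[current]
      drop_feat <- current[which.min(imp)]
      elim_order[drop_feat] <- p - size + 1L
      current <- setdiff(current, drop_feat)
    } else {
      elim_order[current] <- p
    }
  }

  learning_curve <- data.frame(
    n_features = seq_len(p),
    mean_score = curve[, "mean"],
    sd_score = curve[, "sd"]
  )
  ranking <- data.frame(
    feature = names(elim_order),
    elimination_order = unname(elim_order),
    rank = p + 1L - unname(elim_order)
  )
  ranking <- ranking[order(ranking$rank), ]
  rownames(ranking) <- NULL
  optimal_n <- choose_optimal_n(learning_curve, rule)
  structure(
    list(
      learning_curve = learning_curve,
      ranking = ranking,
      optimal_n = optimal_n,
      optimal_set = ranking$feature[seq_len(optimal_n)],
      seed = seed
    ),
    class = "rfe_result"
  )
}

#' Pick the optimal number of features from an RFE learning curve
#'
#' `"argmax"` takes the subset size with the highest mean CV score, breaking
#' ties toward the smallest size. `"onese"` takes the smallest size whose
#' mean score is within one standard error (the SD at the argmax) of the
#' maximum.
#'
#' @param curve `data.frame` with `n_features`, `mean_score` and (for
#'   `"onese"`) `sd_score` columns.
#' @param rule `"argmax"` (default) or `"onese"`.
#' @return Integer subset size.
#' @export
choose_optimal_n <- function(curve, rule = c("argmax", "onese")) {
  rule <- match.arg(rule)
  if (nrow(curve) == 0) stop("empty learning curve", call. = FALSE)
  best <- which(curve$mean_score == max(curve$mean_score))[1L]
  if (rule == "argmax") return(curve$n_features[best])
  thr <- curve$mean_score[best] - curve$sd_score[best]
  curve$n_features[which(curve$mean_score >= thr)[1L]]
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf(
    "rfe_result: %d candidate features, optimal n = %d (best CV R2 = %.4f)\n",
    nrow(x$ranking), x$optimal_n,
    max(x$learning_curve$mean_score)
  ))
  cat("optimal set:", paste(head(x$optimal_set, 10), collapse = ", "),
      if (x$optimal_n > 10) "..." else "", "\n")
  invisible(x)
}

#' Write RFE outputs (learning curve, ranking, selected set)
#'
#' @param rfe An `rfe_result`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix identifying the cell (e.g. `"20m_VIs"`).
#' @return Character vector of the written paths, invisibly.
#' @export
write_rfe_results <- function(rfe, dir, prefix = "rfe") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    curve = file.path(dir, paste0(prefix, "_learning_curve.csv")),
    ranking = file.path(dir, paste0(prefix, "_ranking.csv")),
    selected = file.path(dir, paste0(prefix, "_selected.json"))
  )
  write.csv(rfe$learning_curve, paths["curve"], row.names = FALSE, quote = FALSE)
  write.csv(rfe$ranking, paths["ranking"], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(optimal_n = rfe$optimal_n, optimal_set = rfe$optimal_set),
    paths["selected"], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
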