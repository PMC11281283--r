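#' The seven named variable sets
#'
#' @return Character vector: `"VIs"`, `"TIs"`, `"DWT"` and their pairwise and
#'   three-way unions.
#' @export
variable_set_names <- function() {
  c("VIs", "TIs", "DWT", "VIs+TIs", "VIs+DWT", "TIs+DWT", "VIs+TIs+DWT")
}

#' Feature columns belonging to a variable set
#'
#' @param set One of [variable_set_names()].
#' @return Character vector of feature column names (22, 40, 20 for the
#'   single sets; exact unions for the combinations).
#' @export
variable_set_columns <- function(set) {
  parts <- strsplit(set, "+", fixed = TRUE)[[1L]]
  cols <- character(0)
  for (p in parts) {
    cols <- c(cols, switch(
      p,
      VIs = VI_NAMES,
      TIs = TEXTURE_NAMES,
      DWT = WAVELET_NAMES,
      stop("unknown variable set part: ", p, call. = FALSE)
    ))
  }
  cols
}

#' Assemble the plots x features matrix for a variable set
#'
#' Extracts (or reuses) the VI, texture and wavelet tables required by `set`,
#' joins them on `plot_id`, attaches measured SPAD as the target column and
#' drops rows with any non-finite feature.
#'
#' @param scene A [multiband_scene()].
#' @param spad_table Table with `plot_id` and `spad_measured` columns.
#' @param set One of [variable_set_names()].
#' @param tables Optional named list caching precomputed feature tables
#'   (`VIs`, `TIs`, `DWT`) to share across sets.
#' @param glcm A [glcm_config()] for the texture part.
#' @return `data.frame` with `plot_id`, `spad_measured` and the set's feature
#'   columns; attribute `"feature_names"` holds the feature column names.
#' @export
build_feature_matrix <- function(scene, spad_table, set = "VIs",
                                 tables = NULL, glcm = glcm_config()) {
  parts <- strsplit(set, "+", fixed = TRUE)[[1L]]
  tabs <- lapply(parts, function(p) {
    if (!is.null(tables[[p]])) return(tables[[p]])
    switch(p,
      VIs = vi_features(scene),
      TIs = texture_features(scene, glcm),
      DWT = wavelet_features(scene),
      stop("unknown variable set part: ", p, call. = FALSE)
    )
  })
  merged <- Reduce(function(a, b) merge(a, b, by = "plot_id", sort = TRUE), tabs)
  out <- merge(
    spad_table[, c("plot_id", "spad_measured")], merged,
    by = "plot_id", sort = TRUE
  )
  feats <- variable_set_columns(set)
  keep <- apply(is.finite(as.matrix(out[, feats, drop = FALSE])), 1L, all)
  if (!all(keep)) {
    warning(sum(!keep), " plot(s) dropped for non-finite features")
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "feature_names") <- feats
  out
}
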