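#' GLCM texture configuration
#'
#' Defaults follow the extraction protocol used throughout the package: a
#' 7 x 7 moving window, a displacement of (2, 2) (two columns right, two rows
#' down), 64 gray levels from per-band min-max quantization, and
#' non-symmetric pair counting.
#'
#' @param window Odd window side length in pixels.
#' @param offset Integer displacement `c(dx, dy)` (columns, rows).
#' @param gray_levels Number of quantization levels (>= 2).
#' @param symmetric Also count transposed pairs.
#' @return A list of class `glcm_config`.
#' @export
glcm_config <- function(window = 7, offset = c(2, 2), gray_levels = 64,
                        symmetric = FALSE) {
  if (window %% 2 != 1) stop("window must be odd-sized", call. = FALSE)
  if (any(abs(offset) >= window)) {
    stop("offset magnitudes must be smaller than the window", call. = FALSE)
  }
  if (gray_levels < 2) stop("gray_levels must be >= 2", call. = FALSE)
  structure(
    list(window = as.integer(window), offset = as.integer(offset),
         gray_levels = as.integer(gray_levels), symmetric = symmetric),
    class = "glcm_config"
  )
}

TEXTURE_METRICS <- c("mean", "variance", "homogeneity", "contrast",
                     "dissimilarity", "entropy", "secondmoment", "correlation")

#' Names of the 40 GLCM texture features
#'
#' Eight Haralick metrics per band, named `<band>-<metric>` (e.g. `"R-mean"`,
#' `"RE-secondmoment"`).
#'
#' @format Character vector of length 40.
#' @export
TEXTURE_NAMES <- as.vector(t(outer(c("R", "G", "B", "NIR", "RE"),
                                   TEXTURE_METRICS, paste, sep = "-")))

# bounding boxes (r0, r1, c0, c1) of every nonzero mask label, one pass
plot_bboxes <- function(mask) {
  w <- which(mask != 0L)
  if (!length(w)) return(list())
  nr <- nrow(mask)
  lab <- mask[w]
  r <- (w - 1L) %% nr + 1L
  c <- (w - 1L) %/% nr + 1L
  out <- lapply(split(seq_along(w), lab), function(ii) {
    c(range(r[ii]), range(c[ii]))
  })
  out
}

#' Quantize a band raster to integer gray levels
#'
#' Linear min-max mapping of the band's value range onto
#' `0 .. gray_levels - 1`; a constant band maps entirely to level 0.
#'
#' @param band Numeric matrix.
#' @param gray_levels Number of levels.
#' @return Integer matrix of gray levels.
#' @export
quantize_band <- function(band, gray_levels = 64) {
  rng <- range(band)
  if (rng[2] - rng[1] <= 0) {
    return(matrix(0L, nrow(band), ncol(band)))
  }
  q <- floor((band - rng[1]) / (rng[2] - rng[1]) * gray_levels)
  q[q == gray_levels] <- gray_levels - 1L
  storage.mode(q) <- "integer"
  q
}

#' Gray-level co-occurrence matrix of a single window
#'
#' Counts ordered gray-level pairs `(p, p + offset)` whose both ends lie in
#' the window and normalizes the counts to sum 1; in symmetric mode the
#' transposed pair is counted as well.
#'
#' @param window Integer matrix of gray levels.
#' @param offset Displacement `c(dx, dy)` (columns, rows).
#' @param gray_levels Matrix side; defaults to `max(window) + 1`.
#' @param symmetric Count transposed pairs too.
#' @return `gray_levels x gray_levels` probability matrix.
#' @export
glcm_for_window <- function(window, offset = c(2, 2), gray_levels = NULL,
                            symmetric = FALSE) {
  dx <- offset[1]; dy <- offset[2]
  nr <- nrow(window); nc <- ncol(window)
  if (nr - abs(dy) < 1 || nc - abs(dx) < 1) {
    stop("window has no valid pixel pair at this offset", call. = FALSE)
  }
  rows <- seq_len(nr - abs(dy)); cols <- seq_len(nc - abs(dx))
  r2 <- rows + abs(dy); c2 <- cols + abs(dx)
  from <- window[rows, cols, drop = FALSE]
  to <- window[r2, c2, drop = FALSE]
  g <- gray_levels %||% (max(window) + 1L)
  P <- matrix(0, g, g)
  for (k in seq_along(from)) {
    i <- from[k] + 1L; j <- to[k] + 1L
    P[i, j] <- P[i, j] + 1
    if (symmetric) P[j, i] <- P[j, i] + 1
  }
  P / sum(P)
}

#' Haralick metrics of a co-occurrence matrix
#'
#' Standard definitions over gray levels `i, j` starting at 0:
#' mean `sum(i P)`, variance `sum((i - mean)^2 P)`, homogeneity
#' `sum(P / (1 + (i - j)^2))`, contrast `sum((i - j)^2 P)`, dissimilarity
#' `sum(|i - j| P)`, entropy `-sum(P log P)` (natural log, `0 log 0 := 0`),
#' second moment `sum(P^2)`, and correlation
#' `sum((i - mu_i)(j - mu_j) P) / (sigma_i sigma_j)` with correlation defined
#' as 1 when `sigma_i sigma_j = 0` (a constant texture is perfectly
#' correlated).
#'
#' @param P Square co-occurrence probability matrix.
#' @return Named numeric vector of the 8 metrics.
#' @export
haralick_metrics <- function(P) {
  g <- nrow(P)
  i <- matrix(0:(g - 1), g, g)        # row gray level
  j <- t(i)                           # column gray level
  mu_i <- sum(i * P)
  mu_j <- sum(j * P)
  var_i <- sum((i - mu_i)^2 * P)
  var_j <- sum((j - mu_j)^2 * P)
  pos <- P > 0
  entropy <- -sum(P[pos] * log(P[pos]))
  sig <- sqrt(var_i * var_j)
  correlation <- if (sig == 0) 1 else sum((i - mu_i) * (j - mu_j) * P) / sig
  c(mean = mu_i,
    variance = var_i,
    homogeneity = sum(P / (1 + (i - j)^2)),
    contrast = sum((i - j)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    entropy = entropy,
    secondmoment = sum(P^2),
    correlation = correlation)
}

#' Plot-level GLCM texture features (40 per plot)
#'
#' Each band is min-max quantized over the full raster, then for every pixel
#' whose centered window lies entirely inside the plot's mask footprint the 8
#' Haralick metrics are computed from that window's co-occurrence matrix; the
#' plot feature is the mean of each metric over those window centers. The
#' 5 bands x 8 metrics give 40 features.
#'
#' @param scene A [multiband_scene()].
#' @param plot_id Plot label.
#' @param config A [glcm_config()].
#' @param quantized Optional precomputed list of quantized band matrices (as
#'   produced internally); used by [texture_features()] to share work across
#'   plots.
#' @return Named numeric vector of length 40 (`<band>-<metric>`).
#' @export
texture_features_for_plot <- function(scene, plot_id, config = glcm_config(),
                                      quantized = NULL) {
  stopifnot(inherits(config, "glcm_config"))
  quantized <- quantized %||% lapply(scene$bands, quantize_band,
                                     gray_levels = config$gray_levels)
  # bounding box: full windows inside the plot mask cannot reach outside it
  bbox <- attr(quantized, "bboxes")[[as.character(plot_id)]] %||%
    plot_bboxes(scene$mask)[[as.character(plot_id)]]
  if (is.null(bbox)) {
    stop("plot_id ", plot_id, " not present in mask", call. = FALSE)
  }
  rows <- bbox[1]:bbox[2]; cols <- bbox[3]:bbox[4]
  mask_crop <- scene$mask[rows, cols, drop = FALSE]
  out <- numeric(0)
  for (b in c("R", "G", "B", "NIR", "RE")) {
    m <- glcm_plot_metrics(
      quantized[[b]][rows, cols, drop = FALSE], mask_crop, as.integer(plot_id),
      config$window, config$offset[1], config$offset[2],
      config$gray_levels, config$symmetric
    )
    if (m[9] < 1) {
      stop("plot ", plot_id, " admits no full ", config$window, "x",
           config$window, " window", call. = FALSE)
    }
    names(m) <- c(paste(b, TEXTURE_METRICS, sep = "-"), "n_windows")
    out <- c(out, m[1:8])
  }
  out[TEXTURE_NAMES]
}

#' GLCM texture feature table for every plot in a scene
#'
#' @param scene A [multiband_scene()].
#' @param config A [glcm_config()].
#' @param plot_ids Plots to extract; defaults to all labels in the mask.
#' @return `data.frame` with `plot_id` plus the 40 texture columns.
#' @export
texture_features <- function(scene, config = glcm_config(), plot_ids = NULL) {
  plot_ids <- plot_ids %||% sort(setdiff(unique(as.vector(scene$mask)), 0L))
  quantized <- lapply(scene$bands, quantize_band,
                      gray_levels = config$gray_levels)
  attr(quantized, "bboxes") <- plot_bboxes(scene$mask)
  rows <- lapply(plot_ids, function(p) {
    texture_features_for_plot(scene, p, config, quantized = quantized)
  })
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  cbind(plot_id = plot_ids, out)
}
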