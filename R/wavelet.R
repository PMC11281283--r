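#' bior 1.3 biorthogonal filter bank
#'
#' Standard biorthogonal spline 1.3 analysis/synthesis filters (6-tap
#' analysis low-pass paired with a Haar-type high-pass); the analysis
#' low-pass sums to `sqrt(2)`, so one 2-D decomposition level has a DC gain
#' of 2 in the LL band.
#'
#' @return List with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` numeric vectors.
#' @export
bior13_filters <- function() {
  h <- 0.088388347648318447  # sqrt(2) / 16
  s <- 0.70710678118654746   # 1 / sqrt(2)
  list(
    dec_lo = c(-h, h, s, s, h, -h),
    dec_hi = c(0, 0, -s, s, 0, 0),
    rec_lo = c(0, 0, s, s, 0, 0),
    rec_hi = c(-h, -h, s, -s, h, h)
  )
}

# symmetric (half-sample) extension indices for a length-n signal padded by p
sym_ext_idx <- function(n, p) {
  c(rev(seq_len(p)), seq_len(n), n + 1 - seq_len(p))
}

# one analysis pass along dim 1 (rows) for low and high filters jointly:
# symmetric pad by flen-1, valid convolution, keep even output indices
dwt_pass_dim1 <- function(x, filt) {
  n <- nrow(x)
  flen <- length(filt)
  if (n < flen) stop("raster smaller than the filter support", call. = FALSE)
  p <- flen - 1L
  xe <- x[sym_ext_idx(n, p), , drop = FALSE]
  n_full <- n + p
  y <- matrix(0, n_full, ncol(x))
  for (m in seq_len(flen)) {
    y <- y + filt[m] * xe[(flen - m) + seq_len(n_full), , drop = FALSE]
  }
  y[seq(2L, n_full, by = 2L), , drop = FALSE]
}

# one synthesis pass along dim 1: zero-upsample, full convolution, trim flen-2
idwt_pass_dim1 <- function(c_lo, c_hi, filters, n_out) {
  flen <- length(filters$rec_lo)
  L <- nrow(c_lo)
  up <- function(cm) {
    u <- matrix(0, 2L * L, ncol(cm))
    u[seq(1L, 2L * L, by = 2L), ] <- cm
    u
  }
  conv_full <- function(u, filt) {
    z <- matrix(0, 2L * L + flen - 1L, ncol(u))
    for (m in seq_len(flen)) {
      z[(m - 1L) + seq_len(2L * L), ] <- z[(m - 1L) + seq_len(2L * L), ] +
        filt[m] * u
    }
    z
  }
  z <- conv_full(up(c_lo), filters$rec_lo) + conv_full(up(c_hi), filters$rec_hi)
  z[(flen - 2L) + seq_len(n_out), , drop = FALSE]
}

#' Single-level 2-D discrete wavelet transform (bior 1.3)
#'
#' Separable analysis: the low/high-pass filter pair is applied along rows,
#' then along columns, each pass followed by dyadic downsampling, with
#' symmetric (half-sample) boundary extension. Sub-band dimensions are
#' `floor((n + filter_length - 1) / 2)`. `LH` carries horizontal detail
#' (variation across rows), `HL` vertical detail, `HH` diagonal detail and
#' `LL` the approximation; for a constant input of value `c`, all `LL`
#' coefficients equal `2 c` and the detail bands are exactly zero.
#'
#' @param band Numeric matrix with both dimensions `>=` the filter length (6).
#' @return List of class `subband_set` with matrices `LL`, `LH`, `HL`, `HH`
#'   and attribute `orig_dim`.
#' @export
dwt2_single_level <- function(band) {
  f <- bior13_filters()
  lo1 <- dwt_pass_dim1(band, f$dec_lo)
  hi1 <- dwt_pass_dim1(band, f$dec_hi)
  along2 <- function(x, filt) t(dwt_pass_dim1(t(x), filt))
  out <- list(
    LL = along2(lo1, f$dec_lo),
    LH = along2(hi1, f$dec_lo),
    HL = along2(lo1, f$dec_hi),
    HH = along2(hi1, f$dec_hi)
  )
  attr(out, "orig_dim") <- dim(band)
  class(out) <- "subband_set"
  out
}

#' Inverse of [dwt2_single_level()]
#'
#' Reconstructs the input raster from its four sub-bands with the bior 1.3
#' synthesis filters; exact (to numerical precision) for even-sized inputs.
#'
#' @param subbands A `subband_set` from [dwt2_single_level()].
#' @return Numeric matrix of the original dimensions.
#' @export
idwt2_single_level <- function(subbands) {
  f <- bior13_filters()
  od <- attr(subbands, "orig_dim")
  # invert along columns first (reverse of the forward order)
  ncol_out <- od[2]
  along2 <- function(c_lo, c_hi) {
    t(idwt_pass_dim1(t(c_lo), t(c_hi), f, ncol_out))
  }
  lo1 <- along2(subbands$LL, subbands$HL)
  hi1 <- along2(subbands$LH, subbands$HH)
  idwt_pass_dim1(lo1, hi1, f, od[1])
}

#' Names of the 20 wavelet features
#'
#' Mean sub-band coefficient per band, named `<band>_<subband>` (e.g.
#' `"R_HH"`, `"NIR_LL"`).
#'
#' @format Character vector of length 20.
#' @export
WAVELET_NAMES <- as.vector(t(outer(c("R", "G", "B", "NIR", "RE"),
                                   c("LL", "LH", "HL", "HH"), paste, sep = "_")))

# nearest-neighbor downsampling of the mask to the sub-band grid: sub-band
# index k maps to source index 2k - 2 (clamped), the center of the filter
# support feeding that coefficient
mask_to_subband <- function(mask, sub_dim) {
  idx <- function(L, n) pmin(pmax(2L * seq_len(L) - 2L, 1L), n)
  mask[idx(sub_dim[1], nrow(mask)), idx(sub_dim[2], ncol(mask)), drop = FALSE]
}

#' Wavelet features for one plot (20 values)
#'
#' Each full band raster is transformed once; the plot mask is downsampled to
#' the sub-band grid by nearest neighbor and the feature is the mean
#' coefficient over the plot footprint in each of LL/LH/HL/HH for each band.
#'
#' @param scene A [multiband_scene()].
#' @param plot_id Plot label.
#' @param subbands Optional precomputed list of per-band `subband_set`s
#'   (shared across plots by [wavelet_features()]).
#' @param abs_detail Take the mean of absolute coefficients for the detail
#'   bands (LH/HL/HH) instead of the signed mean.
#' @param mask_ds Optional precomputed sub-band-resolution mask (shared
#'   across plots by [wavelet_features()]).
#' @return Named numeric vector of length 20 (`<band>_<subband>`).
#' @export
wavelet_features_for_plot <- function(scene, plot_id, subbands = NULL,
                                      abs_detail = FALSE, mask_ds = NULL) {
  subbands <- subbands %||% lapply(scene$bands, dwt2_single_level)
  mask_ds <- mask_ds %||% mask_to_subband(scene$mask, dim(subbands[[1]]$LL))
  sel <- mask_ds == plot_id
  if (!any(sel)) {
    stop("plot ", plot_id, " footprint vanished at sub-band resolution",
         call. = FALSE)
  }
  out <- numeric(0)
  for (b in c("R", "G", "B", "NIR", "RE")) {
    sb <- subbands[[b]]
    for (s in c("LL", "LH", "HL", "HH")) {
      v <- sb[[s]][sel]
      if (abs_detail && s != "LL") v <- abs(v)
      out[[paste(b, s, sep = "_")]] <- mean(v)
    }
  }
  out[WAVELET_NAMES]
}

#' Wavelet feature table for every plot in a scene
#'
#' @param scene A [multiband_scene()].
#' @param plot_ids Plots to extract; defaults to all labels in the mask.
#' @param abs_detail See [wavelet_features_for_plot()].
#' @return `data.frame` with `plot_id` plus the 20 wavelet columns.
#' @export
wavelet_features <- function(scene, plot_ids = NULL, abs_detail = FALSE) {
  plot_ids <- plot_ids %||% sort(setdiff(unique(as.vector(scene$mask)), 0L))
  subbands <- lapply(scene$bands, dwt2_single_level)
  mask_ds <- mask_to_subband(scene$mask, dim(subbands[[1]]$LL))
  rows <- lapply(plot_ids, function(p) {
    wavelet_features_for_plot(scene, p, subbands = subbands,
                              abs_detail = abs_detail, mask_ds = mask_ds)
  })
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  cbind(plot_id = plot_ids, out)
}
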