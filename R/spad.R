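#' Treatment-effect parameters of the synthetic SPAD model
#'
#' Plot-level true SPAD is modelled as
#' `mu0 + variety offset + f(nitrogen rate) + method offset + N(0, sigma_plot)`,
#' truncated to the SPAD-502Plus meter range 0--99.9. The nitrogen response
#' `f(N) = n_span * N / (N + n_half)` is monotone non-decreasing and
#' saturating, emulating the diminishing return of fertilization on leaf
#' chlorophyll; with the defaults it spans roughly 10 SPAD units from N0 to
#' the 330 kg/ha rate. Fertilizer-method offsets apply to Experiment-2 plots
#' only.
#'
#' @param mu0 Baseline SPAD (unitless, meter scale).
#' @param variety_offsets Named additive offsets (SPAD) per variety.
#' @param n_span,n_half Saturating nitrogen-response parameters: asymptotic
#'   span (SPAD) and half-saturation rate (kg/ha).
#' @param method_offsets Named additive offsets (SPAD) per fertilizer method.
#' @param sigma_plot Plot-to-plot SD (SPAD) of the residual noise; must be
#'   non-negative.
#' @return A list of class `spad_effect_params`.
#' @export
spad_effect_params <- function(mu0 = 45,
                               variety_offsets = c(YM22 = 0, YM25 = -1.5,
                                                   YM39 = 1, NM26 = -0.5),
                               n_span = 15.4, n_half = 180,
                               method_offsets = c(M1 = 0, M2 = 0.6,
                                                  M3 = 0.9, M4 = 1.2),
                               sigma_plot = 1.5) {
  if (sigma_plot < 0) stop("sigma_plot must be >= 0", call. = FALSE)
  if (n_span < 0) stop("n_span must be >= 0 (monotone non-decreasing response)",
                       call. = FALSE)
  structure(
    list(mu0 = mu0, variety_offsets = variety_offsets,
         n_span = n_span, n_half = n_half,
         method_offsets = method_offsets, sigma_plot = sigma_plot),
    class = "spad_effect_params"
  )
}

nitrogen_response <- function(n_rate, params) {
  params$n_span * n_rate / (n_rate + params$n_half)
}

#' Simulate true plot-level SPAD from the treatment design
#'
#' @param design Output of [generate_design()].
#' @param params [spad_effect_params()] describing treatment effects.
#' @param seed Integer seed for the plot-level noise.
#' @return A `data.frame` (`plot_id`, `spad_true`) with `spad_true` in
#'   SPAD units, truncated to `[0, 99.9]`.
#' @examples
#' d <- generate_design(1)
#' spad <- simulate_true_spad(d, spad_effect_params(sigma_plot = 0), seed = 1)
#' @export
simulate_true_spad <- function(design, params = spad_effect_params(), seed = 1) {
  stopifnot(inherits(params, "spad_effect_params"))
  voff <- params$variety_offsets[design$variety]
  voff[is.na(voff)] <- 0
  moff <- rep(0, nrow(design))
  has_m <- !is.na(design$method)
  moff[has_m] <- params$method_offsets[design$method[has_m]]
  moff[is.na(moff)] <- 0
  mu <- params$mu0 + unname(voff) + nitrogen_response(design$nitrogen_rate, params) + moff
  noise <- with_local_seed(seed, rnorm(nrow(design), 0, params$sigma_plot))
  spad <- pmin(pmax(mu + noise, 0), 99.9)
  data.frame(plot_id = design$plot_id, spad_true = spad)
}

#' Field SPAD measurement protocol
#'
#' Emulates the in-situ protocol: five sampling points per plot, ten flag
#' leaves per point (50 leaves), three meter reads per leaf; the plot
#' measurement is the mean over the 50 per-leaf read means. `leaf_sd` is the
#' leaf-to-leaf biological SD and `meter_sd` the per-read instrument SD, which
#' is bounded by the +/- 1.0 SPAD accuracy of the SPAD-502Plus.
#'
#' @param points_per_plot,leaves_per_point,reads_per_leaf Positive counts.
#' @param leaf_sd,meter_sd Non-negative SDs in SPAD units; `meter_sd <= 1`.
#' @return A list of class `spad_protocol`.
#' @export
spad_protocol <- function(points_per_plot = 5, leaves_per_point = 10,
                          reads_per_leaf = 3, leaf_sd = 2, meter_sd = 0.5) {
  counts <- c(points_per_plot, leaves_per_point, reads_per_leaf)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("protocol counts must be positive integers", call. = FALSE)
  }
  if (leaf_sd < 0 || meter_sd < 0) stop("SDs must be >= 0", call. = FALSE)
  if (meter_sd > 1) {
    stop("meter_sd exceeds the 1.0 SPAD unit instrument accuracy", call. = FALSE)
  }
  structure(
    list(points_per_plot = points_per_plot, leaves_per_point = leaves_per_point,
         reads_per_leaf = reads_per_leaf, leaf_sd = leaf_sd, meter_sd = meter_sd),
    class = "spad_protocol"
  )
}

#' Simulate measured plot SPAD under the sampling protocol
#'
#' Each leaf draws `spad_true + N(0, leaf_sd)`; each of the three reads on a
#' leaf adds `N(0, meter_sd)`; the plot measurement is the mean over all
#' leaves of the per-leaf read means, truncated to the meter range 0--99.9.
#'
#' @param spad_table Output of [simulate_true_spad()] (`plot_id`, `spad_true`).
#' @param protocol A [spad_protocol()].
#' @param seed Integer seed.
#' @return A `data.frame` with `plot_id`, `spad_true`, `spad_measured`,
#'   `n_leaves`.
#' @export
simulate_measured_spad <- function(spad_table, protocol = spad_protocol(),
                                   seed = 1) {
  stopifnot(inherits(protocol, "spad_protocol"))
  n_leaves <- protocol$points_per_plot * protocol$leaves_per_point
  reads <- protocol$reads_per_leaf
  measured <- with_local_seed(seed, {
    vapply(spad_table$spad_true, function(s) {
      leaf <- s + rnorm(n_leaves, 0, protocol$leaf_sd)
      read_means <- leaf + colMeans(matrix(
        rnorm(n_leaves * reads, 0, protocol$meter_sd),
        nrow = reads
      ))
      mean(read_means)
    }, numeric(1))
  })
  data.frame(
    plot_id = spad_table$plot_id,
    spad_true = spad_table$spad_true,
    spad_measured = pmin(pmax(measured, 0), 99.9),
    n_leaves = n_leaves
  )
}

#' Write a SPAD table to CSV
#' @param spad_table Output of [simulate_measured_spad()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_spad_csv <- function(spad_table, path) {
  write.csv(spad_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
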