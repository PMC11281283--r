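#' Generate the 72-plot split-plot field design
#'
#' Builds the factorial layout of the two winter-wheat experiments:
#' Experiment 1 crosses four varieties (YM22, YM25, YM39, NM26) with four
#' nitrogen rates (0, 150, 240, 330 kg/ha) in three replicates (48 plots);
#' Experiment 2 crosses two varieties (YM22, YM39) with four fertilizer
#' application methods (M1--M4) at 240 kg/ha in three replicates (24 plots).
#' Plots are 3 m x 4 m (12 m2) with 25 cm row spacing, laid out on a
#' 12-column x 6-row grid with 0.5 m alleys; Experiment 1 occupies the first
#' four grid rows. The seed randomizes which treatment combination lands on
#' which plot position within each experiment; the factorial structure itself
#' is identical for every seed.
#'
#' @param seed Integer seed controlling the treatment-to-position assignment.
#' @param plot_width_m,plot_height_m Plot dimensions in meters; their product
#'   must equal 12 m2.
#' @param alley_m Width of the alleys separating plots (and the field border).
#' @return A `data.frame` with one row per plot: `plot_id` (1--72),
#'   `experiment` (1 or 2), `variety`, `nitrogen_rate` (kg/ha), `method`
#'   (M1--M4, `NA` for Experiment 1), `replicate`, plot geometry columns and
#'   the plot origin in field coordinates (`origin_x_m`, `origin_y_m`, meters).
#' @examples
#' design <- generate_design(seed = 1)
#' table(design$experiment)
#' @export
generate_design <- function(seed = 1, plot_width_m = 3, plot_height_m = 4,
                            alley_m = 0.5) {
  if (abs(plot_width_m * plot_height_m - 12) > 1e-9) {
    stop("plot area must be 12 m2 (plot_width_m * plot_height_m)", call. = FALSE)
  }
  exp1 <- expand.grid(
    variety = c("YM22", "YM25", "YM39", "NM26"),
    nitrogen_rate = c(0, 150, 240, 330),
    replicate = 1:3,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  exp1$experiment <- 1L
  exp1$method <- NA_character_
  exp2 <- expand.grid(
    variety = c("YM22", "YM39"),
    method = c("M1", "M2", "M3", "M4"),
    replicate = 1:3,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  exp2$experiment <- 2L
  exp2$nitrogen_rate <- 240

  with_local_seed(seed, {
    exp1 <- exp1[sample.int(nrow(exp1)), ]
    exp2 <- exp2[sample.int(nrow(exp2)), ]
  })
  design <- rbind(
    exp1[, c("experiment", "variety", "nitrogen_rate", "method", "replicate")],
    exp2[, c("experiment", "variety", "nitrogen_rate", "method", "replicate")]
  )
  n <- nrow(design)
  design <- cbind(plot_id = seq_len(n), design)
  rownames(design) <- NULL

  # 12 columns x 6 rows; rows 1-4 hold Experiment 1 (plots 1-48)
  ncol_grid <- 12L
  design$grid_col <- ((design$plot_id - 1L) %% ncol_grid) + 1L
  design$grid_row <- ((design$plot_id - 1L) %/% ncol_grid) + 1L
  design$plot_width_m <- plot_width_m
  design$plot_height_m <- plot_height_m
  design$row_spacing_m <- 0.25
  design$origin_x_m <- alley_m + (design$grid_col - 1L) * (plot_width_m + alley_m)
  design$origin_y_m <- alley_m + (design$grid_row - 1L) * (plot_height_m + alley_m)
  attr(design, "alley_m") <- alley_m
  design
}

#' Write a plot design table to CSV
#'
#' @param design Output of [generate_design()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
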