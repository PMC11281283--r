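#' Names of the 22 vegetation-index features
#'
#' The five raw band reflectances count as the first five "indices"; the
#' remaining 17 are algebraic band combinations. `OSAVI` and `EVI` follow the
#' exact formulations used for this feature set, which differ from some
#' textbook variants: `OSAVI = (NIR - R)/(NIR - R + 0.16)` and
#' `EVI = 2.5 (NIR - R)/(1 + NIR - 2.4 R)` (no blue term); `NDREI` is
#' `(RE - G)/(RE + G)`.
#'
#' @format Character vector of length 22.
#' @export
VI_NAMES <- c(
  "R", "G", "B", "RE", "NIR",
  "RVI", "GCI", "RECI", "TCARI", "NDVI", "GNDVI", "GRVI", "NDRE", "NDREI",
  "SCCCI", "EVI", "EVI2", "OSAVI", "MCARI", "TCARI/OSAVI", "MCARI/OSAVI",
  "WDRVI"
)

#' Mean band reflectance over a plot footprint
#'
#' @param scene A [multiband_scene()].
#' @param plot_id Plot label present in the scene mask.
#' @return Named numeric vector (R, G, B, RE, NIR) of plot-mean reflectance.
#' @export
plot_mean_reflectance <- function(scene, plot_id) {
  sel <- scene$mask == plot_id
  if (!any(sel)) stop("plot_id ", plot_id, " not present in mask", call. = FALSE)
  out <- vapply(c("R", "G", "B", "RE", "NIR"),
                function(b) mean(scene$bands[[b]][sel]), numeric(1))
  out
}

#' Compute the 22 vegetation indices from plot-mean reflectance
#'
#' All formulas are evaluated as written in the feature-set definition, with
#' `L = 0.16` in OSAVI and `a = 0.12` in WDRVI; `SCCCI = NDRE/NDVI` and the
#' two ratio indices are computed from the previously evaluated parts. A zero
#' denominator yields a non-finite value that is flagged in the `"errors"`
#' attribute (per-index record) rather than raising an error.
#'
#' @param refl Named reflectance vector with entries R, G, B, RE, NIR.
#' @return Named numeric vector of length 22; attribute `"errors"` lists any
#'   indices that evaluated non-finite.
#' @examples
#' compute_vis(c(R = 0.1, G = 0.12, B = 0.08, RE = 0.3, NIR = 0.5))
#' @export
compute_vis <- function(refl) {
  need <- c("R", "G", "B", "RE", "NIR")
  if (!all(need %in% names(refl))) {
    stop("refl must contain bands ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(refl[need]))) stop("band values must be finite", call. = FALSE)
  R <- refl[["R"]]; G <- refl[["G"]]; B <- refl[["B"]]
  RE <- refl[["RE"]]; NIR <- refl[["NIR"]]
  L <- 0.16; a <- 0.12

  v <- c(R = R, G = G, B = B, RE = RE, NIR = NIR)
  v[["RVI"]]   <- NIR / R
  v[["GCI"]]   <- NIR / G - 1
  v[["RECI"]]  <- NIR / RE - 1
  v[["TCARI"]] <- 3 * ((RE - R) - 0.2 * (RE - G) * (RE / R))
  v[["NDVI"]]  <- (NIR - R) / (NIR + R)
  v[["GNDVI"]] <- (NIR - G) / (NIR + G)
  v[["GRVI"]]  <- (G - R) / (G + R)
  v[["NDRE"]]  <- (NIR - RE) / (NIR + RE)
  v[["NDREI"]] <- (RE - G) / (RE + G)
  v[["SCCCI"]] <- v[["NDRE"]] / v[["NDVI"]]
  v[["EVI"]]   <- 2.5 * (NIR - R) / (1 + NIR - 2.4 * R)
  v[["EVI2"]]  <- 2.5 * (NIR - R) / (NIR + 2.4 * R + 1)
  v[["OSAVI"]] <- (NIR - R) / (NIR - R + L)
  v[["MCARI"]] <- ((RE - R) - 0.2 * (RE - G)) * (RE / R)
  v[["TCARI/OSAVI"]] <- v[["TCARI"]] / v[["OSAVI"]]
  v[["MCARI/OSAVI"]] <- v[["MCARI"]] / v[["OSAVI"]]
  v[["WDRVI"]] <- (a * NIR - R) / (a * NIR + R)

  v <- v[VI_NAMES]
  bad <- names(v)[!is.finite(v)]
  if (length(bad)) {
    attr(v, "errors") <- data.frame(
      index = bad,
      reason = "non-finite value (zero denominator or overflow)"
    )
  }
  v
}

#' Vegetation-index feature table for every plot in a scene
#'
#' Plot-mean reflectance is computed first and the indices are evaluated on
#' the means (mean-then-index).
#'
#' @param scene A [multiband_scene()].
#' @param plot_ids Plots to extract; defaults to all labels in the mask.
#' @return `data.frame` with `plot_id` plus the 22 VI columns.
#' @export
vi_features <- function(scene, plot_ids = NULL) {
  plot_ids <- plot_ids %||% sort(setdiff(unique(as.vector(scene$mask)), 0L))
  refl <- plot_reflectance_table(scene, plot_ids)
  rows <- lapply(seq_along(plot_ids), function(i) {
    v <- compute_vis(refl[i, ])
    attributes(v)[["errors"]] <- NULL
    v
  })
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  cbind(plot_id = plot_ids, out)
}

# plot-mean reflectance for many plots in one pass over the mask
plot_reflectance_table <- function(scene, plot_ids) {
  sel <- scene$mask %in% plot_ids
  grp <- factor(scene$mask[sel], levels = plot_ids)
  if (any(tabulate(grp, nbins = length(plot_ids)) == 0)) {
    stop("some plot_ids are absent from the mask", call. = FALSE)
  }
  m <- vapply(c("R", "G", "B", "RE", "NIR"), function(b) {
    as.vector(tapply(scene$bands[[b]][sel], grp, mean))
  }, numeric(length(plot_ids)))
  matrix(m, nrow = length(plot_ids),
         dimnames = list(NULL, c("R", "G", "B", "RE", "NIR")))
}

#' Write a feature table to CSV
#'
#' Non-finite entries are written as empty cells and reported via a warning,
#' so a zero-denominator index never silently propagates.
#'
#' @param features `data.frame` with a `plot_id` column plus feature columns.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  num <- vapply(features, is.numeric, logical(1))
  bad <- sum(!sapply(features[num], is.finite))
  if (bad > 0) {
    warning(bad, " non-finite feature value(s) written as empty cells")
    features[num] <- lapply(features[num], function(x) {
      x[!is.finite(x)] <- NA
      x
    })
  }
  write.csv(features, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
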