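#' Flight altitude specification
#'
#' At fixed optics the ground sampling distance (GSD) scales linearly with
#' flight altitude; the reference survey flies at 20 m with 1.06 cm/pixel.
#'
#' @param target_altitude Simulated altitude in meters, `>= base_altitude`.
#' @param base_altitude Reference altitude in meters (default 20).
#' @param base_gsd GSD at the reference altitude, cm/pixel (default 1.06).
#' @return A list of class `altitude_spec`.
#' @export
altitude_spec <- function(target_altitude, base_altitude = 20, base_gsd = 1.06) {
  if (base_altitude <= 0 || any(target_altitude <= 0)) {
    stop("altitudes must be positive", call. = FALSE)
  }
  if (any(target_altitude < base_altitude)) {
    stop("target_altitude must be >= base_altitude (no upsampling)", call. = FALSE)
  }
  structure(
    list(target_altitude = target_altitude, base_altitude = base_altitude,
         base_gsd = base_gsd),
    class = "altitude_spec"
  )
}

#' Ground sampling distance for a simulated flight altitude
#'
#' @param spec An [altitude_spec()], or a numeric target altitude (meters)
#'   with the default 20 m / 1.06 cm baseline.
#' @param rounded Round to 2 decimals for reporting (default); internal
#'   computations use the unrounded value.
#' @return GSD in cm/pixel.
#' @examples
#' gsd_for_altitude(40) # 2.12
#' gsd_for_altitude(60) # 3.18
#' @export
gsd_for_altitude <- function(spec, rounded = TRUE) {
  if (is.numeric(spec)) spec <- altitude_spec(spec)
  gsd <- spec$base_gsd * spec$target_altitude / spec$base_altitude
  if (rounded) round(gsd, 2) else gsd
}

#' Degrade a scene to a coarser GSD by nearest-neighbor resampling
#'
#' Each output pixel takes the value of the source pixel whose center is
#' nearest to the output pixel's center (ties broken toward the smaller
#' index), so no new pixel values are created -- the output band values are a
#' subset of the input's. The plot mask is resampled with the identical index
#' mapping. Output dimensions are `floor(input_dim * scene_gsd / target_gsd)`.
#'
#' @param scene A [multiband_scene()].
#' @param target_gsd Target GSD in cm/pixel, `>= scene$gsd`.
#' @param altitude Optional altitude label (meters) for the resampled scene;
#'   inferred from the GSD ratio when `NULL`.
#' @return A [multiband_scene()] at `target_gsd`.
#' @export
resample_nearest <- function(scene, target_gsd, altitude = NULL) {
  stopifnot(inherits(scene, "multiband_scene"))
  if (target_gsd < scene$gsd) {
    stop("target_gsd must be >= the scene gsd (downsampling only)", call. = FALSE)
  }
  factor <- target_gsd / scene$gsd
  map_idx <- function(n_in) {
    n_out <- floor(n_in / factor)
    if (n_out < 1L) stop("scene too small for this target_gsd", call. = FALSE)
    # output center (i - 0.5) * factor in source pixel units; nearest source
    # center (j - 0.5): j = ceiling(x), which lands ties on the smaller index
    idx <- ceiling((seq_len(n_out) - 0.5) * factor)
    pmin(pmax(idx, 1L), n_in)
  }
  ri <- map_idx(nrow(scene$mask))
  ci <- map_idx(ncol(scene$mask))
  bands <- lapply(scene$bands, function(m) m[ri, ci, drop = FALSE])
  multiband_scene(
    bands, scene$mask[ri, ci, drop = FALSE], gsd = target_gsd,
    altitude = altitude %||% (scene$altitude * factor)
  )
}

#' Simulate a flight altitude by resampling the base scene
#'
#' Convenience wrapper combining [gsd_for_altitude()] (unrounded) and
#' [resample_nearest()].
#'
#' @param scene A base [multiband_scene()].
#' @param target_altitude Altitude in meters.
#' @return A resampled [multiband_scene()].
#' @export
simulate_altitude <- function(scene, target_altitude) {
  spec <- altitude_spec(target_altitude, base_altitude = scene$altitude,
                        base_gsd = scene$gsd)
  if (target_altitude == scene$altitude) return(scene)
  resample_nearest(scene, gsd_for_altitude(spec, rounded = FALSE),
                   altitude = target_altitude)
}
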