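#' Parameters of the synthetic canopy forward model
#'
#' The scene renderer is a deliberately simple, monotone forward model: within
#' each plot, pixels belong to vegetation rows (25 cm period stripes whose
#' width scales with canopy cover) or to exposed soil. A vegetation pixel in
#' band b takes the leaf reflectance `a_b * exp(-SPAD / k_b) + c_b`, so red
#' and green reflectance decrease with chlorophyll while NIR is dominated by
#' the `c_b` term; soil pixels take the fixed soil spectrum (brighter in red
#' than vegetation, reproducing the soil-exposure confound at coarse
#' resolutions). Canopy cover increases with nitrogen rate as
#' `cover_base + cover_gain * N / (N + cover_half)`. Gaussian per-pixel noise
#' is added per band and values are clipped to `[0, 1]`.
#'
#' @param base_gsd Ground sampling distance, cm/pixel, at the 20 m reference
#'   altitude (default 1.06).
#' @param soil_spectrum Named soil reflectance per band, in `[0,1]`.
#' @param leaf_a,leaf_k,leaf_c Named per-band coefficients of the exponential
#'   leaf model (`leaf_k` in SPAD units).
#' @param cover_base,cover_gain,cover_half Canopy-cover response to nitrogen
#'   rate (fractions; `cover_half` in kg/ha).
#' @param noise_sd Named per-band SD of additive reflectance noise.
#' @param seed Integer seed for the pixel noise.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(base_gsd = 1.06,
                         soil_spectrum = c(B = 0.10, G = 0.16, R = 0.22,
                                           RE = 0.26, NIR = 0.30),
                         leaf_a = c(B = 0.12, G = 0.25, R = 0.30,
                                    RE = 0.35, NIR = -0.08),
                         leaf_k = c(B = 30, G = 35, R = 25,
                                    RE = 45, NIR = 40),
                         leaf_c = c(B = 0.03, G = 0.06, R = 0.03,
                                    RE = 0.12, NIR = 0.50),
                         cover_base = 0.55, cover_gain = 0.40,
                         cover_half = 120,
                         noise_sd = c(B = 0.01, G = 0.01, R = 0.01,
                                      RE = 0.01, NIR = 0.01),
                         seed = 1) {
  if (base_gsd <= 0) stop("base_gsd must be > 0", call. = FALSE)
  for (nm in list(soil_spectrum, leaf_a, leaf_k, leaf_c, noise_sd)) {
    if (!all(BAND_NAMES %in% names(nm))) {
      stop("per-band parameters must be named with ", paste(BAND_NAMES, collapse = ", "),
           call. = FALSE)
    }
  }
  if (any(soil_spectrum < 0 | soil_spectrum > 1)) {
    stop("soil reflectances must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(base_gsd = base_gsd, soil_spectrum = soil_spectrum,
         leaf_a = leaf_a, leaf_k = leaf_k, leaf_c = leaf_c,
         cover_base = cover_base, cover_gain = cover_gain,
         cover_half = cover_half, noise_sd = noise_sd, seed = seed),
    class = "scene_params"
  )
}

#' Leaf reflectance implied by the forward model
#'
#' @param spad SPAD value(s).
#' @param params A [scene_params()].
#' @return Matrix with one row per `spad` value and one column per band.
#' @export
leaf_reflectance <- function(spad, params = scene_params()) {
  out <- sapply(BAND_NAMES, function(b) {
    params$leaf_a[[b]] * exp(-spad / params$leaf_k[[b]]) + params$leaf_c[[b]]
  })
  m <- matrix(out, nrow = length(spad), ncol = length(BAND_NAMES),
              dimnames = list(NULL, BAND_NAMES))
  pmin(pmax(m, 0), 1)
}

canopy_cover <- function(n_rate, params) {
  pmin(pmax(params$cover_base +
              params$cover_gain * n_rate / (n_rate + params$cover_half), 0), 1)
}

#' Construct a multiband scene object
#'
#' @param bands Named list of numeric reflectance matrices (B, G, R, RE, NIR),
#'   all sharing dimensions, values in `[0,1]`.
#' @param mask Integer matrix of the same dimensions; 0 = background,
#'   k = plot k.
#' @param gsd Ground sampling distance, cm/pixel.
#' @param altitude Nominal flight altitude, meters.
#' @return An object of class `multiband_scene`.
#' @export
multiband_scene <- function(bands, mask, gsd, altitude = 20) {
  if (!all(BAND_NAMES %in% names(bands))) {
    stop("bands must be named ", paste(BAND_NAMES, collapse = ", "), call. = FALSE)
  }
  dims <- dim(bands[[1L]])
  for (b in BAND_NAMES) {
    if (!identical(dim(bands[[b]]), dims)) {
      stop("all band rasters must share dimensions", call. = FALSE)
    }
  }
  if (!identical(dim(mask), dims)) {
    stop("mask must share the band raster dimensions", call. = FALSE)
  }
  if (gsd <= 0) stop("gsd must be > 0", call. = FALSE)
  structure(
    list(bands = bands[BAND_NAMES], mask = mask, gsd = gsd, altitude = altitude),
    class = "multiband_scene"
  )
}

#' @export
print.multiband_scene <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "multiband_scene: %d x %d pixels, 5 bands (%s)\n  gsd %.4f cm/pixel, altitude %g m, %d plots\n",
    d[1], d[2], paste(BAND_NAMES, collapse = ","), x$gsd, x$altitude,
    length(setdiff(unique(as.vector(x$mask)), 0L))
  ))
  invisible(x)
}

#' Render a multispectral canopy scene from the design and true SPAD
#'
#' Rasterizes every plot at the base ground sampling distance, fills it with
#' the 25 cm row-stripe vegetation pattern (stripe width set by the plot's
#' nitrogen-driven canopy cover), assigns leaf reflectance from the plot's
#' true SPAD via the exponential forward model, soil reflectance elsewhere,
#' adds per-band Gaussian pixel noise and clips to `[0, 1]`. The integer mask
#' labels every pixel of a plot's footprint (vegetation and soil alike) with
#' its `plot_id`.
#'
#' @param design Output of [generate_design()].
#' @param spad_table A table with `plot_id` and `spad_true` columns.
#' @param params A [scene_params()].
#' @return A [multiband_scene()] at `params$base_gsd` and 20 m altitude.
#' @export
render_scene <- function(design, spad_table, params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  spad <- spad_table$spad_true[match(design$plot_id, spad_table$plot_id)]
  if (anyNA(spad)) stop("spad_table is missing plots present in design", call. = FALSE)
  g <- params$base_gsd / 100  # meters per pixel
  width_m <- max(design$origin_x_m + design$plot_width_m) +
    (attr(design, "alley_m") %||% 0.5)
  height_m <- max(design$origin_y_m + design$plot_height_m) +
    (attr(design, "alley_m") %||% 0.5)
  nc <- floor(width_m / g)
  nr <- floor(height_m / g)

  # plot pixel extents: pixels whose centers fall inside the plot rectangle
  col0 <- floor(design$origin_x_m / g + 0.5) + 1L
  col1 <- floor((design$origin_x_m + design$plot_width_m) / g + 0.5)
  row0 <- floor(design$origin_y_m / g + 0.5) + 1L
  row1 <- floor((design$origin_y_m + design$plot_height_m) / g + 0.5)
  if (any(col1 - col0 < 6L) || any(row1 - row0 < 6L)) {
    stop("plot too small for a 7x7 texture window at this base_gsd", call. = FALSE)
  }

  mask <- matrix(0L, nr, nc)
  leaf <- leaf_reflectance(spad, params)
  cover <- canopy_cover(design$nitrogen_rate, params)
  bands <- lapply(BAND_NAMES, function(b) {
    matrix(params$soil_spectrum[[b]], nr, nc)
  })
  names(bands) <- BAND_NAMES

  for (i in seq_len(nrow(design))) {
    rows <- row0[i]:row1[i]
    cols <- col0[i]:col1[i]
    mask[rows, cols] <- design$plot_id[i]
    # row stripes run along x; phase over y with 25 cm period
    y_centers <- (rows - 0.5) * g - design$origin_y_m[i]
    phase <- y_centers %% design$row_spacing_m[i]
    veg_rows <- rows[phase < cover[i] * design$row_spacing_m[i]]
    if (length(veg_rows)) {
      for (b in BAND_NAMES) bands[[b]][veg_rows, cols] <- leaf[i, b]
    }
  }

  bands <- with_local_seed(params$seed, {
    lapply(BAND_NAMES, function(b) {
      v <- bands[[b]]
      if (params$noise_sd[[b]] > 0) {
        v <- v + matrix(rnorm(nr * nc, 0, params$noise_sd[[b]]), nr, nc)
      }
      pmin(pmax(v, 0), 1)
    })
  })
  names(bands) <- BAND_NAMES
  multiband_scene(bands, mask, gsd = params$base_gsd, altitude = 20)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
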