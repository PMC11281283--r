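#' Write a scene to multiband TIFF (plus mask and metadata sidecars)
#'
#' Bands are written in the order B, G, R, RE, NIR as the pages of a
#' multi-page 32-bit float TIFF at `<path>`, the integer plot mask to
#' `<path base>_mask.tif` (16-bit), and the grid metadata (gsd, altitude,
#' band order) to `<path base>.json`. Reflectance is stored as-is in
#' `[0, 1]`.
#'
#' @param scene A [multiband_scene()].
#' @param path Output TIFF path (e.g. `"scene.tif"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scene_tiff <- function(scene, path) {
  stopifnot(inherits(scene, "multiband_scene"))
  base <- sub("\\.tiff?$", "", path)
  tiff::writeTIFF(unname(scene$bands[BAND_NAMES]), path,
                  bits.per.sample = 32L, reduce = FALSE)
  mask_path <- paste0(base, "_mask.tif")
  # writeTIFF stores [0,1]; mask labels are scaled by the 16-bit range
  tiff::writeTIFF(scene$mask / 65535, mask_path, bits.per.sample = 16L)
  meta_path <- paste0(base, ".json")
  jsonlite::write_json(
    list(gsd = scene$gsd, altitude = scene$altitude, bands = BAND_NAMES,
         dim = dim(scene$mask)),
    meta_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(scene = path, mask = mask_path, meta = meta_path))
}

#' Read a scene written by [write_scene_tiff()]
#'
#' @param path Path to the multiband TIFF.
#' @return A [multiband_scene()].
#' @export
read_scene_tiff <- function(path) {
  base <- sub("\\.tiff?$", "", path)
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  bands <- setNames(pages[seq_along(BAND_NAMES)], meta$bands)
  mask <- round(tiff::readTIFF(paste0(base, "_mask.tif")) * 65535)
  storage.mode(mask) <- "integer"
  multiband_scene(bands, mask, gsd = meta$gsd, altitude = meta$altitude)
}
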