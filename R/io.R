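#' Read and write grayscale TIFF images
#'
#' Thin wrappers mapping between the package's numeric matrices (row =
#' image row) and 16-bit grayscale TIFF files.
#'
#' @param path file path.
#' @param img numeric matrix with values in `[0, 1]`.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' @rdname read_image_tiff
#' @export
write_image_tiff <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read and write field specifications as JSON
#'
#' @param spec a [field_spec()].
#' @param path JSON path.
#' @export
write_field_spec <- function(spec, path) {
  jsonlite::write_json(
    list(shape = spec$shape, pixel_size_um = spec$pixel_size,
         phi0 = spec$phi0, confine_radius_um = spec$confine_radius,
         defects = spec$defects),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_field_spec
#' @export
read_field_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  defects <- if (is.null(j$defects) || length(j$defects) == 0) NULL else
    as.data.frame(j$defects)
  field_spec(j$shape, j$pixel_size_um, j$phi0, defects,
             confine_radius = j$confine_radius_um)
}
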