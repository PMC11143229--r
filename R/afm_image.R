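#' AFM height images
#'
#' A height map in nanometres on a square pixel grid, with the pixel size
#' carried as metadata. Maps must be at least 64 x 64 pixels with finite
#' heights.
#'
#' @param height_map numeric matrix, heights in nm.
#' @param pixel_nm pixel size in nm/pixel (> 0).
#' @param metadata optional named list (ribbon geometry, generator
#'   provenance, ...).
#' @return Object of class `snf_afm_image`.
#' @export
afm_image <- function(height_map, pixel_nm, metadata = list()) {
  height_map <- as.matrix(height_map)
  if (!is.numeric(height_map) || any(!is.finite(height_map)))
    snf_abort("height map must be a finite numeric matrix", "nonfinite")
  if (nrow(height_map) < 64 || ncol(height_map) < 64)
    snf_abort("height map must be at least 64 x 64 pixels", "degenerate_input")
  if (!is.numeric(pixel_nm) || pixel_nm <= 0)
    snf_abort("pixel size must be positive", "domain")
  structure(list(map = height_map, pixel_nm = pixel_nm, metadata = metadata),
            class = "snf_afm_image")
}

#' @export
print.snf_afm_image <- function(x, ...) {
  cat(sprintf("<snf_afm_image: %d x %d px, %.3g nm/px, heights %.2f-%.2f nm>\n",
              nrow(x$map), ncol(x$map), x$pixel_nm, min(x$map), max(x$map)))
  invisible(x)
}

#' Read / write AFM height images
#'
#' Two interchangeable on-disk forms are supported, each with a JSON
#' sidecar `<path>.json` recording `pixel_nm` (and, for TIFF, the linear
#' `offset`/`scale` mapping the stored \[0, 1\] floats back to nm):
#'
#' * `.tif` / `.tiff`: 32-bit float TIFF.
#' * anything else: whitespace-delimited text matrix of heights in nm.
#'
#' @param path file path.
#' @return [read_afm_image()] returns a `snf_afm_image`.
#' @export
read_afm_image <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    snf_abort("missing JSON sidecar with pixel size", "format")
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    m <- tiff::readTIFF(path)
    m <- m * side$scale + side$offset
  } else {
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
  }
  meta <- side[setdiff(names(side), c("pixel_nm", "scale", "offset"))]
  afm_image(m, side$pixel_nm, metadata = meta)
}

#' @rdname read_afm_image
#' @param img image to write.
#' @export
write_afm_image <- function(img, path) {
  stopifnot(inherits(img, "snf_afm_image"))
  side <- c(list(pixel_nm = img$pixel_nm), img$metadata)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    lo <- min(img$map); hi <- max(img$map)
    scale <- max(hi - lo, 1e-12)
    tiff::writeTIFF((img$map - lo) / scale, path, bits.per.sample = 32,
                    compression = "none")
    side$offset <- lo
    side$scale <- scale
  } else {
    utils::write.table(format(img$map, digits = 8), path,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
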