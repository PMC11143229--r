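#' Spectrum objects
#'
#' A spectrum couples a strictly increasing wavenumber grid (cm^-1) with
#' dimensionless values and a kind tag identifying what the values are:
#' raw gated transmittance (`"transmittance"`, values in (0, 1]), extinction
#' (`"extinction"`, 1 - T_VG/T0, values < 1), or baseline-subtracted
#' Delta-Extinction (`"delta_extinction"`), the observable the amide-I
#' deconvolution consumes.
#'
#' @param wavenumbers numeric, strictly increasing wavenumber grid in cm^-1.
#' @param values numeric, same length as `wavenumbers`, all finite.
#' @param kind one of `"transmittance"`, `"extinction"`, `"delta_extinction"`.
#' @return An object of class `snf_spectrum`.
#' @examples
#' s <- spectrum(seq(1400, 1800), rep(0.9, 401), kind = "transmittance")
#' range(s$wavenumbers)
#' @export
spectrum <- function(wavenumbers, values,
                     kind = c("extinction", "transmittance", "delta_extinction")) {
  kind <- match.arg(kind)
  wavenumbers <- as.numeric(wavenumbers)
  values <- as.numeric(values)
  if (length(wavenumbers) != length(values))
    snf_abort("wavenumbers and values differ in length", "length_mismatch")
  if (length(wavenumbers) < 2)
    snf_abort("a spectrum needs at least two grid points", "degenerate_input")
  if (any(!is.finite(wavenumbers)) || any(!is.finite(values)))
    snf_abort("non-finite wavenumbers or values", "nonfinite")
  if (any(diff(wavenumbers) <= 0))
    snf_abort("wavenumber grid must be strictly increasing", "grid_order")
  if (kind == "transmittance" && any(values <= 0 | values > 1))
    snf_abort("transmittance values must lie in (0, 1]", "domain")
  if (kind == "extinction" && any(values >= 1))
    snf_abort("extinction values must be < 1", "domain")
  structure(list(wavenumbers = wavenumbers, values = values, kind = kind),
            class = "snf_spectrum")
}

#' @export
print.snf_spectrum <- function(x, ...) {
  cat(sprintf("<snf_spectrum: %s, %d points, %.1f-%.1f cm-1>\n",
              x$kind, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' @export
length.snf_spectrum <- function(x) length(x$wavenumbers)

same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavenumbers) == length(b$wavenumbers) &&
    all(abs(a$wavenumbers - b$wavenumbers) <= tol)
}

#' Extinction from gated transmittance
#'
#' Extinction = 1 - T_VG / T0, where T_VG is the transmittance at the probe
#' gate voltage and T0 the transmittance at the charge-neutral point. This
#' is the spectroscopic contrast of the gated graphene sensor; vibrational
#' features of adsorbed protein appear as dips on the plasmon peak.
#'
#' @param t_vg transmittance spectrum at the measurement gate voltage.
#' @param t_0 transmittance spectrum at the charge-neutral point; must share
#'   the exact wavenumber grid of `t_vg` and be strictly positive.
#' @return An extinction `snf_spectrum`.
#' @examples
#' wn <- seq(1400, 1800, by = 2)
#' e <- extinction_from_transmittance(
#'   spectrum(wn, rep(0.95, length(wn)), "transmittance"),
#'   spectrum(wn, rep(1.00, length(wn)), "transmittance"))
#' unique(e$values)
#' @export
extinction_from_transmittance <- function(t_vg, t_0) {
  stopifnot(inherits(t_vg, "snf_spectrum"), inherits(t_0, "snf_spectrum"))
  if (!same_grid(t_vg, t_0))
    snf_abort("T_VG and T_0 are not on the same wavenumber grid", "grid_mismatch")
  if (any(t_0$values <= 0))
    snf_abort("T_0 must be strictly positive", "domain")
  spectrum(t_vg$wavenumbers, 1 - t_vg$values / t_0$values, "extinction")
}

#' Amide I window
#'
#' The amide I band of the protein backbone spans 1600-1700 cm^-1; its line
#' shape encodes secondary structure.
#' @param lo,hi window bounds in cm^-1 (inclusive).
#' @return list with `lo`, `hi`.
#' @export
amide_window <- function(lo = 1600, hi = 1700) {
  if (!(lo < hi)) snf_abort("window lo must be < hi", "domain")
  list(lo = lo, hi = hi)
}

#' Restrict a Delta-Extinction spectrum to the amide I window
#'
#' Keeps grid points with lo <= wavenumber <= hi (both endpoints included).
#'
#' @param dspec a `snf_spectrum` (normally kind `delta_extinction`).
#' @param window an [amide_window()].
#' @return The sliced spectrum, same kind.
#' @export
window_amide_I <- function(dspec, window = amide_window()) {
  stopifnot(inherits(dspec, "snf_spectrum"))
  wn <- dspec$wavenumbers
  if (window$lo < min(wn) || window$hi > max(wn))
    snf_abort(sprintf("window [%g, %g] not fully covered by grid [%g, %g]",
                      window$lo, window$hi, min(wn), max(wn)), "range")
  keep <- wn >= window$lo & wn <= window$hi
  spectrum(wn[keep], dspec$values[keep], dspec$kind)
}

#' Align a spectrum onto a reference grid by linear interpolation
#'
#' Grid alignment is kept out of the arithmetic operations on purpose: those
#' demand identical grids, and any resampling is done explicitly here.
#'
#' @param spec spectrum to resample.
#' @param grid target wavenumber grid (must lie inside the spectrum range).
#' @return Resampled `snf_spectrum` of the same kind.
#' @export
align_spectrum <- function(spec, grid) {
  stopifnot(inherits(spec, "snf_spectrum"))
  grid <- as.numeric(grid)
  if (min(grid) < min(spec$wavenumbers) || max(grid) > max(spec$wavenumbers))
    snf_abort("target grid extends beyond the spectrum range", "range")
  v <- stats::approx(spec$wavenumbers, spec$values, xout = grid)$y
  spectrum(grid, v, spec$kind)
}

#' Read / write two-column spectrum CSV
#'
#' The on-disk format is a UTF-8 CSV with header `wavenumber_cm-1,<kind>`
#' where `<kind>` is `transmittance`, `extinction` or `delta_extinction`,
#' rows in ascending wavenumber. [write_spectrum_csv()] also writes a JSON
#' sidecar `<path>.json` recording the kind tag and any provenance supplied.
#'
#' @param path CSV file path.
#' @return [read_spectrum_csv()] returns a `snf_spectrum`.
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (ncol(d) != 2 || names(d)[1] != "wavenumber_cm-1")
    snf_abort("expected two columns with first header 'wavenumber_cm-1'", "format")
  kind <- names(d)[2]
  if (!kind %in% c("transmittance", "extinction", "delta_extinction"))
    snf_abort(sprintf("unknown spectrum kind column '%s'", kind), "format")
  spectrum(d[[1]], d[[2]], kind)
}

#' @rdname read_spectrum_csv
#' @param spec spectrum to write.
#' @param provenance optional named list stored in the JSON sidecar.
#' @export
write_spectrum_csv <- function(spec, path, provenance = list()) {
  stopifnot(inherits(spec, "snf_spectrum"))
  d <- data.frame(a = spec$wavenumbers, b = spec$values)
  names(d) <- c("wavenumber_cm-1", spec$kind)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  side <- c(list(kind = spec$kind, n_points = length(spec$wavenumbers)),
            provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
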