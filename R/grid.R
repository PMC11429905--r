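#' Wavelength grid for synchronous fluorescence scans
#'
#' The acquisition grid used throughout the package: excitation wavelengths
#' from `start_nm` to `end_nm` in steps of `step_nm`. The study default is
#' 250-550 nm at 0.5 nm, i.e. 601 points; zone definitions index this axis.
#'
#' @param start_nm First wavelength (nm).
#' @param end_nm Last wavelength (nm), must exceed `start_nm`.
#' @param step_nm Positive step; `(end_nm - start_nm) / step_nm` must be an
#'   integer so the grid closes exactly on `end_nm`.
#' @return An object of class `wavelength_grid`.
#' @examples
#' g <- wavelength_grid()
#' length(grid_points(g)) # 601
#' @export
wavelength_grid <- function(start_nm = 250, end_nm = 550, step_nm = 0.5) {
  stopifnot(is.numeric(start_nm), is.numeric(end_nm), is.numeric(step_nm))
  if (start_nm >= end_nm) stop("wavelength_grid: start_nm must be < end_nm")
  if (step_nm <= 0) stop("wavelength_grid: step_nm must be > 0")
  n_steps <- (end_nm - start_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-8)
    stop("wavelength_grid: (end_nm - start_nm) / step_nm must be an integer")
  structure(
    list(start_nm = start_nm, end_nm = end_nm, step_nm = step_nm,
         n = as.integer(round(n_steps)) + 1L),
    class = "wavelength_grid"
  )
}

#' Grid wavelengths as a numeric vector
#' @param grid A `wavelength_grid`.
#' @return Strictly increasing numeric vector of wavelengths (nm).
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  seq(grid$start_nm, grid$end_nm, by = grid$step_nm)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm (%d points)\n",
              x$start_nm, x$end_nm, x$step_nm, x$n))
  invisible(x)
}

#' One synchronous fluorescence spectrum
#'
#' A single sample's synchronous scan (fixed excitation-emission offset,
#' here 30 nm) on a [wavelength_grid()]. Intensities are in arbitrary
#' fluorescence units and must be finite and nonnegative.
#'
#' @param sample_id Sample identifier.
#' @param intensities Numeric vector, one value per grid point.
#' @param grid A `wavelength_grid` (default: study grid).
#' @param delta_lambda_nm Synchronous offset in nm (study value 30).
#' @param dilution_factor Dilution of the measured aliquot (1 = undiluted).
#' @param clip_negative If `TRUE`, negative intensities (instrument baseline
#'   artifacts) are clipped to 0 with a logged warning instead of erroring.
#' @return An object of class `syn_spectrum`.
#' @export
syn_spectrum <- function(sample_id, intensities, grid = wavelength_grid(),
                         delta_lambda_nm = 30, dilution_factor = 1,
                         clip_negative = FALSE) {
  stopifnot(inherits(grid, "wavelength_grid"))
  intensities <- as.numeric(intensities)
  if (length(intensities) != grid$n)
    stop(sprintf("syn_spectrum '%s': %d intensities for a %d-point grid",
                 sample_id, length(intensities), grid$n))
  if (any(!is.finite(intensities)))
    stop(sprintf("syn_spectrum '%s': non-finite intensities", sample_id))
  if (any(intensities < 0)) {
    if (!clip_negative)
      stop(sprintf("syn_spectrum '%s': negative intensities", sample_id))
    utfmp_log("spectra_io", sprintf(
      "clipped %d negative intensities to 0 for sample '%s'",
      sum(intensities < 0), sample_id))
    intensities <- pmax(intensities, 0)
  }
  if (!is.numeric(dilution_factor) || dilution_factor <= 0)
    stop("syn_spectrum: dilution_factor must be a positive number")
  structure(
    list(sample_id = as.character(sample_id), grid = grid,
         intensities = intensities, delta_lambda_nm = delta_lambda_nm,
         dilution_factor = dilution_factor),
    class = "syn_spectrum"
  )
}

#' @export
print.syn_spectrum <- function(x, ...) {
  cat(sprintf("<syn_spectrum> '%s' (dilution %gx), %d points, max %.1f a.u.\n",
              x$sample_id, x$dilution_factor, x$grid$n, max(x$intensities)))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$start_nm, b$start_nm)) &&
    isTRUE(all.equal(a$end_nm, b$end_nm)) &&
    isTRUE(all.equal(a$step_nm, b$step_nm))
}
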