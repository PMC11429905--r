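#' Savitzky-Golay smoothing configuration
#'
#' Defaults match the study protocol: window of 11 grid points (5.5 nm on the
#' 0.5 nm grid) and cubic local polynomials. The window must be odd and
#' strictly wider than the polynomial order.
#'
#' @param window_length Odd window length in grid points.
#' @param poly_order Local polynomial order.
#' @export
smoothing_config <- function(window_length = 11, poly_order = 3) {
  if (window_length %% 2 != 1) stop("smoothing_config: window_length must be odd")
  if (poly_order >= window_length)
    stop("smoothing_config: poly_order must be < window_length")
  structure(list(window_length = as.integer(window_length),
                 poly_order = as.integer(poly_order)),
            class = "smoothing_config")
}

#' Smooth a spectrum with a Savitzky-Golay filter
#'
#' Local least-squares polynomial smoothing (window 11, order 3 by default).
#' Interior points use the symmetric convolution kernel; the first and last
#' half-windows are fitted by least squares on the truncated edge window, so
#' output length equals input length. The filter is linear and reproduces any
#' polynomial up to `poly_order` exactly at interior points.
#'
#' @param spectrum A [syn_spectrum()] (or bare numeric vector).
#' @param cfg A [smoothing_config()].
#' @return Object of the same type with smoothed intensities, clipped at 0
#'   for spectra (smoothing can undershoot near sharp features).
#' @export
savgol_smooth <- function(spectrum, cfg = smoothing_config()) {
  stopifnot(inherits(cfg, "smoothing_config"))
  x <- if (inherits(spectrum, "syn_spectrum")) spectrum$intensities else as.numeric(spectrum)
  if (length(x) < cfg$window_length)
    stop("savgol_smooth: spectrum shorter than the smoothing window")
  y <- signal::sgolayfilt(x, p = cfg$poly_order, n = cfg$window_length)
  if (inherits(spectrum, "syn_spectrum")) {
    out <- spectrum
    out$intensities <- pmax(y, 0)
    out
  } else y
}

#' Fluorescent zone scheme
#'
#' Ordered, non-overlapping half-open wavelength intervals `[start, end)`
#' partitioning 250-500 nm on the excitation axis, named after the dominant
#' fluorophore families: Z1a/Z1b indole derivatives and catecholamine
#' metabolites (250-300), Z2 5-HIAA (300-325), Z3 3-HAA (325-345), Z4a/Z4b
#' NADH-like metabolites (345-380), Z5 xanthurenic acid (380-410), Z6
#' kynurenine/xanthopterin (410-450), Z7 flavins/FAD (450-500).
#'
#' Only the parent ranges of zones 1 and 4 are established; the sub-zone
#' splits default to even halves of the parent range (Z1a/Z1b at 275 nm,
#' Z4a/Z4b at 362.5 nm) and are configurable.
#'
#' @param z1_split,z4_split Interior split points for the two parent zones.
#' @return Object of class `zone_scheme`: a data.frame with `zone`, `start_nm`,
#'   `end_nm`.
#' @export
zone_scheme <- function(z1_split = 275, z4_split = 362.5) {
  if (!(z1_split > 250 && z1_split < 300))
    stop("zone_scheme: z1_split must lie inside (250, 300)")
  if (!(z4_split > 345 && z4_split < 380))
    stop("zone_scheme: z4_split must lie inside (345, 380)")
  df <- data.frame(
    zone = c("Z1a", "Z1b", "Z2", "Z3", "Z4a", "Z4b", "Z5", "Z6", "Z7"),
    start_nm = c(250, z1_split, 300, 325, 345, z4_split, 380, 410, 450),
    end_nm = c(z1_split, 300, 325, 345, z4_split, 380, 410, 450, 500),
    stringsAsFactors = FALSE
  )
  class(df) <- c("zone_scheme", "data.frame")
  validate_zone_scheme(df)
}

validate_zone_scheme <- function(scheme) {
  if (!identical(scheme$zone, c("Z1a", "Z1b", "Z2", "Z3", "Z4a", "Z4b", "Z5", "Z6", "Z7")))
    stop("zone_scheme: zone names must be Z1a...Z7 in order")
  if (any(scheme$end_nm <= scheme$start_nm))
    stop("zone_scheme: coverage error - empty or inverted interval")
  if (any(scheme$start_nm[-1] != scheme$end_nm[-nrow(scheme)]))
    stop("zone_scheme: intervals must be contiguous")
  if (scheme$start_nm[1] < 250 || scheme$end_nm[nrow(scheme)] > 500)
    stop("zone_scheme: intervals must lie within 250-500 nm")
  scheme
}

#' Construct a urinary total fluorescent metabolome profile (uTFMP)
#'
#' Builds the per-sample profile from one or more dilutions of the same
#' sample. Each dilution is Savitzky-Golay smoothed first. With
#' `construction = "max_over_dilutions"` (default) the profile is the
#' per-wavelength maximum across the series, capturing each fluorophore at
#' the dilution where it is least quenched; `"single_dilution"` returns the
#' smoothed spectrum at `dilution` (for sensitivity analysis).
#'
#' @param series List of [syn_spectrum()] objects, all for one sample on one
#'   grid.
#' @param cfg A [smoothing_config()].
#' @param construction `"max_over_dilutions"` or `"single_dilution"`.
#' @param dilution Requested factor when `construction = "single_dilution"`.
#' @return Object of class `utfmp_profile` with fields `sample_id`, `grid`,
#'   `intensities`, `construction`.
#' @export
build_utfmp <- function(series, cfg = smoothing_config(),
                        construction = c("max_over_dilutions", "single_dilution"),
                        dilution = 1) {
  construction <- match.arg(construction)
  if (inherits(series, "syn_spectrum")) series <- list(series)
  if (length(series) == 0) stop("build_utfmp: empty series")
  ids <- unique(vapply(series, function(s) s$sample_id, character(1)))
  if (length(ids) != 1)
    stop(sprintf("build_utfmp: integrity error - mixed sample ids (%s)",
                 paste(ids, collapse = ", ")))
  grid <- series[[1]]$grid
  for (s in series) if (!same_grid(s$grid, grid))
    stop("build_utfmp: integrity error - mixed grids")
  smoothed <- lapply(series, savgol_smooth, cfg = cfg)
  if (construction == "single_dilution") {
    hit <- which(vapply(smoothed, function(s)
      isTRUE(all.equal(s$dilution_factor, dilution)), logical(1)))
    if (!length(hit))
      stop(sprintf("build_utfmp: lookup error - dilution %g not in series", dilution))
    intens <- smoothed[[hit[1]]]$intensities
  } else {
    intens <- do.call(pmax, lapply(smoothed, function(s) s$intensities))
  }
  structure(list(sample_id = ids, grid = grid, intensities = intens,
                 construction = construction),
            class = "utfmp_profile")
}

#' @export
print.utfmp_profile <- function(x, ...) {
  cat(sprintf("<utfmp_profile> '%s' (%s), %d points, max %.1f a.u.\n",
              x$sample_id, x$construction, x$grid$n, max(x$intensities)))
  invisible(x)
}

zone_index <- function(grid, start_nm, end_nm) {
  wl <- grid_points(grid)
  idx <- which(wl >= start_nm - 1e-9 & wl < end_nm - 1e-9)
  if (!length(idx))
    stop(sprintf("segment_zones: coverage error - no grid points in [%g, %g)",
                 start_nm, end_nm))
  idx
}

#' Segment a uTFMP into fluorescent zones
#'
#' Splits a profile into the nine zone sub-vectors. Intervals are half-open
#' `[start, end)`, so the concatenation over Z1a...Z7 covers `[250, 500)` with
#' no gaps or double-counted boundary wavelengths.
#'
#' @param profile A `utfmp_profile` (or [syn_spectrum()]).
#' @param scheme A [zone_scheme()].
#' @return Named list of numeric intensity sub-vectors, wavelengths as names.
#' @export
segment_zones <- function(profile, scheme = zone_scheme()) {
  validate_zone_scheme(scheme)
  grid <- profile$grid
  wl <- grid_points(grid)
  if (scheme$start_nm[1] < min(wl) - 1e-9 || scheme$end_nm[nrow(scheme)] > max(wl) + 1e-9)
    stop("segment_zones: coverage error - scheme outside the grid")
  out <- lapply(seq_len(nrow(scheme)), function(i) {
    idx <- zone_index(grid, scheme$start_nm[i], scheme$end_nm[i])
    setNames(profile$intensities[idx], wl[idx])
  })
  names(out) <- scheme$zone
  out
}
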