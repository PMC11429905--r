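#' Read a cohort of synchronous fluorescence spectra from CSV
#'
#' Canonical format is wide: a `wavelength_nm` column followed by one column
#' per sample. Long format (`sample_id`, `wavelength_nm`, `intensity`) is also
#' accepted. A dilution series is encoded by suffixing the column name (or
#' long-format id) as `sampleid@factor`; absence of a suffix means the
#' undiluted aliquot (factor 1). Spectra sampled on a different wavelength
#' axis are linearly interpolated onto `grid`, provided they cover it.
#' Negative intensities are clipped to 0 with a logged warning.
#'
#' @param path CSV file path.
#' @param grid Target [wavelength_grid()].
#' @param delta_lambda_nm Synchronous offset recorded on each spectrum.
#' @return List of [syn_spectrum()] objects.
#' @export
read_spectra <- function(path, grid = wavelength_grid(), delta_lambda_nm = 30) {
  if (!file.exists(path)) stop(sprintf("read_spectra: no such file '%s'", path))
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("read_spectra: empty file")
  nm <- names(raw)
  if (all(c("sample_id", "wavelength_nm", "intensity") %in% nm)) {
    # long format -> pivot to wide
    wide <- split(raw, raw$sample_id)
    wl <- sort(unique(raw$wavelength_nm))
    mat <- sapply(wide, function(d) d$intensity[order(d$wavelength_nm)])
    raw <- data.frame(wavelength_nm = wl, mat, check.names = FALSE)
    nm <- names(raw)
  }
  if (nm[1] != "wavelength_nm")
    stop("read_spectra: format error - first column must be 'wavelength_nm'")
  if (ncol(raw) < 2) stop("read_spectra: no sample columns")
  for (j in seq_along(raw)) {
    if (!is.numeric(raw[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[j]]))) & !is.na(raw[[j]]))
      stop(sprintf("read_spectra: parse error - non-numeric cell in column '%s', row %d",
                   nm[j], if (length(bad)) bad[1] else NA_integer_))
    }
  }
  wl_in <- raw$wavelength_nm
  if (anyDuplicated(wl_in)) stop("read_spectra: duplicated wavelengths")
  target <- grid_points(grid)
  if (min(wl_in) > min(target) + 1e-9 || max(wl_in) < max(target) - 1e-9)
    stop(sprintf(
      "read_spectra: coverage error - file spans %g-%g nm, grid needs %g-%g nm",
      min(wl_in), max(wl_in), min(target), max(target)))
  ids <- nm[-1]
  if (anyDuplicated(ids)) stop("read_spectra: duplicated sample columns")
  on_grid <- length(wl_in) == length(target) &&
    max(abs(sort(wl_in) - target)) < 1e-9
  ord <- order(wl_in)
  lapply(ids, function(id) {
    parsed <- parse_dilution_id(id)
    y <- raw[[id]]
    if (!on_grid) {
      y <- approx(wl_in[ord], y[ord], xout = target, method = "linear")$y
      utfmp_log("spectra_io",
                sprintf("interpolated '%s' onto the %d-point grid", id, grid$n))
    }
    syn_spectrum(parsed$sample_id, y, grid = grid,
                 delta_lambda_nm = delta_lambda_nm,
                 dilution_factor = parsed$dilution, clip_negative = TRUE)
  })
}

parse_dilution_id <- function(id) {
  if (grepl("@", id, fixed = TRUE)) {
    parts <- strsplit(id, "@", fixed = TRUE)[[1]]
    if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2]))))
      stop(sprintf("read_spectra: malformed dilution id '%s'", id))
    list(sample_id = parts[1], dilution = as.numeric(parts[2]))
  } else {
    list(sample_id = id, dilution = 1)
  }
}

#' Write a cohort of spectra to wide CSV
#'
#' Inverse of [read_spectra()]; dilution factors other than 1 are encoded as
#' `sampleid@factor` column names.
#'
#' @param spectra List of [syn_spectrum()] objects sharing one grid.
#' @param path Output CSV path.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(length(spectra) > 0)
  grid <- spectra[[1]]$grid
  for (s in spectra) {
    if (!inherits(s, "syn_spectrum")) stop("write_spectra: not a syn_spectrum")
    if (!same_grid(s$grid, grid)) stop("write_spectra: mixed grids")
  }
  cols <- lapply(spectra, function(s) s$intensities)
  names(cols) <- vapply(spectra, function(s) {
    if (s$dilution_factor == 1) s$sample_id
    else sprintf("%s@%g", s$sample_id, s$dilution_factor)
  }, character(1))
  if (anyDuplicated(names(cols))) stop("write_spectra: duplicate sample ids")
  df <- data.frame(wavelength_nm = grid_points(grid), cols, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate sample metadata
#'
#' Expects a CSV with at least `sample_id` and `group` columns; `group` must
#' be one of control / benign / malignant. Optional columns: `age_years`
#' (validated to 18-100) and the ten urine strip parameters (pH validated to
#' 4.5-9 when present).
#'
#' @param path CSV file path.
#' @return A `data.frame` with one validated row per sample; group is a factor
#'   with levels control, benign, malignant.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_metadata: no such file '%s'", path))
  md <- read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  if (!all(c("sample_id", "group") %in% names(md)))
    stop("metadata: header must contain 'sample_id' and 'group'")
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id))
    stop(sprintf("metadata: integrity error - duplicate sample_id '%s'",
                 md$sample_id[duplicated(md$sample_id)][1]))
  bad <- setdiff(unique(md$group), GROUP_LEVELS)
  if (length(bad))
    stop(sprintf("metadata: unknown group label '%s' (allowed: %s)",
                 bad[1], paste(GROUP_LEVELS, collapse = ", ")))
  md$group <- factor(md$group, levels = GROUP_LEVELS)
  if ("age_years" %in% names(md)) {
    out <- which(md$age_years < 18 | md$age_years > 100)
    if (length(out))
      stop(sprintf("metadata: age_years out of 18-100 for sample '%s'",
                   md$sample_id[out[1]]))
  }
  if ("pH" %in% names(md)) {
    out <- which(!is.na(md$pH) & (md$pH < 4.5 | md$pH > 9))
    if (length(out))
      stop(sprintf("metadata: strip pH out of 4.5-9 for sample '%s'",
                   md$sample_id[out[1]]))
  }
  md
}

#' Group counts of a metadata table
#' @param metadata Data frame from [read_metadata()].
#' @return Named integer vector over the three group labels.
#' @export
group_counts <- function(metadata) {
  table(factor(metadata$group, levels = GROUP_LEVELS))
}

#' Write / read a feature table as CSV
#'
#' Round-trip safe: labels are reproduced exactly and numeric values to at
#' least 12 significant digits.
#'
#' @param table A feature table from [build_feature_table()].
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("write_feature_table: table must be a nonempty data.frame")
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 15, format = "g"))
  write.csv(out, path, row.names = FALSE, quote = which(!num))
  invisible(path)
}

#' @rdname write_feature_table
#' @return `read_feature_table` returns the feature table with its
#'   `representation` attribute re-inferred from the columns.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_feature_table: no such file '%s'", path))
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if ("group" %in% names(tab)) tab$group <- factor(tab$group, levels = GROUP_LEVELS)
  attr(tab, "representation") <-
    if (any(grepl("^wl[0-9]", names(tab)))) "utfmp" else "zones"
  tab
}
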