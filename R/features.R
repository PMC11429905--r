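#' Per-zone summary of a uTFMP
#'
#' Reduces the profile to one value per zone. `max` (default) is the zone's
#' smoothed peak height, which is robust to small wavelength shifts within a
#' zone; `mean` and `integral` (trapezoidal, in intensity x nm over the
#' half-open zone slice) are alternatives.
#'
#' @param profile A `utfmp_profile`.
#' @param scheme A [zone_scheme()].
#' @param stat `"max"`, `"mean"` or `"integral"`.
#' @return Named numeric vector over the nine zones.
#' @export
zone_summary <- function(profile, scheme = zone_scheme(),
                         stat = c("max", "mean", "integral")) {
  stat <- match.arg(stat)
  slices <- segment_zones(profile, scheme)
  vapply(slices, function(y) {
    switch(stat,
           max = max(y),
           mean = mean(y),
           integral = pracma::trapz(as.numeric(names(y)), y))
  }, numeric(1))
}

#' Spectral-marker ratios Z4a/Z5 and Z6/Z7
#'
#' The two zone-intensity quotients used as per-sample scalar biomarkers:
#' Z4a/Z5 contrasts NADH-like metabolites with xanthurenic acid, Z6/Z7
#' kynurenine/xanthopterin with flavins. Denominators are guarded by
#' `epsilon`; a triggered guard is logged, never silently passed.
#'
#' @param features Named zone summary vector from [zone_summary()].
#' @param epsilon Small positive denominator guard (fluorescence units).
#' @return Named numeric vector `c(Z4a_over_Z5, Z6_over_Z7)`.
#' @export
ratio_markers <- function(features, epsilon = 1e-9) {
  need <- c("Z4a", "Z5", "Z6", "Z7")
  if (!all(need %in% names(features)))
    stop("ratio_markers: features must contain Z4a, Z5, Z6, Z7")
  if (any(features[need] < 0))
    stop("ratio_markers: negative zone summaries")
  guarded <- function(num, den, label) {
    if (den < epsilon)
      utfmp_log("zone_features",
                sprintf("denominator guard triggered for %s (%.3g < %.3g)",
                        label, den, epsilon))
    num / max(den, epsilon)
  }
  c(Z4a_over_Z5 = guarded(features[["Z4a"]], features[["Z5"]], "Z4a/Z5"),
    Z6_over_Z7 = guarded(features[["Z6"]], features[["Z7"]], "Z6/Z7"))
}

#' Peak-coding rule
#'
#' Ternary encoding of the within-zone spectral rise: code 2 ("peak") for a
#' characteristic increase of at least `peak_threshold` fluorescence units,
#' 1 ("slight inclination") for an increase in `[flat_threshold,
#' peak_threshold)`, 0 ("flat") below `flat_threshold`. The published bands
#' (5-10 and >= 15 units) leave 10-15 unassigned; this implementation widens
#' the inclination band to cover it.
#'
#' Two readings of "increase between consecutive measurements" are provided:
#' `zone_rise` (default) takes the largest rise from any earlier point in the
#' zone to a later one, which is the physically plausible reading on smoothed
#' 0.5 nm data; `consecutive_step` takes the largest single-step difference,
#' the literal reading.
#'
#' @param peak_threshold Units of rise for code 2.
#' @param flat_threshold Units below which the zone codes 0.
#' @param mode `"zone_rise"` or `"consecutive_step"`.
#' @export
peak_rule <- function(peak_threshold = 15, flat_threshold = 5,
                      mode = c("zone_rise", "consecutive_step")) {
  mode <- match.arg(mode)
  if (!(flat_threshold > 0 && flat_threshold < peak_threshold))
    stop("peak_rule: need 0 < flat_threshold < peak_threshold")
  structure(list(peak_threshold = peak_threshold,
                 flat_threshold = flat_threshold, mode = mode),
            class = "peak_rule")
}

#' Ternary peak code of a zone slice
#'
#' @param slice Numeric intensity vector (length >= 2), typically one element
#'   of [segment_zones()].
#' @param rule A [peak_rule()].
#' @return Integer code 0, 1 or 2.
#' @export
peak_code <- function(slice, rule = peak_rule()) {
  slice <- as.numeric(slice)
  if (length(slice) < 2) stop("peak_code: slice must have at least 2 points")
  delta <- switch(rule$mode,
                  consecutive_step = max(diff(slice)),
                  zone_rise = max(slice - cummin(slice)))
  if (delta >= rule$peak_threshold) 2L
  else if (delta >= rule$flat_threshold) 1L
  else 0L
}

#' Assemble the model input matrix
#'
#' Two representations feed the statistical and machine-learning stages:
#' `"zones"` is the 20-column transposed-zone representation (9 zone
#' summaries, 9 peak codes, 2 ratio markers) and `"utfmp"` is the full
#' profile (one column per grid point, named `wl<wavelength>`). Rows are
#' sorted by sample id and carry the group label.
#'
#' @param profiles List of `utfmp_profile` objects.
#' @param metadata Metadata data.frame covering every profile's sample id.
#' @param representation `"zones"` or `"utfmp"`.
#' @param scheme,stat,rule Zone scheme, summary statistic and peak rule used
#'   by the zones representation.
#' @return A `data.frame` feature table with attribute `representation`.
#' @export
build_feature_table <- function(profiles, metadata,
                                representation = c("zones", "utfmp"),
                                scheme = zone_scheme(), stat = "max",
                                rule = peak_rule()) {
  representation <- match.arg(representation)
  stopifnot(length(profiles) > 0)
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  missing <- setdiff(ids, metadata$sample_id)
  if (length(missing))
    stop(sprintf("build_feature_table: join error - no metadata for sample '%s'",
                 missing[1]))
  ord <- order(ids)
  profiles <- profiles[ord]
  ids <- ids[ord]
  grp <- metadata$group[match(ids, metadata$sample_id)]
  if (representation == "zones") {
    rows <- lapply(profiles, function(p) {
      zs <- zone_summary(p, scheme, stat)
      slices <- segment_zones(p, scheme)
      pk <- vapply(slices, peak_code, integer(1), rule = rule)
      names(pk) <- paste0("pk_", names(pk))
      c(zs, pk, ratio_markers(zs))
    })
    mat <- do.call(rbind, rows)
  } else {
    mat <- do.call(rbind, lapply(profiles, function(p) p$intensities))
    colnames(mat) <- sprintf("wl%.1f", grid_points(profiles[[1]]$grid))
  }
  tab <- data.frame(sample_id = ids, group = grp, mat,
                    check.names = FALSE, row.names = NULL)
  attr(tab, "representation") <- representation
  tab
}

# Numeric feature columns of a feature table (everything but id/group).
feature_matrix <- function(table) {
  keep <- setdiff(names(table), c("sample_id", "group"))
  as.matrix(table[, keep, drop = FALSE])
}
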