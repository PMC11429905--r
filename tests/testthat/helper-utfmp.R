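# Shared fixtures, all generated in code.

# Small cohort -> list(spectra, metadata, profiles, zones table)
make_small_cohort <- function(n_control = 12, n_benign = 5, n_malignant = 12,
                              seed = 11, effect = group_effect_profile()) {
  co <- generate_cohort(cohort_spec(n_control, n_benign, n_malignant,
                                    seed = seed, effect = effect))
  profiles <- lapply(split(co$spectra,
                           vapply(co$spectra, function(s) s$sample_id, character(1))),
                     build_utfmp)
  zones <- suppressMessages(build_feature_table(profiles, co$metadata, "zones"))
  list(spectra = co$spectra, metadata = co$metadata,
       profiles = profiles, zones = zones)
}

# A deterministic synthetic profile: Gaussian bands on the study grid.
make_profile <- function(bands = data.frame(center = 470, width = 12, amp = 200),
                         baseline = 10, sample_id = "S1") {
  wl <- grid_points(wavelength_grid())
  y <- baseline + Reduce(`+`, lapply(seq_len(nrow(bands)), function(i)
    bands$amp[i] * exp(-0.5 * ((wl - bands$center[i]) / bands$width[i])^2)))
  structure(list(sample_id = sample_id, grid = wavelength_grid(),
                 intensities = y, construction = "single_dilution"),
            class = "utfmp_profile")
}

# Feature table with two well-separated Gaussian feature clusters.
make_separated_table <- function(n_per_class = 50, gap = 6, p = 2, seed = 3) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
               matrix(rnorm(n_per_class * p, mean = gap), ncol = p))
    tab <- data.frame(
      sample_id = sprintf("S%03d", seq_len(2 * n_per_class)),
      group = factor(rep(c("control", "malignant"), each = n_per_class),
                     levels = c("control", "benign", "malignant")),
      X)
    names(tab)[-(1:2)] <- paste0("f", seq_len(p))
    tab
  })
}

# Brute-force oracles --------------------------------------------------------

oracle_peak_delta <- function(x, mode) {
  best <- -Inf
  if (mode == "consecutive_step") {
    for (i in seq_len(length(x) - 1)) best <- max(best, x[i + 1] - x[i])
  } else {
    for (j in 2:length(x)) for (i in 1:(j - 1)) best <- max(best, x[j] - x[i])
    best <- max(best, 0)
  }
  best
}

oracle_peak_code <- function(x, mode) {
  d <- oracle_peak_delta(x, mode)
  if (d >= 15) 2L else if (d >= 5) 1L else 0L
}

# Pairwise Mann-Whitney AUC with ties counted half.
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
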