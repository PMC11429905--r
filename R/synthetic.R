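#' Default fluorophore band set
#'
#' Eight Gaussian emission bands, one or two per fluorescent zone, centred at
#' the zone midpoints associated with the named fluorophore families. Band
#' parameters (centres, widths, amplitudes) are simulation defaults chosen to
#' produce realistic-looking urine profiles on the study grid -- they are
#' configuration, not measured values.
#'
#' @return A data.frame with columns `name`, `center_nm`, `width_nm`,
#'   `amplitude`.
#' @export
default_bands <- function() {
  data.frame(
    name = c("indoles_a", "indoles_b", "hiaa_5", "haa_3", "nadh_like",
             "xanthurenic", "kynurenine_xanthopterin", "flavins"),
    center_nm = c(270, 290, 312, 335, 360, 395, 430, 470),
    width_nm = c(10, 10, 9, 8, 9, 12, 13, 14),
    amplitude = c(320, 300, 180, 80, 160, 120, 140, 100),
    stringsAsFactors = FALSE
  )
}

#' Group effect profile for the synthetic cohort
#'
#' Houses the qualitative between-group effects reported for the clinical
#' cohort as per-band amplitude multipliers and centre shifts: indole and
#' 5-HIAA fluorescence highest in controls, a 3-HAA band present only in
#' malignant samples, an NADH-like band elevated and red-shifted (+6 nm) in
#' malignancy, xanthurenic acid unchanged, kynurenine/xanthopterin reduced
#' and flavins elevated in malignancy. The malignant-side multipliers for
#' zones 6 and 7 are calibrated so that the Z6/Z7 control-vs-malignant AUC
#' of large simulated cohorts falls in 0.75-0.85 (see the methods vignette);
#' no quantitative effect size is a claim about the clinical data.
#'
#' @param multipliers 3 x 8 matrix (groups x bands) of amplitude multipliers.
#' @param center_shift_nm 3 x 8 matrix of centre shifts in nm.
#' @param sigma_log Between-subject log-scale SD of each band amplitude.
#' @param subject_scale_sigma Log-scale SD of a per-subject global intensity
#'   factor (urine concentration variability).
#' @param noise_floor,noise_frac Additive Gaussian noise SD is
#'   `noise_floor + noise_frac * intensity` (photon-noise-like).
#' @param baseline Constant baseline level (fluorescence units).
#' @export
group_effect_profile <- function(
    multipliers = NULL, center_shift_nm = NULL,
    sigma_log = 0.3, subject_scale_sigma = 0.15,
    noise_floor = 2, noise_frac = 0.02, baseline = 5) {
  bands <- default_bands()$name
  if (is.null(multipliers)) {
    multipliers <- rbind(
      control   = c(1.00, 1.00, 1.00, 0.00, 1.00, 1.00, 1.00, 1.00),
      benign    = c(0.80, 0.80, 0.70, 0.00, 1.35, 1.00, 0.85, 1.10),
      malignant = c(0.55, 0.55, 0.70, 1.00, 1.50, 1.00, 0.75, 1.20))
    colnames(multipliers) <- bands
  }
  if (is.null(center_shift_nm)) {
    center_shift_nm <- matrix(0, 3, length(bands),
                              dimnames = list(GROUP_LEVELS, bands))
    center_shift_nm["malignant", "nadh_like"] <- 6
  }
  stopifnot(all(multipliers >= 0), sigma_log >= 0, subject_scale_sigma >= 0,
            noise_floor >= 0, noise_frac >= 0, baseline >= 0)
  structure(list(multipliers = multipliers, center_shift_nm = center_shift_nm,
                 sigma_log = sigma_log, subject_scale_sigma = subject_scale_sigma,
                 noise_floor = noise_floor, noise_frac = noise_frac,
                 baseline = baseline),
            class = "group_effect_profile")
}

#' Effect-free (null) profile
#'
#' All groups share unit multipliers and zero shifts, making them
#' exchangeable: downstream classifiers should score near AUC 0.5 on
#' cohorts generated with it.
#' @inheritParams group_effect_profile
#' @export
null_effect_profile <- function(sigma_log = 0.3, subject_scale_sigma = 0.15,
                                noise_floor = 2, noise_frac = 0.02,
                                baseline = 5) {
  bands <- default_bands()$name
  m <- matrix(1, 3, length(bands), dimnames = list(GROUP_LEVELS, bands))
  s <- matrix(0, 3, length(bands), dimnames = list(GROUP_LEVELS, bands))
  group_effect_profile(m, s, sigma_log, subject_scale_sigma,
                       noise_floor, noise_frac, baseline)
}

#' Default per-group urine strip rates
#'
#' Positivity probabilities per strip parameter and mean pH for each group,
#' set to the counts reported for the clinical cohort (e.g. leukocytes 4/96
#' in controls, 61/77 in the malignant group; mean pH 6.06 / 6.43 / 5.69).
#' Parameters without reported positives default to rate 0.
#' @return List with elements `rates` (3 x 8 matrix) and `ph_mean`, `ph_sd`.
#' @export
default_strip_rates <- function() {
  params <- c("leukocytes", "nitrite", "protein", "glucose", "ketones",
              "urobilinogen", "bilirubin", "blood")
  rates <- rbind(
    control   = c(4 / 96, 0, 36 / 96, 0, 5 / 96, 0, 7 / 96, 8 / 96),
    benign    = c(8 / 23, 0, 11 / 23, 0, 8 / 23, 7 / 23, 12 / 23, 1 / 23),
    malignant = c(61 / 77, 0, 28 / 77, 3 / 77, 26 / 77, 26 / 77, 38 / 77, 32 / 77))
  colnames(rates) <- params
  list(rates = rates,
       ph_mean = c(control = 6.06, benign = 6.43, malignant = 5.69),
       ph_sd = 0.45)
}

#' Cohort specification
#'
#' @param n_control,n_benign,n_malignant Group sizes (study design:
#'   96 / 23 / 77).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec and seed.
#' @param effect A [group_effect_profile()].
#' @param dilution_factors Increasing dilution factors (>= 1) measured per
#'   sample; the default measures only the undiluted aliquot.
#' @param quench_strength Quench parameter passed to
#'   [generate_dilution_series()] when several factors are requested.
#' @param strip_rates Output of [default_strip_rates()] or a like-shaped list.
#' @export
cohort_spec <- function(n_control = 96, n_benign = 23, n_malignant = 77,
                        seed = 1, effect = group_effect_profile(),
                        dilution_factors = 1, quench_strength = 3,
                        strip_rates = default_strip_rates()) {
  stopifnot(n_control >= 0, n_benign >= 0, n_malignant >= 0)
  if (n_control + n_benign + n_malignant == 0)
    stop("cohort_spec: empty cohort (all counts zero)")
  if (any(dilution_factors < 1) || is.unsorted(dilution_factors, strictly = TRUE))
    stop("cohort_spec: dilution_factors must be >= 1 and strictly increasing")
  structure(list(n_control = n_control, n_benign = n_benign,
                 n_malignant = n_malignant, seed = as.integer(seed),
                 effect = effect, dilution_factors = dilution_factors,
                 quench_strength = quench_strength, strip_rates = strip_rates),
            class = "cohort_spec")
}

# Age model per group, matching the reported cohort age summaries
# (mean +/- SD, truncated to the reported min/max).
age_model <- list(
  control = c(mean = 36.4, sd = 11.66, lo = 18, hi = 65),
  benign = c(mean = 32.7, sd = 6.25, lo = 21, hi = 46),
  malignant = c(mean = 60.9, sd = 11.5, lo = 30, hi = 80)
)

#' Generate a synthetic three-group cohort
#'
#' Each sample's undiluted spectrum is a sum of Gaussian fluorophore bands
#' (group-specific amplitude multipliers and centre shifts, log-normal
#' between-subject loadings, a log-normal global concentration factor), a
#' constant baseline and heteroscedastic additive noise, clipped at zero.
#' If `spec$dilution_factors` has several entries a quenched dilution series
#' is generated per sample. Ages and strip covariates are drawn per group.
#'
#' @param spec A [cohort_spec()].
#' @return List with elements `spectra` (list of [syn_spectrum()]) and
#'   `metadata` (data.frame: sample_id, group, age_years, strip columns).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  bands <- default_bands()
  eff <- spec$effect
  grid <- wavelength_grid()
  wl <- grid_points(grid)
  counts <- c(control = spec$n_control, benign = spec$n_benign,
              malignant = spec$n_malignant)
  prefix <- c(control = "CTRL", benign = "BEN", malignant = "MAL")
  spectra <- list()
  meta <- list()
  with_seed(spec$seed, {
    for (g in GROUP_LEVELS) {
      n <- counts[[g]]
      if (n == 0) next
      am <- age_model[[g]]
      for (i in seq_len(n)) {
        id <- sprintf("%s%03d", prefix[[g]], i)
        loadings <- rlnorm(nrow(bands), 0, eff$sigma_log)
        gscale <- rlnorm(1, 0, eff$subject_scale_sigma)
        amp <- bands$amplitude * eff$multipliers[g, bands$name] * loadings * gscale
        ctr <- bands$center_nm + eff$center_shift_nm[g, bands$name]
        clean <- eff$baseline +
          colSums(amp * exp(-0.5 * ((matrix(wl, nrow(bands), length(wl),
                                            byrow = TRUE) - ctr) / bands$width_nm)^2))
        noisy <- clean + rnorm(length(wl), 0,
                               eff$noise_floor + eff$noise_frac * clean)
        sp <- syn_spectrum(id, pmax(noisy, 0), grid = grid)
        if (length(spec$dilution_factors) > 1) {
          base <- syn_spectrum(id, pmax(clean, 0), grid = grid)
          ser <- generate_dilution_series(
            base, spec$dilution_factors, spec$quench_strength,
            seed = derive_seed(spec$seed, length(spectra) + 1L),
            noise_floor = eff$noise_floor, noise_frac = eff$noise_frac)
          spectra <- c(spectra, ser)
        } else {
          spectra <- c(spectra, list(sp))
        }
        age <- min(max(rnorm(1, am["mean"], am["sd"]), am["lo"]), am["hi"])
        meta[[length(meta) + 1L]] <-
          data.frame(sample_id = id, group = g, age_years = round(age, 1),
                     stringsAsFactors = FALSE)
      }
    }
  })
  metadata <- do.call(rbind, meta)
  strip <- do.call(rbind, lapply(GROUP_LEVELS, function(g) {
    n <- counts[[g]]
    if (n == 0) return(NULL)
    generate_strip_covariates(g, n, seed = derive_seed(spec$seed, match(g, GROUP_LEVELS)),
                              rates = spec$strip_rates)
  }))
  metadata <- cbind(metadata, strip)
  metadata <- validate_metadata(metadata)
  list(spectra = spectra, metadata = metadata)
}

#' Generate a quenched dilution series from one spectrum
#'
#' Models concentration-dependent fluorescence with saturable inner-filter
#' quenching: at dilution factor `f` (relative concentration `c = 1/f`) the
#' intensity is `I0 * c * exp(q * (1 - c))`. With `q = 0` intensity scales
#' exactly as `1/f`; with `q > 0` the per-wavelength intensity is maximal at
#' the interior factor `f = q`, reproducing the non-monotonic
#' concentration-intensity curve of concentrated urine.
#'
#' @param spectrum Undiluted [syn_spectrum()].
#' @param factors Dilution factors, all >= 1 (study series: 3^k, k = 0..6).
#' @param quench_strength Nonnegative quench parameter `q`.
#' @param seed Seed for the measurement noise.
#' @param noise_floor,noise_frac Additive noise model, as in
#'   [group_effect_profile()]; defaults are noise-free so the `q = 0` limit
#'   is exact.
#' @return List of [syn_spectrum()] objects, one per factor.
#' @export
generate_dilution_series <- function(spectrum, factors = 3^(0:6),
                                     quench_strength = 3, seed = 1,
                                     noise_floor = 0, noise_frac = 0) {
  stopifnot(inherits(spectrum, "syn_spectrum"))
  if (any(factors < 1)) stop("generate_dilution_series: factors must be >= 1")
  if (quench_strength < 0) stop("generate_dilution_series: quench_strength must be >= 0")
  with_seed(seed, {
    lapply(seq_along(factors), function(k) {
      f <- factors[k]
      conc <- 1 / f
      y <- spectrum$intensities * conc * exp(quench_strength * (1 - conc))
      if (noise_floor > 0 || noise_frac > 0)
        y <- pmax(y + rnorm(length(y), 0, noise_floor + noise_frac * y), 0)
      syn_spectrum(spectrum$sample_id, y, grid = spectrum$grid,
                   delta_lambda_nm = spectrum$delta_lambda_nm,
                   dilution_factor = f)
    })
  })
}

#' Generate urine strip covariates for one group
#'
#' Bernoulli positivity per strip parameter at the group's configured rate,
#' pH drawn around the group mean (truncated to the strip's 4.5-9 range) and
#' specific gravity around 1.015.
#'
#' @param group One of control / benign / malignant.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param rates Rate configuration, see [default_strip_rates()].
#' @return Data frame with the ten strip columns (binary positivity for
#'   eight parameters, numeric pH and specific_gravity).
#' @export
generate_strip_covariates <- function(group, n, seed = 1,
                                      rates = default_strip_rates()) {
  if (!group %in% GROUP_LEVELS)
    stop(sprintf("generate_strip_covariates: unknown group '%s'", group))
  stopifnot(n >= 0)
  with_seed(seed, {
    out <- as.data.frame(lapply(colnames(rates$rates), function(p)
      rbinom(n, 1, rates$rates[group, p])))
    names(out) <- colnames(rates$rates)
    out$pH <- round(pmin(pmax(rnorm(n, rates$ph_mean[[group]], rates$ph_sd), 4.5), 9), 1)
    out$specific_gravity <- round(rnorm(n, 1.015, 0.005), 3)
    out[, STRIP_PARAMS]
  })
}
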