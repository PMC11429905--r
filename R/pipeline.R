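#' Pipeline run configuration
#'
#' Bundles every stage's settings. Either `spectra_path`/`metadata_path`
#' point at CSV inputs, or `simulate` holds a [cohort_spec()] and the
#' cohort is generated. The `profile` switches the cross-validation
#' repetition count: `"desk"` (10 repetitions, the test default) or
#' `"paper"` (100 repetitions, the study-faithful protocol).
#'
#' @param simulate A [cohort_spec()], or `NULL` when reading files.
#' @param spectra_path,metadata_path Input CSVs (ignored when simulating).
#' @param smoothing A [smoothing_config()].
#' @param scheme A [zone_scheme()].
#' @param rule A [peak_rule()].
#' @param stat Zone summary statistic.
#' @param construction uTFMP construction mode, see [build_utfmp()].
#' @param representations Character subset of `c("zones", "utfmp")`.
#' @param models List of [model_spec()]s.
#' @param n_folds Cross-validation folds.
#' @param profile `"desk"` or `"paper"`; sets the repetition count unless
#'   `n_reps` is given explicitly.
#' @param n_reps Optional explicit repetition count.
#' @param test_fraction Held-out fraction for split-based stages.
#' @param n_components PLS-DA components.
#' @param seed Base seed; every stage derives child seeds from it.
#' @param output_dir Directory for the report bundle, or `NULL` to keep
#'   results in memory only.
#' @param stages Character vector of enabled stages, subset of
#'   `c("descriptive", "stats", "roc", "plsda", "suite")`.
#' @export
run_config <- function(simulate = cohort_spec(), spectra_path = NULL,
                       metadata_path = NULL, smoothing = smoothing_config(),
                       scheme = zone_scheme(), rule = peak_rule(),
                       stat = "max",
                       construction = "max_over_dilutions",
                       representations = c("zones", "utfmp"),
                       models = default_models(), n_folds = 10,
                       profile = c("desk", "paper"), n_reps = NULL,
                       test_fraction = 0.3, n_components = 2, seed = 2024,
                       output_dir = NULL,
                       stages = c("descriptive", "stats", "roc", "plsda", "suite")) {
  profile <- match.arg(profile)
  if (is.null(n_reps)) n_reps <- if (profile == "desk") 10L else 100L
  if (length(stages) == 0)
    stop("run_config: validation error - no stages enabled")
  bad <- setdiff(stages, c("descriptive", "stats", "roc", "plsda", "suite"))
  if (length(bad)) stop(sprintf("run_config: unknown stage '%s'", bad[1]))
  if (is.null(simulate) && (is.null(spectra_path) || is.null(metadata_path)))
    stop("run_config: either a simulation spec or both input paths are required")
  bad_rep <- setdiff(representations, c("zones", "utfmp"))
  if (length(bad_rep)) stop(sprintf("run_config: unknown representation '%s'", bad_rep[1]))
  structure(list(simulate = simulate, spectra_path = spectra_path,
                 metadata_path = metadata_path, smoothing = smoothing,
                 scheme = scheme, rule = rule, stat = stat,
                 construction = construction,
                 representations = representations, models = models,
                 n_folds = n_folds, profile = profile, n_reps = as.integer(n_reps),
                 test_fraction = test_fraction, n_components = n_components,
                 seed = as.integer(seed), output_dir = output_dir,
                 stages = stages),
            class = "run_config")
}

#' Tabulate strip positivity and pH by group
#'
#' Per-group positive counts for each semiquantitative strip parameter and
#' the group mean pH, mirroring the descriptive urinalysis table.
#'
#' @param metadata Metadata data.frame with strip columns.
#' @return Data frame: parameter x group counts (and a `mean_pH` row when
#'   pH is present); zero-row with a warning when no strip data exist.
#' @export
tabulate_strip <- function(metadata) {
  present <- intersect(setdiff(STRIP_PARAMS, c("pH", "specific_gravity")),
                       names(metadata))
  if (!length(present) && !"pH" %in% names(metadata)) {
    warning("tabulate_strip: no strip data present")
    return(data.frame(parameter = character(0)))
  }
  g <- factor(metadata$group, levels = GROUP_LEVELS)
  rows <- lapply(present, function(p) {
    cnt <- tapply(metadata[[p]] > 0, g, sum, default = 0L)
    data.frame(parameter = p, control = cnt[["control"]],
               benign = cnt[["benign"]], malignant = cnt[["malignant"]])
  })
  out <- do.call(rbind, rows)
  if ("pH" %in% names(metadata)) {
    m <- tapply(metadata$pH, g, mean)
    out <- rbind(out, data.frame(parameter = "mean_pH",
                                 control = round(m[["control"]], 2),
                                 benign = round(m[["benign"]], 2),
                                 malignant = round(m[["malignant"]], 2)))
  } else {
    warning("tabulate_strip: pH column missing, mean pH row omitted")
  }
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Simulates or loads a cohort, builds uTFMPs, extracts both feature
#' representations, and runs every enabled stage: descriptive tables
#' (group counts, strip tabulation), zone/ratio group statistics, ROC
#' analysis of both spectral-marker ratios for control-vs-benign and
#' control-vs-malignant (Z4a/Z5 higher-is-positive, Z6/Z7
#' lower-is-positive), PLS-DA for the same two comparisons, and the
#' four-model cross-validation suite. The run is idempotent: identical
#' config and seed reproduce every number.
#'
#' @param config A [run_config()].
#' @return Object of class `report_bundle`: list with `metadata`,
#'   `features`, `descriptive`, `stats`, `roc`, `plsda`, `suite`, and
#'   `manifest`. When `config$output_dir` is set, all tables plus the
#'   manifest JSON are written there.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate)
    spectra <- cohort$spectra
    metadata <- cohort$metadata
  } else {
    spectra <- read_spectra(config$spectra_path)
    metadata <- read_metadata(config$metadata_path)
  }
  # --- preprocess -> profiles ----------------------------------------------
  by_sample <- split(spectra, vapply(spectra, function(s) s$sample_id, character(1)))
  profiles <- lapply(by_sample, build_utfmp, cfg = config$smoothing,
                     construction = config$construction)
  # --- features -------------------------------------------------------------
  features <- lapply(setNames(config$representations, config$representations),
                     function(rep)
                       build_feature_table(profiles, metadata, rep,
                                           scheme = config$scheme,
                                           stat = config$stat,
                                           rule = config$rule))
  bundle <- list(metadata = metadata, features = features)
  zones_tab <- features[["zones"]]
  # --- descriptive ----------------------------------------------------------
  if ("descriptive" %in% config$stages) {
    bundle$descriptive <- list(
      group_counts = group_counts(metadata),
      strip = tryCatch(tabulate_strip(metadata), warning = function(w) {
        utfmp_log("pipeline", conditionMessage(w)); data.frame()
      }))
  }
  # --- group statistics -----------------------------------------------------
  if ("stats" %in% config$stages && !is.null(zones_tab)) {
    vars <- c(config$scheme$zone, "Z4a_over_Z5", "Z6_over_Z7")
    bundle$stats <- lapply(setNames(vars, vars), function(v)
      test_group_differences(zones_tab, v))
  }
  # --- ROC of the ratio markers --------------------------------------------
  if ("roc" %in% config$stages && !is.null(zones_tab)) {
    comparisons <- list(benign = "benign", malignant = "malignant")
    markers <- list(Z4a_over_Z5 = "higher_is_positive",
                    Z6_over_Z7 = "lower_is_positive")
    bundle$roc <- list()
    for (cmp in names(comparisons)) {
      sub <- zones_tab[zones_tab$group %in% c("control", cmp), , drop = FALSE]
      if (length(unique(as.character(sub$group))) < 2) next
      for (mk in names(markers)) {
        key <- sprintf("%s_control_vs_%s", mk, cmp)
        bundle$roc[[key]] <- roc_analysis(
          sub[[mk]], as.character(sub$group), polarity = markers[[mk]],
          positive = cmp)
      }
    }
  }
  # --- PLS-DA ---------------------------------------------------------------
  if ("plsda" %in% config$stages && !is.null(zones_tab)) {
    bundle$plsda <- list()
    for (cmp in c("malignant", "benign")) {
      sub <- zones_tab[zones_tab$group %in% c("control", cmp), , drop = FALSE]
      sub$group <- droplevels(sub$group)
      if (nlevels(sub$group) < 2 || min(table(sub$group)) < 7) next
      split <- stratified_split(sub, config$test_fraction,
                                seed = derive_seed(config$seed, 77L))
      bundle$plsda[[paste0("control_vs_", cmp)]] <-
        fit_plsda(split$train, split$test, config$n_components,
                  positive = cmp, seed = derive_seed(config$seed, 78L))
    }
  }
  # --- classifier suite -----------------------------------------------------
  if ("suite" %in% config$stages) {
    bundle$suite <- run_suite(features, models = config$models,
                              n_folds = config$n_folds, n_reps = config$n_reps,
                              test_fraction = config$test_fraction,
                              seed = derive_seed(config$seed, 99L))
  }
  bundle$manifest <- list(
    package_version = as.character(packageVersion("utfmp")),
    seed = config$seed, profile = config$profile, n_reps = config$n_reps,
    n_folds = config$n_folds, stages = config$stages,
    representations = config$representations,
    construction = config$construction, stat = config$stat,
    smoothing = unclass(config$smoothing),
    peak_rule = unclass(config$rule),
    zones = as.data.frame(unclass(config$scheme)),
    simulate = if (!is.null(config$simulate)) {
      s <- config$simulate
      list(n_control = s$n_control, n_benign = s$n_benign,
           n_malignant = s$n_malignant, seed = s$seed,
           dilution_factors = s$dilution_factors,
           quench_strength = s$quench_strength)
    },
    inputs = list(spectra = config$spectra_path, metadata = config$metadata_path),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  class(bundle) <- "report_bundle"
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

# Persist every tabular output plus the JSON manifest (with file hashes).
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  save_csv <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    paths[[length(paths) + 1L]] <<- p
  }
  for (rep in names(bundle$features)) {
    p <- file.path(dir, sprintf("features_%s.csv", rep))
    write_feature_table(bundle$features[[rep]], p)
    paths[[length(paths) + 1L]] <- p
  }
  if (!is.null(bundle$descriptive)) {
    save_csv(as.data.frame(bundle$descriptive$group_counts), "group_counts.csv")
    if (nrow(bundle$descriptive$strip)) save_csv(bundle$descriptive$strip, "strip_positivity.csv")
  }
  if (!is.null(bundle$stats)) {
    save_csv(do.call(rbind, lapply(bundle$stats, function(s)
      data.frame(variable = s$variable, test = s$test, global_p = s$global_p,
                 s$pairwise))), "group_tests.csv")
  }
  if (!is.null(bundle$roc)) {
    save_csv(do.call(rbind, lapply(names(bundle$roc), function(k) {
      r <- bundle$roc[[k]]
      data.frame(comparison = k, auc = r$auc, auc_se = r$auc_se,
                 ci_lower = r$auc_ci_95[1], ci_upper = r$auc_ci_95[2],
                 p_value = r$p_value, polarity = r$polarity)
    })), "roc_summary.csv")
    for (k in names(bundle$roc))
      save_csv(bundle$roc[[k]]$sweep, sprintf("roc_sweep_%s.csv", k))
  }
  if (!is.null(bundle$plsda)) {
    save_csv(do.call(rbind, lapply(names(bundle$plsda), function(k) {
      p <- bundle$plsda[[k]]
      data.frame(comparison = k, accuracy = p$accuracy, auc = p$auc,
                 r2 = p$r2, q2 = p$q2)
    })), "plsda_summary.csv")
  }
  if (!is.null(bundle$suite)) {
    save_csv(bundle$suite$cv_summary, "suite_cv_summary.csv")
    save_csv(bundle$suite$test, "suite_test_metrics.csv")
    save_csv(bundle$suite$pooled_metrics, "suite_pooled_metrics.csv")
    save_csv(data.frame(key = names(bundle$suite$pooled_confusion),
                        do.call(rbind, bundle$suite$pooled_confusion)),
             "suite_pooled_confusion.csv")
  }
  manifest <- bundle$manifest
  manifest$files <- lapply(unlist(paths), function(p)
    list(name = basename(p), md5 = unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
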