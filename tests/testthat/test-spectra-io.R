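test_that("wavelength grid validates its invariants", {
  g <- wavelength_grid()
  expect_equal(g$n, 601L)
  wl <- grid_points(g)
  expect_true(all(diff(wl) > 0))
  expect_equal(range(wl), c(250, 550))
  expect_error(wavelength_grid(300, 250), "start_nm")
  expect_error(wavelength_grid(250, 550, -1), "step")
  expect_error(wavelength_grid(250, 550, 0.7), "integer")
})

test_that("wide spectra CSV round-trips, including dilution-coded columns", {
  g <- wavelength_grid()
  wl <- grid_points(g)
  s1 <- syn_spectrum("S1", 100 + 50 * sin(wl / 20), g)
  s2 <- syn_spectrum("S1", 40 + 10 * cos(wl / 30), g, dilution_factor = 3)
  s3 <- syn_spectrum("S2", rep(7, g$n), g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(list(s1, s2, s3), path)
  back <- read_spectra(path)
  expect_length(back, 3)
  expect_equal(vapply(back, function(s) s$sample_id, character(1)),
               c("S1", "S1", "S2"))
  expect_equal(vapply(back, function(s) s$dilution_factor, numeric(1)),
               c(1, 3, 1))
  expect_equal(back[[1]]$intensities, s1$intensities, tolerance = 1e-12)
  expect_equal(back[[2]]$intensities, s2$intensities, tolerance = 1e-12)
})

test_that("off-grid spectra are linearly interpolated, endpoints preserved", {
  wl_coarse <- seq(250, 550, by = 1)
  y <- 10 + (wl_coarse - 250) * 0.3          # linear, so interpolation is exact
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(wavelength_nm = wl_coarse, A = y), path, row.names = FALSE)
  sp <- suppressMessages(read_spectra(path))[[1]]
  expect_equal(length(sp$intensities), 601L)
  expect_equal(sp$intensities[1], 10)                    # endpoint exact
  expect_equal(sp$intensities[601], 10 + 300 * 0.3)      # endpoint exact
  # midpoint of a 1 nm cell is the average of its neighbours
  expect_equal(sp$intensities[2], (y[1] + y[2]) / 2)
  # already-on-grid data are untouched
  wl_fine <- grid_points(wavelength_grid())
  write.csv(data.frame(wavelength_nm = wl_fine, A = sin(wl_fine)^2), path,
            row.names = FALSE)
  sp2 <- read_spectra(path)[[1]]
  expect_equal(sp2$intensities, sin(wl_fine)^2, tolerance = 1e-12)
})

test_that("malformed spectra files fail with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  wl <- grid_points(wavelength_grid())
  write.csv(data.frame(nm = wl, A = wl), path, row.names = FALSE)
  expect_error(read_spectra(path), "wavelength_nm")
  df <- data.frame(wavelength_nm = wl, A = wl)
  df$A <- as.character(df$A); df$A[5] <- "oops"
  write.csv(df, path, row.names = FALSE)
  expect_error(read_spectra(path), "non-numeric")
  write.csv(data.frame(wavelength_nm = seq(300, 500, 0.5),
                       A = seq(300, 500, 0.5)), path, row.names = FALSE)
  expect_error(read_spectra(path), "coverage")
})

test_that("negative intensities are clipped to zero on read, with a log line", {
  path <- withr::local_tempfile(fileext = ".csv")
  wl <- grid_points(wavelength_grid())
  y <- rep(5, length(wl)); y[10] <- -2
  write.csv(data.frame(wavelength_nm = wl, A = y), path, row.names = FALSE)
  expect_message(sp <- read_spectra(path)[[1]], "clipped")
  expect_equal(sp$intensities[10], 0)
  expect_true(all(sp$intensities >= 0))
})

test_that("metadata reader validates labels, duplicates and ranges", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(sample_id = c("S1", "S2"), group = c("control", "benign"),
                       age_years = c(36, 60)), path, row.names = FALSE)
  md <- read_metadata(path)
  expect_s3_class(md$group, "factor")
  expect_equal(as.character(md$group), c("control", "benign"))
  write.csv(data.frame(sample_id = "S2", group = "cancer", age_years = 60),
            path, row.names = FALSE)
  expect_error(read_metadata(path), "unknown group")
  write.csv(data.frame(sample_id = c("S1", "S1"), group = "control"),
            path, row.names = FALSE)
  expect_error(read_metadata(path), "duplicate")
  write.csv(data.frame(sample_id = "S1", group = "control", age_years = 12),
            path, row.names = FALSE)
  expect_error(read_metadata(path), "age")
})

test_that("group counts reproduce the label multiset of the study design", {
  path <- withr::local_tempfile(fileext = ".csv")
  md <- data.frame(
    sample_id = sprintf("S%03d", 1:196),
    group = rep(c("control", "benign", "malignant"), c(96, 23, 77)))
  write.csv(md[sample(196), ], path, row.names = FALSE)
  counts <- group_counts(read_metadata(path))
  expect_equal(as.integer(counts), c(96L, 23L, 77L))
  expect_equal(names(counts), c("control", "benign", "malignant"))
})

test_that("feature tables round-trip through CSV to 12 significant digits", {
  sc <- make_small_cohort(n_control = 3, n_benign = 0, n_malignant = 2, seed = 5)
  tab <- sc$zones
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_identical(back$sample_id, tab$sample_id)
  expect_identical(as.character(back$group), as.character(tab$group))
  expect_true(all(c("Z4a_over_Z5", "Z6_over_Z7") %in% names(back)))
  expect_equal(attr(back, "representation"), "zones")
  for (col in setdiff(names(tab), c("sample_id", "group")))
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-12)
  expect_error(write_feature_table(tab[0, ], path), "nonempty")
})
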