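test_that("measurement grid has the documented 12 points in fixed order", {
  g <- make_measurement_grid()
  expect_equal(nrow(g), 12)
  expect_equal(unlist(g[1, c("depth_cm", "lateral_cm")], use.names = FALSE),
               c(3, 0))
  expect_equal(unlist(g[12, c("depth_cm", "lateral_cm")], use.names = FALSE),
               c(10, 10))
  expect_equal(sum(g$in_field), 3)
  expect_identical(g, make_measurement_grid())
})

test_that("default_params rejects unknown fields and off-grid points", {
  expect_error(default_params("CO60"), "unsupported field")
  expect_error(default_params("FF_6MV", c(4, 0)), "no shipped calibration")
  expect_error(default_params("FF_6MV", "d4_l2"), "unknown measurement point")
})

test_that("the 220 kVp reference parameters are position-independent", {
  p1 <- default_params("REF_220KVP", c(3, 0))
  p2 <- default_params("REF_220KVP", c(10, 10))
  p3 <- default_params("REF_220KVP")
  p1$depth_cm <- p2$depth_cm <- p3$depth_cm <- NULL
  p1$lateral_cm <- p2$lateral_cm <- p3$lateral_cm <- NULL
  expect_identical(p1, p2)
  expect_identical(p1, p3)
})

test_that("shipped calibration encodes spectral softening", {
  g <- make_measurement_grid()
  means <- sapply(c("FF_6MV", "FFF_6MV"), function(f)
    sapply(seq_len(nrow(g)), function(i)
      spectrum_mean_energy(generate_spectrum(default_params(f, g[i, ])))))
  # FFF strictly softer than FF at every point, in-field included
  expect_true(all(means[, "FFF_6MV"] < means[, "FF_6MV"]))
  # mean energy non-increasing with lateral distance at each depth
  for (f in colnames(means)) for (d in unique(g$depth_cm)) {
    m <- means[g$depth_cm == d, f]
    expect_true(all(diff(m) <= 1e-9),
                info = sprintf("%s depth %g", f, d))
  }
})

test_that("generated spectra are normalized, deterministic and binned as asked", {
  p <- spectrum_model_params(mean_energy_keV = 300)
  s <- generate_spectrum(p, 100)
  expect_length(s$weight, 100)
  expect_equal(sum(s$weight), 1, tolerance = 1e-12)
  expect_true(all(s$energy_keV >= 1))
  expect_true(!is.unsorted(s$energy_keV, strictly = TRUE))
  expect_identical(s, generate_spectrum(p, 100))
  expect_error(generate_spectrum(p, 1), "n_bins")
  expect_error(generate_spectrum(p, -3), "n_bins")
})

test_that("a degenerate support collapses to a single-bin delta spectrum", {
  p <- spectrum_model_params(mean_energy_keV = 10, e_min_keV = 50,
                             e_max_keV = 50 * (1 + 1e-13))
  s <- generate_spectrum(p, 100)
  expect_length(s$weight, 1)
  expect_equal(s$weight, 1)
  expect_equal(s$energy_keV, 50)
})

test_that("spectrum params validate their domain", {
  expect_error(spectrum_model_params(-5), "positive")
  expect_error(spectrum_model_params(10, low_energy_fraction = 1.2), "\\[0, 1\\]")
  expect_error(spectrum_model_params(10, e_min_keV = 0.2), "cut-off")
  expect_error(spectrum_model_params(10, e_min_keV = 90, e_max_keV = 80),
               "below")
  expect_error(spectrum_model_params(10, family = "powerlaw"), "family")
})

test_that("spectrum CSV round trip preserves grid and weights to 1e-9", {
  s <- generate_spectrum(default_params("FFF_6MV", c(5, 8)), 80)
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  s2 <- read_spectrum_csv(path)
  expect_equal(s2$energy_keV, s$energy_keV, tolerance = 1e-9)
  expect_equal(s2$weight, s$weight, tolerance = 1e-9)
  expect_equal(s2$field, "FFF_6MV")
  expect_equal(s2$depth_cm, 5)
  expect_equal(s2$lateral_cm, 8)
})

test_that("malformed spectrum CSVs are rejected with the offending row", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("# field=FF_6MV", "energy_keV,weight", "10,0.5", "20,-0.1"),
             path)
  expect_error(read_spectrum_csv(path), "negative weight.*row 2")
  writeLines(c("energy_keV,weight", "20,0.5", "10,0.5"), path)
  expect_error(read_spectrum_csv(path), "not strictly increasing.*row 2")
  writeLines(c("energy,weight", "10,1"), path)
  expect_error(read_spectrum_csv(path), "missing required column")
})

test_that("a one-row spectrum file is a valid single-energy spectrum", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("# field=FF_6MV", "energy_keV,weight", "33,4"), path)
  s <- read_spectrum_csv(path)
  expect_equal(s$energy_keV, 33)
  expect_equal(s$weight, 1) # normalized
})
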