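test_that("below the 1 keV cut-off a track is one local event", {
  tr <- simulate_track(0.5, seed = 11)
  expect_equal(nrow(tr$events), 1)
  expect_equal(tr$events$deposit_eV, 500)
  expect_equal(unlist(tr$events[, c("x_nm", "y_nm", "z_nm")],
                      use.names = FALSE), c(0, 0, 0))
})

test_that("energy is conserved exactly in every track", {
  for (e in c(0.7, 2, 7.3, 40, 300)) for (s in 1:3) {
    tr <- simulate_track(e, seed = derive_seed(99, e * 10, s))
    expect_equal(sum(tr$events$deposit_eV) / 1000, e, tolerance = 1e-9)
    expect_true(all(tr$events$deposit_eV > 0))
  }
})

test_that("tracks are deterministic in the seed and vary across seeds", {
  a <- simulate_track(10, seed = 5)
  b <- simulate_track(10, seed = 5)
  c <- simulate_track(10, seed = 6)
  expect_identical(a$events, b$events)
  expect_false(nrow(a$events) == nrow(c$events) &&
                 isTRUE(all.equal(a$events, c$events)))
})

test_that("invalid inputs are rejected", {
  expect_error(simulate_track(-1), "positive")
  expect_error(simulate_track(NA_real_), "positive")
  expect_error(default_track_params(cluster_mean_multiplicity = 0.5), ">= 1")
})

test_that("the fused counting path reproduces the stored-events path", {
  p <- default_track_params()
  for (e in c(0.4, 3, 25, 120)) {
    tr <- simulate_track(e, p, seed = 42)
    ct <- trackRBE:::track_counts(e, p, seed = 42)
    expect_equal(unname(ct["n_event"]), nrow(tr$events))
    expect_equal(unname(ct["n_link"]), count_linkages(tr))
  }
})

test_that("cohorts are reproducible, order-independent and sized as asked", {
  sp <- generate_spectrum(default_params("FF_6MV", c(3, 10)), 40)
  co1 <- simulate_cohort(sp, 10, seed = 7)
  co2 <- simulate_cohort(sp, 10, seed = 7)
  expect_length(co1, 10)
  expect_identical(lapply(co1, `[[`, "events"), lapply(co2, `[[`, "events"))
  # track i depends only on (master seed, i, its energy), not on the loop
  e5 <- co1[[5]]$incident_energy_keV
  solo <- simulate_track(e5, default_track_params(), derive_seed(7, 5))
  expect_identical(solo$events, co1[[5]]$events)
})

test_that("a single-energy spectrum yields tracks at exactly that energy", {
  s <- trackRBE:::new_electron_spectrum(80, 1)
  co <- simulate_cohort(s, 5, seed = 3)
  expect_true(all(vapply(co, `[[`, numeric(1), "incident_energy_keV") == 80))
})

test_that("events_per_keV matches a direct recount and handles edge cases", {
  t1 <- manual_track(rep(0, 10), rep(0, 10), 1:10, rep(100, 10),
                     e_in_keV = 1)
  r <- events_per_keV(t1)
  expect_equal(r$mean, 10)
  expect_equal(r$se, 0)
  t2 <- manual_track(0, 0, 0, 1000, e_in_keV = 0.5) # ratio 2
  expect_equal(events_per_keV(list(t1, t2))$mean, 6)
  co <- simulate_cohort(trackRBE:::new_electron_spectrum(15, 1), 8, seed = 2)
  recount <- mean(vapply(co, function(t) nrow(t$events), integer(1)) / 15)
  expect_equal(events_per_keV(co)$mean, recount)
})

test_that("mean deposit per event tracks the shipped energy-per-event curve", {
  p <- default_track_params()
  tr <- simulate_track(5, p, seed = 31)
  m <- mean(tr$events$deposit_eV)
  # slowing-down average must stay within the curve's range below 5 keV
  lo <- min(p$curve$ev_per_event)
  hi <- max(p$curve$ev_per_event[p$curve$energy_keV <= 5])
  expect_gt(m, lo * 0.9)
  expect_lt(m, hi * 1.1)
})

test_that("lower incident energy gives denser linkage per event", {
  r100 <- cohort_link_ratio(100, 40, seed = 201)
  r10 <- cohort_link_ratio(10, 200, seed = 202)
  r2 <- cohort_link_ratio(2, 400, seed = 203)
  expect_gt(r10, r100)
  expect_gt(r2, r10)
})

test_that("cohort TSV round trip preserves events and energies", {
  sp <- trackRBE:::new_electron_spectrum(c(5, 20), c(0.5, 0.5))
  co <- simulate_cohort(sp, 3, seed = 9)
  path <- tempfile(fileext = ".tsv.gz")
  write_cohort_tsv(co, path)
  co2 <- read_cohort_tsv(path)
  expect_length(co2, 3)
  for (i in 1:3) {
    expect_equal(co2[[i]]$incident_energy_keV, co[[i]]$incident_energy_keV)
    expect_equal(co2[[i]]$events$deposit_eV, co[[i]]$events$deposit_eV,
                 tolerance = 1e-6)
    expect_equal(co2[[i]]$events$x_nm, co[[i]]$events$x_nm,
                 tolerance = 1e-6)
  }
})
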