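test_that("mean chord length follows the Cauchy formula for a sphere", {
  expect_equal(domain_spec(1)$mean_chord_um, 2 / 3)
  expect_equal(domain_spec(0.3)$mean_chord_um, 0.2)
  expect_error(domain_spec(0), "positive")
})

test_that("a fully contained deposit scores y = epsilon / l", {
  t1 <- manual_track(0, 0, 0, 1000, e_in_keV = 1) # 1 keV point deposit
  s <- lineal_energy_samples(t1, domain_spec(1), 300, seed = 3)
  expect_gt(nrow(s), 0)
  expect_equal(unique(round(s$y, 9)), 1.5) # 1 keV / (2/3 um)
  # additivity: two co-located deposits of 0.4 and 0.6 keV
  t2 <- manual_track(c(0, 0.5), c(0, 0), c(0, 0), c(400, 600), e_in_keV = 1)
  s2 <- lineal_energy_samples(t2, domain_spec(1), 300, seed = 3)
  expect_true(all(abs(s2$y - 1.5) < 1e-9 | abs(s2$y - 0.6) < 1e-9 |
                    abs(s2$y - 0.9) < 1e-9))
  expect_true(any(abs(s2$y - 1.5) < 1e-9)) # both inside for central sites
})

test_that("site sampling is deterministic and rejects empty input", {
  tr <- simulate_track(5, seed = 8)
  a <- lineal_energy_samples(tr, n_domains = 200, seed = 12)
  b <- lineal_energy_samples(tr, n_domains = 200, seed = 12)
  expect_identical(a, b)
  empty <- manual_track(numeric(0), numeric(0), numeric(0), numeric(0),
                        e_in_keV = 1)
  expect_error(lineal_energy_samples(empty), "nothing to score")
})

test_that("importance and uniform placement agree on a compact track", {
  tr <- simulate_track(3, seed = 44) # few hundred nm extent
  yD <- function(m, sd) {
    s <- lineal_energy_samples(tr, domain_spec(1), 30000, seed = sd,
                               method = m)
    d <- build_distribution(s)
    d$y_D
  }
  imp <- yD("importance", 5)
  uni <- yD("uniform", 6)
  expect_equal(imp, uni, tolerance = 0.05)
})

test_that("degenerate sample sets give y_F = y_D at the sample value", {
  d <- build_distribution(rep(2.5, 100))
  expect_equal(d$y_F, d$y_D)
  expect_equal(d$y_D, 2.5, tolerance = 0.025) # within one log bin
  d2 <- build_distribution(c(1, 3, 1, 3))
  expect_equal(d2$y_D, 2.5, tolerance = 0.03)
})

test_that("f and d normalize, d is proportional to y f, y_D >= y_F", {
  set.seed(71)
  for (rep in 1:5) {
    y <- stats::rlnorm(2000, meanlog = stats::runif(1, -1, 1),
                       sdlog = stats::runif(1, 0.2, 1))
    d <- build_distribution(y)
    dy <- diff(d$y_edges)
    expect_equal(sum(d$f_y * dy), 1, tolerance = 1e-9)
    expect_equal(sum(d$d_y * dy), 1, tolerance = 1e-9)
    q <- d$y_mid * d$f_y
    expect_equal(d$d_y, q / sum(q * dy), tolerance = 1e-9)
    expect_gte(d$y_D, d$y_F)
  }
})

test_that("binned y_D stays within 1% of the raw moment ratio", {
  co <- simulate_cohort(trackRBE:::new_electron_spectrum(30, 1), 20,
                        seed = 5)
  s <- lineal_energy_samples(co, n_domains = 20000, seed = 6)
  d <- build_distribution(s)
  raw <- sum(s$weight * s$y^2) / sum(s$weight * s$y)
  expect_equal(d$y_D, raw, tolerance = 0.01)
})

test_that("a uniform lineal-energy density on (0, 2] has y_D = 4/3", {
  set.seed(13)
  y <- stats::runif(2e5, 0, 2)
  d <- build_distribution(y[y > 0])
  expect_equal(d$y_D, 4 / 3, tolerance = 0.01)
})

test_that("invalid samples are rejected", {
  expect_error(build_distribution(numeric(0)), "at least one")
  expect_error(build_distribution(c(1, -2)), "positive")
  expect_error(build_distribution(c(1, 2), weights = c(1, -1)),
               "non-negative")
})

test_that("denser clustering raises y_D at fixed incident energy", {
  dense_curve <- default_track_params()$curve
  dense_curve$cluster_spacing_nm <- dense_curve$cluster_spacing_nm / 3
  dense <- default_track_params(curve = dense_curve)
  yD <- function(p, sd) {
    co <- lapply(1:30, function(i) simulate_track(20, p, derive_seed(sd, i)))
    dose_mean_lineal_energy(co, n_domains = 15000, seed = sd)$y_D
  }
  expect_gt(yD(dense, 91), yD(default_track_params(), 92))
})

test_that("distribution CSV export writes a readable table", {
  d <- build_distribution(c(1, 2, 3, 4))
  path <- tempfile(fileext = ".csv")
  write_ydist_csv(d, path, domain = domain_spec(1))
  df <- utils::read.csv(path, comment.char = "#")
  expect_equal(names(df), c("y_low", "y_high", "f_y", "d_y"))
  expect_equal(sum(df$f_y * (df$y_high - df$y_low)), 1, tolerance = 1e-6)
})
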