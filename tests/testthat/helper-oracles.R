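# Independent all-pairs linkage oracle: plain R, squared distances,
# inclusive boundary. Quadratic on purpose -- it checks the cell-list path.
brute_force_pairs <- function(ev, r_nm) {
  n <- nrow(ev)
  if (n < 2) return(0)
  xyz <- as.matrix(ev[, c("x_nm", "y_nm", "z_nm")])
  cnt <- 0
  for (i in seq_len(n - 1)) {
    d2 <- (xyz[(i + 1):n, 1] - xyz[i, 1])^2 +
      (xyz[(i + 1):n, 2] - xyz[i, 2])^2 +
      (xyz[(i + 1):n, 3] - xyz[i, 3])^2
    cnt <- cnt + sum(d2 <= r_nm^2)
  }
  cnt
}

# build a bare track object from explicit event coordinates
manual_track <- function(x, y, z, dep_eV, e_in_keV = sum(dep_eV) / 1000) {
  ev <- data.frame(x_nm = x, y_nm = y, z_nm = z, deposit_eV = dep_eV,
                   kind = rep("ionization", length(x)))
  trackRBE:::new_track(ev, e_in_keV, c(seed = NA_integer_))
}

# cohort-aggregate link and event densities per keV (ratio of sums)
cohort_link_ratio <- function(energy_keV, n_tracks, seed,
                              params = default_track_params()) {
  ge <- gl <- numeric(n_tracks)
  for (i in seq_len(n_tracks)) {
    tr <- simulate_track(energy_keV, params, derive_seed(seed, i))
    ge[i] <- nrow(tr$events)
    gl[i] <- count_linkages(tr)
  }
  sum(gl) / sum(ge)
}

# random rigid rotation matrix from a seed
random_rotation <- function(seed) {
  set.seed(seed)
  qr_res <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_res)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
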