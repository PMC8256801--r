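#!/usr/bin/env Rscript
# Step 0 (one-off): the calibration that produced the shipped tables
# inst/extdata/track_model_curves.csv (cluster_sigma_nm column) and
# inst/extdata/spectrum_calibration.csv (mean_energy_keV column).
#
# The shipped package already contains the frozen results; this script
# documents and reproduces the protocol (vignette section 4). It takes
# ~20 minutes on one CPU and writes its outputs under results/ -- it
# never overwrites the shipped tables.
#
# Stage 1: with the energy-per-event and stopping-power-tied spacing
#   curves fixed, solve the within-cluster sigma at each tabulated
#   energy so the link-to-event ratio follows the linear relation
#   implied by the published per-point yields and ratios.
# Stage 2: with track response frozen, measure the per-bin link density
#   on the 200-bin spectrum grid and solve each point's spectrum mean
#   energy so the weighted DSB yield equals its anchor value in
#   inst/extdata/calibration_targets.csv.

library(trackRBE)
dir.create("results", showWarnings = FALSE)
k_dsb <- damage_constants()$k_dsb

targets <- read.csv(system.file("extdata", "calibration_targets.csv",
                                package = "trackRBE"))
curve <- default_track_params()$curve

# linear link-ratio relation fitted to the published anchors:
# r(g_e) with g_e = N_event/E_in and r = N_link/N_event
r_line <- function(ge) 1.23376 + 0.0190536 * ge

measure <- function(curve, E, n, seed0) {
  p <- default_track_params(curve = curve)
  ge <- gl <- numeric(n)
  for (i in seq_len(n)) {
    ct <- trackRBE:::track_counts(E, p, derive_seed(seed0, i))
    ge[i] <- ct[["n_event"]] / E
    gl[i] <- ct[["n_link"]] / E
  }
  c(ge = mean(ge), gl = mean(gl), r = mean(gl) / mean(ge))
}
n_for <- function(E) max(60, min(3000, round(30000 / E)))

## Stage 1 -- sigma(E), low energies first (higher-energy tracks carry
## their own slowing-down ends, so sweeps are repeated until stable)
message("stage 1: solving cluster sigma per tabulated energy ...")
ge_hat <- sapply(seq_len(nrow(curve)), function(i)
  measure(curve, curve$energy_keV[i], n_for(curve$energy_keV[i]),
          1000 + i)["ge"])
r_tgt <- r_line(ge_hat)
for (sweep in 1:3) {
  for (i in seq_len(nrow(curve))) {
    E <- curve$energy_keV[i]; n <- n_for(E)
    f <- function(s) {
      cu <- curve; cu$cluster_sigma_nm[i] <- s
      measure(cu, E, n, 2000 + i)["r"] - r_tgt[i]
    }
    s0 <- curve$cluster_sigma_nm[i]; f0 <- f(s0)
    s1 <- s0 * ifelse(f0 > 0, 1.25, 0.8); f1 <- f(s1)
    for (it in 1:6) {
      if (abs(f1) < 0.004 || abs(f1 - f0) < 1e-9) break
      s2 <- max(0.3, min(4, s1 - f1 * (s1 - s0) / (f1 - f0)))
      s0 <- s1; f0 <- f1; s1 <- s2; f1 <- f(s1)
    }
    curve$cluster_sigma_nm[i] <- s1
  }
  message(sprintf("  sweep %d done", sweep))
}
write.csv(curve, "results/track_model_curves_recalibrated.csv",
          row.names = FALSE)

## Stage 2 -- per-bin response, then one root-find per spectrum
message("stage 2: measuring per-bin link density (the slow part) ...")
edges <- exp(seq(log(1), log(1000), length.out = 201))
mids <- sqrt(edges[-1] * edges[-201])
gl_bin <- sapply(seq_along(mids), function(b) {
  E <- mids[b]
  n <- max(40, min(4000, round(20000 / E)))
  measure(curve, E, n, derive_seed(5555, b))["gl"]
})
gl_fun <- approxfun(log(mids), gl_bin, rule = 2)

pred_gl <- function(mu, p_tail, e_max) {
  sp <- generate_spectrum(spectrum_model_params(
    mu, shape = 1.6, low_energy_fraction = p_tail, e_max_keV = e_max), 200)
  sum(sp$weight * gl_fun(log(sp$energy_keV)))
}
tail_for <- function(field, lateral_cm) {
  if (field == "FF_6MV") 0.04 + 0.012 * lateral_cm
  else if (field == "FFF_6MV") 0.05 + 0.015 * lateral_cm
  else 0.10
}
message("stage 2: solving spectrum means per point ...")
rows <- lapply(seq_len(nrow(targets)), function(i) {
  tg <- targets[i, ]
  e_max <- if (tg$field == "REF_220KVP") 220 else 1000
  p_tail <- tail_for(tg$field, tg$lateral_cm)
  gl_t <- tg$y_dsb_target_1e11 * 1e-11 / k_dsb
  mu <- uniroot(function(m) pred_gl(m, p_tail, e_max) - gl_t,
                if (e_max < 1000) c(25, 180) else c(25, 950),
                tol = 1e-7)$root
  data.frame(field = tg$field, depth_cm = tg$depth_cm,
             lateral_cm = tg$lateral_cm, family = "gamma_exp",
             mean_energy_keV = round(mu, 4), shape = 1.6,
             low_energy_fraction = p_tail, e_min_keV = 1,
             e_max_keV = e_max)
})
out <- do.call(rbind, rows)
write.csv(out, "results/spectrum_calibration_recalibrated.csv",
          row.names = FALSE, quote = FALSE)

shipped <- read.csv(system.file("extdata", "spectrum_calibration.csv",
                                package = "trackRBE"), comment.char = "#")
dev <- max(abs(out$mean_energy_keV - shipped$mean_energy_keV) /
             shipped$mean_energy_keV)
cat(sprintf("max relative deviation from shipped means: %.3f\n", dev))
cat("(nonzero deviation reflects Monte-Carlo noise in the response",
    "measurement;\n the shipped tables are the frozen originals)\n")
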