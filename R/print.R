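#' @export
print.electron_spectrum <- function(x, ...) {
  cat(sprintf("<electron_spectrum> %s", x$field))
  if (!is.na(x$depth_cm))
    cat(sprintf(" at depth %g cm, lateral %g cm", x$depth_cm, x$lateral_cm))
  cat(sprintf("\n  %d bins on [%.3g, %.3g] keV, mean energy %.1f keV\n",
              length(x$energy_keV), min(x$energy_keV), max(x$energy_keV),
              spectrum_mean_energy(x)))
  invisible(x)
}

#' @export
print.electron_track <- function(x, ...) {
  cat(sprintf("<electron_track> E_in = %g keV, %d events, %.3g keV deposited\n",
              x$incident_energy_keV, nrow(x$events),
              sum(x$events$deposit_eV) / 1000))
  invisible(x)
}

#' @export
print.track_cohort <- function(x, ...) {
  e <- vapply(x, `[[`, numeric(1), "incident_energy_keV")
  cat(sprintf("<track_cohort> %d tracks, E_in %.3g-%.3g keV (mean %.3g)\n",
              length(x), min(e), max(e), mean(e)))
  invisible(x)
}

#' @export
print.strand_break_yields <- function(x, ...) {
  cat(sprintf(paste0("<strand_break_yields> (%d tracks)\n",
                     "  Y_SSB = %.4g /Gy/Da (se %.2g)\n",
                     "  Y_DSB = %.4g /Gy/Da (se %.2g)\n",
                     "  DSB/SSB = %.4g (se %.2g)\n"),
              x$n_tracks, x$y_ssb, x$y_ssb_se, x$y_dsb, x$y_dsb_se,
              x$dsb_ssb_ratio, x$ratio_se))
  invisible(x)
}

#' @export
print.lineal_energy_distribution <- function(x, ...) {
  cat(sprintf(paste0("<lineal_energy_distribution> %d samples",
                     " (%d outside binning)\n",
                     "  y_F = %.4g keV/um, y_D = %.4g keV/um\n"),
              x$n_samples, x$n_dropped, x$y_F, x$y_D))
  invisible(x)
}
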