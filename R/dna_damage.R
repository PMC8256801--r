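#' Strand-break proportionality constants
#'
#' The published coefficients converting per-keV event and linkage
#' counts into strand-break yields per gray per dalton of DNA:
#' `k_ssb = 5.66e-12` and `k_dsb = 1.61e-13` keV/Gy/Da, and the 3.4 nm
#' (10 base-pair) linkage distance. Overridable only via the arguments.
#'
#' @param k_ssb,k_dsb proportionality coefficients (keV/Gy/Da).
#' @param linkage_distance_nm pairing distance (nm).
#' @return object of class `damage_constants`.
#' @export
damage_constants <- function(k_ssb = 5.66e-12, k_dsb = 1.61e-13,
                             linkage_distance_nm = 3.4) {
  if (k_ssb <= 0 || k_dsb <= 0 || linkage_distance_nm <= 0)
    abort("all damage constants must be positive")
  structure(list(k_ssb = k_ssb, k_dsb = k_dsb,
                 linkage_distance_nm = linkage_distance_nm),
            class = "damage_constants")
}

#' Count events in a track
#'
#' All events count, ionizations and excitations alike: both lesion
#' types contribute to strand breaks, and any per-kind sampling detail is
#' absorbed by the proportionality coefficients.
#'
#' @param track an `electron_track` (or its events data.frame).
#' @return integer N_event.
#' @export
count_events <- function(track) {
  ev <- if (inherits(track, "electron_track")) track$events else track
  nrow(ev)
}

#' Count 3.4 nm event-pair linkages in a track
#'
#' Number of unordered event pairs with Euclidean separation less than
#' or equal to `r_nm` (inclusive boundary). All pairs count, not only
#' consecutive events, so one event may participate in many pairs.
#' Exact and deterministic (cell-list spatial index).
#'
#' @param track an `electron_track` or a data.frame with `x_nm`, `y_nm`,
#'   `z_nm`.
#' @param r_nm pairing distance in nm (> 0); default 3.4.
#' @return numeric N_link.
#' @export
count_linkages <- function(track, r_nm = 3.4) {
  if (!is.numeric(r_nm) || r_nm <= 0) abort("r_nm must be positive")
  ev <- if (inherits(track, "electron_track")) track$events else track
  cpp_count_pairs(ev$x_nm, ev$y_nm, ev$z_nm, r_nm)
}

#' Per-track strand-break counts
#'
#' @param track an `electron_track`.
#' @param r_nm linkage distance in nm.
#' @return object of class `strand_break_counts` with `n_event`,
#'   `n_link`, `e_in_keV`.
#' @export
strand_break_counts <- function(track, r_nm = 3.4) {
  stopifnot(inherits(track, "electron_track"))
  structure(list(n_event = count_events(track),
                 n_link = count_linkages(track, r_nm),
                 e_in_keV = track$incident_energy_keV),
            class = "strand_break_counts")
}

#' Single-strand-break yield
#'
#' `Y_SSB = k_ssb * N_event / E_in`, in /Gy/Da.
#'
#' @param counts a `strand_break_counts` (or list with `n_event`,
#'   `e_in_keV`).
#' @param constants a [damage_constants()].
#' @return Y_SSB in /Gy/Da.
#' @export
ssb_yield <- function(counts, constants = damage_constants()) {
  if (is.null(counts$e_in_keV) || counts$e_in_keV <= 0)
    abort("e_in_keV must be positive")
  constants$k_ssb * counts$n_event / counts$e_in_keV
}

#' Double-strand-break yield
#'
#' `Y_DSB = k_dsb * N_link / E_in`, in /Gy/Da.
#'
#' @param counts a `strand_break_counts` (or list with `n_link`,
#'   `e_in_keV`).
#' @param constants a [damage_constants()].
#' @return Y_DSB in /Gy/Da.
#' @export
dsb_yield <- function(counts, constants = damage_constants()) {
  if (is.null(counts$e_in_keV) || counts$e_in_keV <= 0)
    abort("e_in_keV must be positive")
  constants$k_dsb * counts$n_link / counts$e_in_keV
}

#' Spectrum-averaged strand-break yields
#'
#' Simulates `n_tracks_per_bin` tracks at each energy of the spectrum
#' grid, computes the per-bin mean yields, and combines them with the
#' spectrum's normalized fluence-times-energy (dose) weights:
#' `Y = sum_b w_b * mean_b(k * N / E_b)`. The DSB/SSB ratio is the ratio
#' of the averaged yields, so the exact identity
#' `Y_DSB / Y_SSB = (k_dsb / k_ssb) * (N_link / N_event)` holds on the
#' weighted aggregates. Monte-Carlo standard errors come from the
#' per-track variances within each bin; the ratio standard error uses
#' the first-order delta method with the per-bin covariance.
#' Reproducible given `seed` (per-bin, per-track derived streams).
#'
#' @param spectrum an `electron_spectrum`.
#' @param params a [default_track_params()].
#' @param n_tracks_per_bin tracks per spectrum bin (>= 1).
#' @param constants a [damage_constants()].
#' @param seed master seed.
#' @return object of class `strand_break_yields`: `y_ssb`, `y_dsb`
#'   (/Gy/Da), `dsb_ssb_ratio`, standard errors `y_ssb_se`, `y_dsb_se`,
#'   `ratio_se`, aggregates `events_per_keV`, `links_per_keV`, and
#'   `n_tracks`.
#' @export
spectrum_averaged_yields <- function(spectrum,
                                     params = default_track_params(),
                                     n_tracks_per_bin = 10,
                                     constants = damage_constants(),
                                     seed = 1L) {
  stopifnot(inherits(spectrum, "electron_spectrum"))
  if (!is_count(n_tracks_per_bin))
    abort("n_tracks_per_bin must be a count >= 1")
  nb <- length(spectrum$energy_keV)
  if (nb == 0 || sum(spectrum$weight) <= 0) abort("spectrum is empty")
  w <- spectrum$weight
  r_nm <- constants$linkage_distance_nm
  mean_ge <- mean_gl <- var_ge <- var_gl <- cov_gegl <- numeric(nb)
  for (b in seq_len(nb)) {
    if (w[b] == 0) next
    e <- spectrum$energy_keV[b]
    ge <- gl <- numeric(n_tracks_per_bin)
    for (t in seq_len(n_tracks_per_bin)) {
      ct <- track_counts(e, params, derive_seed(seed, b, t), r_nm)
      ge[t] <- ct[["n_event"]] / e
      gl[t] <- ct[["n_link"]] / e
    }
    mean_ge[b] <- mean(ge); mean_gl[b] <- mean(gl)
    if (n_tracks_per_bin > 1) {
      var_ge[b] <- stats::var(ge) / n_tracks_per_bin
      var_gl[b] <- stats::var(gl) / n_tracks_per_bin
      cov_gegl[b] <- stats::cov(ge, gl) / n_tracks_per_bin
    }
  }
  ge_bar <- sum(w * mean_ge) # weighted events per keV
  gl_bar <- sum(w * mean_gl) # weighted linkages per keV
  ge_var <- sum(w^2 * var_ge)
  gl_var <- sum(w^2 * var_gl)
  gegl_cov <- sum(w^2 * cov_gegl)
  y_ssb <- constants$k_ssb * ge_bar
  y_dsb <- constants$k_dsb * gl_bar
  ratio <- y_dsb / y_ssb
  ratio_se <- abs(ratio) * sqrt(gl_var / gl_bar^2 + ge_var / ge_bar^2 -
                                  2 * gegl_cov / (ge_bar * gl_bar))
  structure(list(y_ssb = y_ssb, y_dsb = y_dsb, dsb_ssb_ratio = ratio,
                 y_ssb_se = constants$k_ssb * sqrt(ge_var),
                 y_dsb_se = constants$k_dsb * sqrt(gl_var),
                 ratio_se = ratio_se, events_per_keV = ge_bar,
                 links_per_keV = gl_bar,
                 n_tracks = n_tracks_per_bin * sum(w > 0)),
            class = "strand_break_yields")
}

#' @importFrom stats cov
NULL
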