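#' Track-structure model parameters
#'
#' The simulator is a compound cluster process: cluster centres are laid
#' along a randomly scattered polyline with exponential inter-cluster
#' spacings; each cluster holds `1 + Poisson(cluster_mean_multiplicity - 1)`
#' events displaced isotropically (Gaussian) around the centre; per-event
#' deposits are exponential. Three quantities vary with the electron's
#' current energy and ship as tabulated curves on `energy_keV`:
#'
#' * `ev_per_event` -- mean energy per event (eV), setting N_event/E_in;
#' * `cluster_sigma_nm` -- within-cluster spread, setting how many event
#'   pairs fall within the 3.4 nm linkage distance;
#' * `cluster_spacing_nm` -- mean centre-to-centre spacing, tied to the
#'   electron collision stopping power of water so that the linear energy
#'   density along the track is physical.
#'
#' Curves are interpolated linearly in log10(energy) and clamped at the
#' tabulated ends. Electrons are followed to full stop; an incident
#' energy below `cutoff_keV` becomes a single local deposit.
#'
#' @param curve data.frame with columns `energy_keV`, `ev_per_event`,
#'   `cluster_sigma_nm`, `cluster_spacing_nm`; default: the shipped
#'   calibrated table.
#' @param cluster_mean_multiplicity mean events per cluster (>= 1).
#' @param cutoff_keV tracking cut-off energy (default 1.0 keV).
#' @param ionization_prob Bernoulli probability that an event is an
#'   ionization rather than an excitation; carried in the event record
#'   but not used by the damage arithmetic.
#' @return object of class `track_model_params`.
#' @export
default_track_params <- function(curve = NULL,
                                 cluster_mean_multiplicity = 5,
                                 cutoff_keV = 1.0,
                                 ionization_prob = 0.5) {
  if (is.null(curve)) {
    if (is.null(.trackRBE_cache$track_curve)) {
      path <- system.file("extdata", "track_model_curves.csv",
                          package = "trackRBE", mustWork = TRUE)
      .trackRBE_cache$track_curve <- utils::read.csv(path,
                                                     comment.char = "#")
    }
    curve <- .trackRBE_cache$track_curve
  }
  need <- c("energy_keV", "ev_per_event", "cluster_sigma_nm",
            "cluster_spacing_nm")
  if (!all(need %in% names(curve)))
    abort("curve must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(as.matrix(curve[need]))) || any(curve$energy_keV <= 0) ||
      any(curve$ev_per_event <= 0) || any(curve$cluster_sigma_nm <= 0) ||
      any(curve$cluster_spacing_nm <= 0))
    abort("all curve values must be finite and positive")
  if (is.unsorted(curve$energy_keV, strictly = TRUE))
    abort("curve energy grid must be strictly increasing")
  if (!is.finite(cluster_mean_multiplicity) || cluster_mean_multiplicity < 1)
    abort("cluster_mean_multiplicity must be >= 1")
  if (!is.finite(cutoff_keV) || cutoff_keV <= 0)
    abort("cutoff_keV must be positive")
  if (ionization_prob < 0 || ionization_prob > 1)
    abort("ionization_prob must lie in [0, 1]")
  structure(list(curve = curve[need],
                 cluster_mean_multiplicity = cluster_mean_multiplicity,
                 cutoff_keV = cutoff_keV,
                 ionization_prob = ionization_prob),
            class = "track_model_params")
}

new_track <- function(events, incident_energy_keV, seed_info) {
  structure(list(events = events,
                 incident_energy_keV = incident_energy_keV,
                 seed_info = seed_info),
            class = "electron_track")
}

#' Simulate one electron track
#'
#' Generates the event list of a single electron of incident energy
#' `e_in_keV` stopping in liquid water. Energy is conserved exactly: the
#' final event absorbs the residual. Deterministic given
#' `(e_in_keV, params, seed)`.
#'
#' @param e_in_keV incident electron energy in keV (> 0). Below the
#'   tracking cut-off the track is a single local event carrying all of
#'   `e_in_keV`.
#' @param params a [default_track_params()] object.
#' @param seed integer seed for this track.
#' @return object of class `electron_track`: `events` (data.frame with
#'   `x_nm`, `y_nm`, `z_nm`, `deposit_eV`, `kind`), `incident_energy_keV`
#'   and `seed_info`.
#' @export
simulate_track <- function(e_in_keV, params = default_track_params(),
                           seed = 1L) {
  stopifnot(inherits(params, "track_model_params"))
  if (!is.numeric(e_in_keV) || length(e_in_keV) != 1 ||
      !is.finite(e_in_keV) || e_in_keV <= 0)
    abort("e_in_keV must be a single positive finite energy")
  set.seed(seed)
  cu <- params$curve
  raw <- cpp_simulate_track(e_in_keV, log10(cu$energy_keV),
                            cu$ev_per_event, cu$cluster_sigma_nm,
                            cu$cluster_spacing_nm,
                            params$cluster_mean_multiplicity - 1,
                            params$cutoff_keV, params$ionization_prob)
  events <- data.frame(x_nm = raw$x_nm, y_nm = raw$y_nm, z_nm = raw$z_nm,
                       deposit_eV = raw$deposit_eV,
                       kind = ifelse(raw$ion == 1L, "ionization",
                                     "excitation"))
  new_track(events, e_in_keV, c(seed = as.integer(seed)))
}

# fused generate+count path; same RNG stream as simulate_track
track_counts <- function(e_in_keV, params, seed, r_link_nm = 3.4) {
  set.seed(seed)
  cu <- params$curve
  ct <- cpp_track_counts(e_in_keV, log10(cu$energy_keV), cu$ev_per_event,
                         cu$cluster_sigma_nm, cu$cluster_spacing_nm,
                         params$cluster_mean_multiplicity - 1,
                         params$cutoff_keV, params$ionization_prob,
                         r_link_nm)
  c(n_event = ct[1], n_link = ct[2])
}

#' Simulate a cohort of tracks from an electron spectrum
#'
#' Samples `n_tracks` incident energies from the spectrum's weights, then
#' simulates each track with a per-track seed derived from `seed` by a
#' counter-based scheme, so the cohort is reproducible and independent of
#' iteration order.
#'
#' @param spectrum an `electron_spectrum`.
#' @param n_tracks number of tracks (>= 1).
#' @param params a [default_track_params()] object.
#' @param seed master seed.
#' @return list of `electron_track` objects, class `track_cohort`.
#' @export
simulate_cohort <- function(spectrum, n_tracks,
                            params = default_track_params(), seed = 1L) {
  stopifnot(inherits(spectrum, "electron_spectrum"))
  if (!is_count(n_tracks)) abort("n_tracks must be a count >= 1")
  if (length(spectrum$energy_keV) == 0 || sum(spectrum$weight) <= 0)
    abort("spectrum is empty")
  set.seed(derive_seed(seed, 0))
  idx <- sample.int(length(spectrum$energy_keV), n_tracks, replace = TRUE,
                    prob = spectrum$weight)
  energies <- spectrum$energy_keV[idx]
  tracks <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    tracks[[i]] <- simulate_track(energies[i], params,
                                  derive_seed(seed, i))
  }
  structure(tracks, class = "track_cohort",
            master_seed = as.integer(seed))
}

#' Events per keV across tracks
#'
#' Per-track ratio N_event/E_in, averaged over tracks, with the standard
#' error of the mean (zero for a single track).
#'
#' @param tracks a `track_cohort`, a list of tracks, or one
#'   `electron_track`.
#' @return list with `mean` and `se` (per keV), plus `per_track`.
#' @export
events_per_keV <- function(tracks) {
  tracks <- as_track_list(tracks)
  r <- vapply(tracks, function(t) nrow(t$events) / t$incident_energy_keV,
              numeric(1))
  se <- if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else 0
  list(mean = mean(r), se = se, per_track = r)
}

as_track_list <- function(tracks) {
  if (inherits(tracks, "electron_track")) return(list(tracks))
  if (inherits(tracks, "track_cohort") || is.list(tracks)) {
    if (length(tracks) == 0) abort("no tracks supplied")
    return(tracks)
  }
  abort("expected an electron_track, a track_cohort, or a list of tracks")
}

#' Write / read a track cohort as TSV
#'
#' Columns `track_id`, `event_id`, `x_nm`, `y_nm`, `z_nm`, `deposit_eV`,
#' `kind`; a `# incident_energy_keV=` comment per track carries the
#' incident energies. Gzip-compressed paths (`.gz`) are accepted.
#'
#' @param tracks a `track_cohort` or list of `electron_track`s.
#' @param path output path (`.tsv` or `.tsv.gz`).
#' @return `write_cohort_tsv` returns `path` invisibly; `read_cohort_tsv`
#'   returns a `track_cohort`.
#' @export
write_cohort_tsv <- function(tracks, path) {
  tracks <- as_track_list(tracks)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  e_in <- vapply(tracks, function(t) t$incident_energy_keV, numeric(1))
  writeLines(sprintf("# incident_energy_keV=%s",
                     paste(sprintf("%.12g", e_in), collapse = ",")), con)
  writeLines(paste("track_id", "event_id", "x_nm", "y_nm", "z_nm",
                   "deposit_eV", "kind", sep = "\t"), con)
  for (i in seq_along(tracks)) {
    ev <- tracks[[i]]$events
    writeLines(sprintf("%d\t%d\t%.9g\t%.9g\t%.9g\t%.9g\t%s", i,
                       seq_len(nrow(ev)), ev$x_nm, ev$y_nm, ev$z_nm,
                       ev$deposit_eV, ev$kind), con)
  }
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  meta <- lines[startsWith(lines, "#")]
  e_in <- as.numeric(strsplit(sub("# incident_energy_keV=", "", meta[1],
                                  fixed = TRUE), ",")[[1]])
  df <- utils::read.csv(text = paste(lines[!startsWith(lines, "#")],
                                     collapse = "\n"), sep = "\t")
  tracks <- lapply(seq_along(e_in), function(i) {
    ev <- df[df$track_id == i,
             c("x_nm", "y_nm", "z_nm", "deposit_eV", "kind")]
    rownames(ev) <- NULL
    new_track(ev, e_in[i], c(seed = NA_integer_))
  })
  structure(tracks, class = "track_cohort")
}
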