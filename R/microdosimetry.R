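#' Spherical scoring-site specification
#'
#' A spherical site of the given diameter; the mean chord length follows
#' the Cauchy formula for convex bodies, `l = (2/3) d` for a sphere. The
#' conventional 1 micrometre site is the default.
#'
#' @param diameter_um sphere diameter in micrometres (> 0).
#' @return object of class `domain_spec` with `diameter_um` and
#'   `mean_chord_um`.
#' @export
domain_spec <- function(diameter_um = 1.0) {
  if (!is.numeric(diameter_um) || length(diameter_um) != 1 ||
      !is.finite(diameter_um) || diameter_um <= 0)
    abort("diameter_um must be a single positive number")
  structure(list(diameter_um = diameter_um,
                 mean_chord_um = 2 / 3 * diameter_um),
            class = "domain_spec")
}

#' Sample lineal energies from tracks
#'
#' Scores spherical sites placed at random over each track's
#' neighbourhood under the uniform-volume measure: every scored site
#' carries a weight equal to the volume it represents, so sites sample
#' space uniformly and tracks of different spatial extent contribute per
#' unit volume. Each site containing at least one event scores the
#' lineal energy `y = epsilon / l`, where `epsilon` is the summed energy
#' deposit inside the site and `l` the mean chord length; empty sites
#' are not scored (single-event distribution convention). Deterministic
#' given `seed`.
#'
#' Two placement estimators of the same measure are available.
#' `"importance"` (default) draws each centre as a uniform offset within
#' one site radius (Chebyshev) of a randomly chosen event and weights
#' the sample by the inverse placement density, `V_cube / m(c)`, with
#' `m(c)` the number of events whose offset cube contains the centre;
#' this concentrates sites on the track envelope and is usable for
#' centimetre-range electrons. `"uniform"` draws centres uniformly over
#' the track's bounding box inflated by one diameter (weight
#' `V_box / n`); it is simple but almost never hits a long track, so it
#' is practical only for spatially small tracks.
#'
#' @param tracks a `track_cohort`, list of tracks, or one track.
#' @param domain a [domain_spec()].
#' @param n_domains total number of sites, split evenly across tracks.
#' @param seed integer seed.
#' @param method `"importance"` or `"uniform"` site placement.
#' @return data.frame with columns `y` (keV/um), `weight` (nm^3 per
#'   site) and `track`.
#' @export
lineal_energy_samples <- function(tracks, domain = domain_spec(),
                                  n_domains = 1000, seed = 1L,
                                  method = c("importance", "uniform")) {
  tracks <- as_track_list(tracks)
  method <- match.arg(method)
  stopifnot(inherits(domain, "domain_spec"))
  if (!is_count(n_domains)) abort("n_domains must be a count >= 1")
  n_ev <- vapply(tracks, function(t) nrow(t$events), integer(1))
  if (sum(n_ev) == 0) abort("no events in any track: nothing to score")
  radius_nm <- domain$diameter_um * 1000 / 2
  n_per <- max(1L, as.integer(ceiling(n_domains / length(tracks))))
  out <- vector("list", length(tracks))
  for (i in seq_along(tracks)) {
    ev <- tracks[[i]]$events
    if (nrow(ev) == 0) next
    set.seed(derive_seed(seed, i))
    if (method == "uniform") {
      infl <- domain$diameter_um * 1000
      lo <- c(min(ev$x_nm), min(ev$y_nm), min(ev$z_nm)) - infl
      hi <- c(max(ev$x_nm), max(ev$y_nm), max(ev$z_nm)) + infl
      cx <- stats::runif(n_per, lo[1], hi[1])
      cy <- stats::runif(n_per, lo[2], hi[2])
      cz <- stats::runif(n_per, lo[3], hi[3])
      w <- rep(prod(hi - lo) / n_per, n_per)
    } else {
      j <- sample.int(nrow(ev), n_per, replace = TRUE)
      h <- radius_nm
      cx <- ev$x_nm[j] + stats::runif(n_per, -h, h)
      cy <- ev$y_nm[j] + stats::runif(n_per, -h, h)
      cz <- ev$z_nm[j] + stats::runif(n_per, -h, h)
      m <- cpp_count_in_cube(ev$x_nm, ev$y_nm, ev$z_nm, cx, cy, cz, h)
      # inverse of the placement density, per site
      w <- nrow(ev) * (2 * h)^3 / (m * n_per)
    }
    eps_eV <- cpp_score_spheres(ev$x_nm, ev$y_nm, ev$z_nm, ev$deposit_eV,
                                cx, cy, cz, radius_nm)
    hit <- eps_eV > 0
    if (!any(hit)) next
    out[[i]] <- data.frame(y = (eps_eV[hit] / 1000) / domain$mean_chord_um,
                           weight = w[hit], track = i)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(y = numeric(0), weight = numeric(0),
                                      track = integer(0))
  rownames(res) <- NULL
  res
}

#' Log-spaced lineal-energy binning
#'
#' @param y_min,y_max range in keV/um.
#' @param bins_per_decade bins per decade (default 50).
#' @return object of class `ydist_binning` holding the bin edges.
#' @export
ydist_binning <- function(y_min = 0.01, y_max = 1000, bins_per_decade = 50) {
  if (y_min <= 0 || y_max <= y_min) abort("need 0 < y_min < y_max")
  n <- ceiling(log10(y_max / y_min) * bins_per_decade)
  structure(list(edges = 10^seq(log10(y_min), log10(y_max),
                                length.out = n + 1)),
            class = "ydist_binning")
}

#' Build the microdosimetric distributions f(y) and d(y)
#'
#' Histograms lineal-energy samples into log-spaced bins, normalizes the
#' frequency distribution `f(y)`, forms the dose distribution
#' `d(y)` proportional to `y f(y)`, and computes the frequency-mean and
#' dose-mean lineal energies on the geometric bin midpoints:
#' `y_F = sum(y p) / sum(p)` and `y_D = sum(y^2 p) / sum(y p)`.
#' Samples outside the binning range are dropped (they are counted in
#' `n_dropped`).
#'
#' @param samples positive lineal-energy samples (keV/um), or the
#'   data.frame returned by [lineal_energy_samples()].
#' @param binning a [ydist_binning()].
#' @param weights optional non-negative per-sample weights.
#' @return object of class `lineal_energy_distribution`: `y_edges`,
#'   `y_mid`, `f_y`, `d_y` (densities), `y_F`, `y_D` (keV/um),
#'   `n_samples`, `n_dropped`.
#' @export
build_distribution <- function(samples, binning = ydist_binning(),
                               weights = NULL) {
  if (is.data.frame(samples)) {
    if (is.null(weights) && "weight" %in% names(samples))
      weights <- samples$weight
    samples <- samples$y
  }
  if (length(samples) < 1) abort("need at least one lineal-energy sample")
  if (any(!is.finite(samples)) || any(samples <= 0))
    abort("all lineal-energy samples must be positive and finite")
  if (is.null(weights)) weights <- rep(1, length(samples))
  if (length(weights) != length(samples) || any(weights < 0))
    abort("weights must be non-negative and match samples in length")
  stopifnot(inherits(binning, "ydist_binning"))
  edges <- binning$edges
  nb <- length(edges) - 1
  # bins are (low, high]; a sample exactly on a shared edge goes below
  idx <- findInterval(samples, edges, left.open = TRUE)
  keep <- idx >= 1 & idx <= nb & samples <= edges[nb + 1]
  if (!any(keep)) abort("all samples fall outside the binning range")
  mass <- numeric(nb)
  tm <- tapply(weights[keep], factor(idx[keep], levels = seq_len(nb)), sum)
  mass[!is.na(tm)] <- tm[!is.na(tm)]
  p <- mass / sum(mass)
  mids <- sqrt(edges[-1] * edges[-(nb + 1)])
  dy <- diff(edges)
  q <- mids * p
  q <- q / sum(q)
  y_F <- sum(mids * p)
  y_D <- sum(mids^2 * p) / sum(mids * p)
  structure(list(y_edges = edges, y_mid = mids, f_y = p / dy, d_y = q / dy,
                 y_F = y_F, y_D = y_D, n_samples = sum(keep),
                 n_dropped = sum(!keep)),
            class = "lineal_energy_distribution")
}

#' Dose-mean lineal energy of a track cohort
#'
#' Convenience composition of [lineal_energy_samples()] and
#' [build_distribution()].
#'
#' @inheritParams lineal_energy_samples
#' @param binning a [ydist_binning()].
#' @return list with `y_D`, `y_F` (keV/um), the full
#'   `lineal_energy_distribution` as `dist`, and the raw `samples`.
#' @export
dose_mean_lineal_energy <- function(tracks, domain = domain_spec(),
                                    n_domains = 1000,
                                    binning = ydist_binning(), seed = 1L) {
  s <- lineal_energy_samples(tracks, domain, n_domains, seed)
  if (nrow(s) == 0) abort("no site scored any energy; increase n_domains")
  d <- build_distribution(s, binning)
  list(y_D = d$y_D, y_F = d$y_F, dist = d, samples = s)
}

#' Write a lineal-energy distribution as CSV
#'
#' Columns `y_low`, `y_high`, `f_y`, `d_y`, with `y_F`, `y_D` and
#' `n_samples` in comment metadata.
#'
#' @param dist a `lineal_energy_distribution`.
#' @param path file path.
#' @param domain optional [domain_spec()] recorded in the metadata.
#' @return `path`, invisibly.
#' @export
write_ydist_csv <- function(dist, path, domain = NULL) {
  stopifnot(inherits(dist, "lineal_energy_distribution"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# y_F_keV_um=%.9g", dist$y_F),
               sprintf("# y_D_keV_um=%.9g", dist$y_D),
               sprintf("# n_samples=%d", dist$n_samples),
               if (!is.null(domain))
                 sprintf("# diameter_um=%g", domain$diameter_um),
               "y_low,y_high,f_y,d_y"), con)
  nb <- length(dist$y_mid)
  writeLines(sprintf("%.9g,%.9g,%.9g,%.9g", dist$y_edges[-(nb + 1)],
                     dist$y_edges[-1], dist$f_y, dist$d_y), con)
  invisible(path)
}
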