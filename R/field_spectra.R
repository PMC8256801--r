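#' Photon field identifiers
#'
#' The three beam qualities handled by the package: the flattened 6 MV
#' field (`"FF_6MV"`), the flattening-filter-free 6 MV field
#' (`"FFF_6MV"`), and the 220 kVp X-ray reference field (`"REF_220KVP"`)
#' used as the denominator of RBE_DSB.
#'
#' @return character vector of the three field kinds.
#' @export
field_kinds <- function() c("FF_6MV", "FFF_6MV", "REF_220KVP")

#' Default measurement grid in the water phantom
#'
#' Twelve points: depths 3, 5 and 10 cm on the central axis (in-field)
#' and 6, 8 and 10 cm lateral to the axis at each depth (out-of-field).
#' Ordered by depth, then lateral distance.
#'
#' @return data.frame with columns `depth_cm`, `lateral_cm`, `label`
#'   (e.g. `"d3_l0"`) and `in_field` (lateral distance zero).
#' @export
make_measurement_grid <- function() {
  depths <- c(3, 5, 10)
  laterals <- c(0, 6, 8, 10)
  g <- expand.grid(lateral_cm = laterals, depth_cm = depths,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("depth_cm", "lateral_cm")]
  g$label <- sprintf("d%g_l%g", g$depth_cm, g$lateral_cm)
  g$in_field <- g$lateral_cm == 0
  rownames(g) <- NULL
  g
}

#' Spectrum model parameters
#'
#' Parametric family for dose-weighted secondary-electron energy spectra.
#' The `"gamma_exp"` family mixes a gamma density (mean
#' `mean_energy_keV`, shape `shape`) with a low-energy exponential tail
#' (scale 8 keV) of mixture weight `low_energy_fraction`, truncated to
#' `[e_min_keV, e_max_keV]`. Two knobs -- the mean and the tail weight --
#' encode spectral softening with position and the FFF-vs-FF difference.
#'
#' @param mean_energy_keV mean of the gamma component (keV), > 0.
#' @param shape gamma shape parameter, > 0.
#' @param low_energy_fraction mixture weight of the low-energy tail, in
#'   `[0, 1]`.
#' @param e_min_keV,e_max_keV support bounds (keV); `e_min_keV` must not
#'   be below the 1 keV tracking cut-off.
#' @param family parametric family identifier; only `"gamma_exp"` is
#'   shipped.
#' @param field,depth_cm,lateral_cm optional provenance metadata.
#' @return object of class `spectrum_model_params`.
#' @export
spectrum_model_params <- function(mean_energy_keV, shape = 1.6,
                                  low_energy_fraction = 0.1,
                                  e_min_keV = 1.0, e_max_keV = 1000.0,
                                  family = "gamma_exp", field = NA_character_,
                                  depth_cm = NA_real_, lateral_cm = NA_real_) {
  if (!identical(family, "gamma_exp"))
    abort("unsupported spectrum family: ", family)
  if (!is.finite(mean_energy_keV) || mean_energy_keV <= 0)
    abort("mean_energy_keV must be positive")
  if (!is.finite(shape) || shape <= 0) abort("shape must be positive")
  if (low_energy_fraction < 0 || low_energy_fraction > 1)
    abort("low_energy_fraction must lie in [0, 1]")
  if (e_min_keV < 1.0 - 1e-9)
    abort("e_min_keV must not be below the 1 keV cut-off")
  if (e_min_keV >= e_max_keV) abort("e_min_keV must be below e_max_keV")
  structure(list(family = family, mean_energy_keV = mean_energy_keV,
                 shape = shape, low_energy_fraction = low_energy_fraction,
                 e_min_keV = e_min_keV, e_max_keV = e_max_keV,
                 field = field, depth_cm = depth_cm,
                 lateral_cm = lateral_cm),
            class = "spectrum_model_params")
}

# unnormalized dose-weighted spectral density of the gamma_exp family
gamma_exp_density <- function(e_keV, params) {
  tail_scale_keV <- 8.0 # fixed by the family definition
  th <- params$mean_energy_keV / params$shape
  (1 - params$low_energy_fraction) *
    stats::dgamma(e_keV, shape = params$shape, scale = th) +
    params$low_energy_fraction * stats::dexp(e_keV, rate = 1 / tail_scale_keV)
}

# shipped calibration table, cached
spectrum_calibration <- function() {
  if (is.null(.trackRBE_cache$calib)) {
    path <- system.file("extdata", "spectrum_calibration.csv",
                        package = "trackRBE", mustWork = TRUE)
    .trackRBE_cache$calib <- utils::read.csv(path, comment.char = "#")
  }
  .trackRBE_cache$calib
}

resolve_point <- function(point) {
  if (is.character(point)) {
    g <- make_measurement_grid()
    i <- match(point, g$label)
    if (is.na(i)) abort("unknown measurement point label: ", point)
    return(g[i, ])
  }
  if (is.numeric(point) && length(point) == 2)
    return(data.frame(depth_cm = point[1], lateral_cm = point[2]))
  if (is.list(point) && all(c("depth_cm", "lateral_cm") %in% names(point)))
    return(point)
  abort("point must be a grid label, c(depth, lateral), or a grid row")
}

#' Shipped spectrum parameters for a field at a measurement point
#'
#' Returns the calibrated `spectrum_model_params` for the given field and
#' grid point. The calibration ships with the package and encodes
#' spectral softening: at fixed depth the mean energy is non-increasing
#' with lateral distance, and the FFF spectrum is softer than FF at every
#' point. The 220 kVp reference is position-independent; any `point` (or
#' none) returns the same parameters.
#'
#' @param field one of [field_kinds()].
#' @param point a grid label (e.g. `"d3_l0"`), a numeric
#'   `c(depth_cm, lateral_cm)` pair, or a row of [make_measurement_grid()].
#'   Ignored for `"REF_220KVP"`.
#' @return a `spectrum_model_params` object.
#' @export
default_params <- function(field, point = NULL) {
  if (!is.character(field) || length(field) != 1 ||
      !(field %in% field_kinds()))
    abort("unsupported field kind: ", paste(field, collapse = ", "))
  tab <- spectrum_calibration()
  if (field == "REF_220KVP") {
    row <- tab[tab$field == field, ][1, ]
    dep <- NA_real_; lat <- NA_real_
  } else {
    p <- resolve_point(point)
    row <- tab[tab$field == field & tab$depth_cm == p$depth_cm &
                 tab$lateral_cm == p$lateral_cm, ]
    if (nrow(row) != 1)
      abort(sprintf("no shipped calibration for %s at depth %g, lateral %g",
                    field, p$depth_cm, p$lateral_cm))
    dep <- p$depth_cm; lat <- p$lateral_cm
  }
  spectrum_model_params(mean_energy_keV = row$mean_energy_keV,
                        shape = row$shape,
                        low_energy_fraction = row$low_energy_fraction,
                        e_min_keV = row$e_min_keV, e_max_keV = row$e_max_keV,
                        family = row$family, field = field,
                        depth_cm = dep, lateral_cm = lat)
}

new_electron_spectrum <- function(energy_keV, weight, field = NA_character_,
                                  depth_cm = NA_real_, lateral_cm = NA_real_) {
  if (length(energy_keV) != length(weight) || length(energy_keV) < 1)
    abort("energy grid and weights must be non-empty and equal length")
  if (any(!is.finite(energy_keV)) || any(energy_keV < 1.0 - 1e-9))
    abort("all energies must be finite and >= 1 keV")
  if (is.unsorted(energy_keV, strictly = TRUE))
    abort("energy grid must be strictly increasing")
  if (any(!is.finite(weight)) || any(weight < 0))
    abort("weights must be finite and non-negative")
  s <- sum(weight)
  if (s <= 0) abort("weights must not all be zero")
  structure(list(energy_keV = as.numeric(energy_keV),
                 weight = as.numeric(weight) / s, field = field,
                 depth_cm = depth_cm, lateral_cm = lateral_cm),
            class = "electron_spectrum")
}

#' Generate a binned electron spectrum from model parameters
#'
#' Deterministic (no sampling): evaluates the parametric dose-weighted
#' density at the geometric midpoints of `n_bins` log-spaced bins over
#' `[e_min_keV, e_max_keV]` and normalizes the resulting bin weights to
#' sum to one.
#'
#' @param params a [spectrum_model_params()] object.
#' @param n_bins number of energy bins (>= 2); default 200.
#' @return object of class `electron_spectrum` with fields `energy_keV`
#'   (bin midpoint grid) and `weight` (normalized fluence-times-energy,
#'   i.e. dose, weights).
#' @export
generate_spectrum <- function(params, n_bins = 200) {
  stopifnot(inherits(params, "spectrum_model_params"))
  if (!is_count(n_bins) || n_bins < 2) abort("n_bins must be a count >= 2")
  lo <- params$e_min_keV; hi <- params$e_max_keV
  if ((hi - lo) / hi < 1e-12) { # degenerate support: delta spectrum
    return(new_electron_spectrum(lo, 1, params$field, params$depth_cm,
                                 params$lateral_cm))
  }
  edges <- exp(seq(log(lo), log(hi), length.out = n_bins + 1))
  mids <- sqrt(edges[-1] * edges[-length(edges)])
  w <- gamma_exp_density(mids, params) * diff(edges)
  new_electron_spectrum(mids, w, params$field, params$depth_cm,
                        params$lateral_cm)
}

#' Mean energy of an electron spectrum
#'
#' Weighted mean of the energy grid under the spectrum's normalized
#' (dose) weights; the package's spectral-softness summary.
#'
#' @param spectrum an `electron_spectrum`.
#' @return mean energy in keV.
#' @export
spectrum_mean_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "electron_spectrum"))
  sum(spectrum$energy_keV * spectrum$weight)
}

#' Write / read a spectrum as CSV
#'
#' The on-disk format is a two-column CSV (`energy_keV`, `weight`)
#' preceded by `# field=`, `# depth_cm=`, `# lateral_cm=` comment lines.
#' A write-then-read round trip reproduces the grid and normalized
#' weights to within 1e-9.
#'
#' @param spectrum an `electron_spectrum`.
#' @param path file path.
#' @return `write_spectrum_csv` returns `path` invisibly;
#'   `read_spectrum_csv` returns an `electron_spectrum`.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "electron_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# field=%s", spectrum$field),
               sprintf("# depth_cm=%g", spectrum$depth_cm),
               sprintf("# lateral_cm=%g", spectrum$lateral_cm),
               "energy_keV,weight"), con)
  writeLines(sprintf("%.12g,%.12g", spectrum$energy_keV, spectrum$weight),
             con)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    m <- meta[startsWith(meta, paste0("# ", key, "="))]
    if (length(m) == 0) return(NA_character_)
    sub(paste0("# ", key, "="), "", m[1], fixed = TRUE)
  }
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 2) abort("spectrum CSV has no data rows: ", path)
  hdr <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (!all(c("energy_keV", "weight") %in% hdr))
    abort("spectrum CSV is missing required columns energy_keV, weight")
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  for (i in seq_len(nrow(df))) {
    if (!is.finite(df$energy_keV[i]) || !is.finite(df$weight[i]))
      abort("non-numeric value in spectrum CSV at data row ", i)
    if (df$weight[i] < 0)
      abort("negative weight in spectrum CSV at data row ", i)
    if (i > 1 && df$energy_keV[i] <= df$energy_keV[i - 1])
      abort("energy grid not strictly increasing at data row ", i)
  }
  dep <- suppressWarnings(as.numeric(get_meta("depth_cm")))
  lat <- suppressWarnings(as.numeric(get_meta("lateral_cm")))
  new_electron_spectrum(df$energy_keV, df$weight, get_meta("field"),
                        dep, lat)
}
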