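#' DSB-based relative biological effectiveness
#'
#' Ratio of the test field's DSB yield to the reference field's DSB
#' yield at equal absorbed dose. Per-dalton yields are valid inputs:
#' genome mass and dose cancel in the ratio.
#'
#' @param test_yield Y_DSB of the test field (/Gy/Da), > 0 allowed 0.
#' @param reference_yield Y_DSB of the reference field (/Gy/Da), > 0.
#' @return RBE_DSB (dimensionless).
#' @export
rbe_dsb <- function(test_yield, reference_yield) {
  if (!is.numeric(reference_yield) || any(reference_yield <= 0))
    abort("reference_yield must be positive")
  test_yield / reference_yield
}

#' Percent difference of FFF relative to FF
#'
#' `100 * (fff - ff) / ff`.
#'
#' @param fff_value,ff_value values to compare; `ff_value` must be
#'   nonzero (positive).
#' @return percent difference.
#' @export
percent_difference <- function(fff_value, ff_value) {
  if (!is.numeric(ff_value) || any(!is.na(ff_value) & ff_value == 0))
    abort("ff_value must be nonzero")
  100 * (fff_value - ff_value) / ff_value
}

#' Default pipeline configuration
#'
#' Everything [run_comparison()] needs: the measurement grid, the fields
#' to compare, simulation sample sizes, the scoring-site geometry, the
#' lineal-energy binning and the damage constants. Spectrum parameters
#' come from the shipped calibration via [default_params()].
#'
#' @param grid measurement grid (default [make_measurement_grid()]).
#' @param fields test fields (default FF and FFF).
#' @param reference reference field kind.
#' @param n_bins spectrum bins.
#' @param n_tracks_per_bin tracks per spectrum bin for yields.
#' @param n_tracks_ydose cohort size for lineal-energy scoring.
#' @param n_domains scoring sites per cohort.
#' @param domain a [domain_spec()].
#' @param binning a [ydist_binning()].
#' @param track_params a [default_track_params()].
#' @param constants a [damage_constants()].
#' @param compute_ydose include microdosimetric scoring (default TRUE).
#' @return list of class `run_config`.
#' @export
default_config <- function(grid = make_measurement_grid(),
                           fields = c("FF_6MV", "FFF_6MV"),
                           reference = "REF_220KVP", n_bins = 200,
                           n_tracks_per_bin = 8, n_tracks_ydose = 240,
                           n_domains = 60000, domain = domain_spec(),
                           binning = ydist_binning(),
                           track_params = default_track_params(),
                           constants = damage_constants(),
                           compute_ydose = TRUE) {
  cfg <- list(grid = grid, fields = fields, reference = reference,
              n_bins = n_bins, n_tracks_per_bin = n_tracks_per_bin,
              n_tracks_ydose = n_tracks_ydose, n_domains = n_domains,
              domain = domain, binning = binning,
              track_params = track_params, constants = constants,
              compute_ydose = compute_ydose)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!all(c("depth_cm", "lateral_cm", "label") %in% names(cfg$grid)) ||
      nrow(cfg$grid) < 1)
    abort("config error: grid must have depth_cm, lateral_cm, label rows")
  if (!all(cfg$fields %in% field_kinds()) ||
      !(cfg$reference %in% field_kinds()))
    abort("config error: unknown field kind")
  if (!is_count(cfg$n_bins) || cfg$n_bins < 2)
    abort("config error: n_bins must be a count >= 2")
  for (nm in c("n_tracks_per_bin", "n_tracks_ydose", "n_domains"))
    if (!is_count(cfg[[nm]]))
      abort("config error: ", nm, " must be a count >= 1")
  stopifnot(inherits(cfg$domain, "domain_spec"),
            inherits(cfg$binning, "ydist_binning"),
            inherits(cfg$track_params, "track_model_params"),
            inherits(cfg$constants, "damage_constants"))
  invisible(cfg)
}

#' Run the full FF-vs-FFF comparison over the measurement grid
#'
#' For the reference field and each test field at each grid point:
#' builds the calibrated spectrum, computes spectrum-averaged strand
#' break yields (and, optionally, the dose-mean lineal energy of a
#' simulated cohort), then RBE_DSB against the single shared reference.
#' Deterministic given `master_seed`; the returned table carries a run
#' manifest (all parameters and seeds) sufficient to reproduce it.
#'
#' The RBE standard error uses the first-order delta method for a ratio
#' of independent means:
#' `se(R) = R * sqrt(se_t^2 / Y_t^2 + se_r^2 / Y_r^2)`.
#'
#' @param config a [default_config()] object.
#' @param master_seed integer master seed.
#' @return data.frame of class `comparison_table` with one row per
#'   (field, point): yields, DSB/SSB ratio, RBE_DSB and standard errors,
#'   plus attributes `reference` (the reference yields) and `manifest`.
#' @export
run_comparison <- function(config = default_config(), master_seed = 1L) {
  validate_config(config)
  ref_params <- default_params(config$reference)
  ref_spec <- generate_spectrum(ref_params, config$n_bins)
  ref_y <- spectrum_averaged_yields(ref_spec, config$track_params,
                                    config$n_tracks_per_bin,
                                    config$constants,
                                    derive_seed(master_seed, 9000))
  rows <- list()
  for (fi in seq_along(config$fields)) {
    field <- config$fields[fi]
    for (pi in seq_len(nrow(config$grid))) {
      pt <- config$grid[pi, ]
      spec <- generate_spectrum(default_params(field, pt), config$n_bins)
      ys <- spectrum_averaged_yields(spec, config$track_params,
                                     config$n_tracks_per_bin,
                                     config$constants,
                                     derive_seed(master_seed, fi, pi))
      y_d <- NA_real_
      if (isTRUE(config$compute_ydose)) {
        cohort <- simulate_cohort(spec, config$n_tracks_ydose,
                                  config$track_params,
                                  derive_seed(master_seed, fi, pi, 77))
        md <- dose_mean_lineal_energy(cohort, config$domain,
                                      config$n_domains, config$binning,
                                      derive_seed(master_seed, fi, pi, 78))
        y_d <- md$y_D
      }
      rbe <- rbe_dsb(ys$y_dsb, ref_y$y_dsb)
      rbe_se <- rbe * sqrt((ys$y_dsb_se / ys$y_dsb)^2 +
                             (ref_y$y_dsb_se / ref_y$y_dsb)^2)
      rows[[length(rows) + 1]] <- data.frame(
        field = field, depth_cm = pt$depth_cm, lateral_cm = pt$lateral_cm,
        label = pt$label, y_d = y_d, y_ssb = ys$y_ssb,
        y_ssb_se = ys$y_ssb_se, y_dsb = ys$y_dsb, y_dsb_se = ys$y_dsb_se,
        dsb_ssb_ratio = ys$dsb_ssb_ratio, ratio_se = ys$ratio_se,
        rbe_dsb = rbe, rbe_se = rbe_se)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  manifest <- list(master_seed = as.integer(master_seed),
                   config = config,
                   package_version = as.character(
                     utils::packageVersion("trackRBE")))
  structure(tab, reference = ref_y, manifest = manifest,
            class = c("comparison_table", "data.frame"))
}

#' FFF-vs-FF percent differences per measurement point
#'
#' @param table a `comparison_table` from [run_comparison()] containing
#'   both `FF_6MV` and `FFF_6MV` rows.
#' @return data.frame with per-point percent differences
#'   (`100 * (FFF - FF) / FF`) for y_D, Y_DSB, DSB/SSB and RBE_DSB.
#' @export
comparison_summary <- function(table) {
  ff <- table[table$field == "FF_6MV", ]
  fff <- table[table$field == "FFF_6MV", ]
  if (nrow(ff) == 0 || nrow(fff) == 0)
    abort("table must contain both FF_6MV and FFF_6MV rows")
  fff <- fff[match(ff$label, fff$label), ]
  data.frame(label = ff$label, depth_cm = ff$depth_cm,
             lateral_cm = ff$lateral_cm,
             y_d_pct = percent_difference(fff$y_d, ff$y_d),
             y_dsb_pct = percent_difference(fff$y_dsb, ff$y_dsb),
             ratio_pct = percent_difference(fff$dsb_ssb_ratio,
                                            ff$dsb_ssb_ratio),
             rbe_pct = percent_difference(fff$rbe_dsb, ff$rbe_dsb))
}

#' Write / read a run configuration as YAML
#'
#' Serializes the scalar knobs of a [default_config()]; the grid is
#' stored as its depth/lateral columns, and the track-model curve table
#' is stored inline.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly;
#'   `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  validate_config(config)
  x <- list(grid = list(depth_cm = config$grid$depth_cm,
                        lateral_cm = config$grid$lateral_cm),
            fields = config$fields, reference = config$reference,
            n_bins = config$n_bins,
            n_tracks_per_bin = config$n_tracks_per_bin,
            n_tracks_ydose = config$n_tracks_ydose,
            n_domains = config$n_domains,
            domain_diameter_um = config$domain$diameter_um,
            binning = list(y_min = config$binning$edges[1],
                           y_max = config$binning$edges[
                             length(config$binning$edges)],
                           bins_per_decade = round(
                             (length(config$binning$edges) - 1) /
                               log10(config$binning$edges[
                                 length(config$binning$edges)] /
                                   config$binning$edges[1]))),
            track_params = list(
              curve = as.list(config$track_params$curve),
              cluster_mean_multiplicity =
                config$track_params$cluster_mean_multiplicity,
              cutoff_keV = config$track_params$cutoff_keV,
              ionization_prob = config$track_params$ionization_prob),
            constants = list(k_ssb = config$constants$k_ssb,
                             k_dsb = config$constants$k_dsb,
                             linkage_distance_nm =
                               config$constants$linkage_distance_nm),
            compute_ydose = config$compute_ydose)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  g <- data.frame(depth_cm = x$grid$depth_cm,
                  lateral_cm = x$grid$lateral_cm)
  g$label <- sprintf("d%g_l%g", g$depth_cm, g$lateral_cm)
  g$in_field <- g$lateral_cm == 0
  default_config(
    grid = g, fields = unlist(x$fields), reference = x$reference,
    n_bins = x$n_bins, n_tracks_per_bin = x$n_tracks_per_bin,
    n_tracks_ydose = x$n_tracks_ydose, n_domains = x$n_domains,
    domain = domain_spec(x$domain_diameter_um),
    binning = ydist_binning(x$binning$y_min, x$binning$y_max,
                            x$binning$bins_per_decade),
    track_params = default_track_params(
      curve = as.data.frame(x$track_params$curve),
      cluster_mean_multiplicity = x$track_params$cluster_mean_multiplicity,
      cutoff_keV = x$track_params$cutoff_keV,
      ionization_prob = x$track_params$ionization_prob),
    constants = damage_constants(x$constants$k_ssb, x$constants$k_dsb,
                                 x$constants$linkage_distance_nm),
    compute_ydose = x$compute_ydose)
}
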