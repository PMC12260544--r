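#' Analysis configuration
#'
#' Bundles every tunable constant of the pipeline in one validated list.
#' Defaults are the method constants used throughout: connectivity matrices
#' are sparsified so each row and column retains its top 0.1% of values;
#' matched subnetwork clusters must span at least half of subjects; density
#' maps are displayed at a minimum of 3 subjects and thresholded for region
#' extraction at >10% of subjects; a study matches a subnetwork when it
#' reports a peak closer than 2 mm to at least 40% of the subnetwork's
#' regions; connections shorter than 20 mm can be excluded; graph nodes are
#' contiguous clusters larger than 20 mm^2; spring graphs start at 10% edge
#' density and escalate in 5% steps; activation-peak density uses a 4 mm
#' radius; term significance is FDR-controlled at 0.05; lags are searched
#' within +/- 8 s.
#'
#' @param subnetwork_density fraction of values kept per row/column when
#'   thresholding at the subnetwork tier.
#' @param network_density fraction kept at the large-scale network tier.
#' @param min_subject_fraction minimum fraction of subjects a matched cluster
#'   must span to be retained.
#' @param densitymap_min_subjects display threshold for density maps
#'   (subjects).
#' @param region_fraction_threshold fraction of subjects above which (strict)
#'   a vertex enters region extraction.
#' @param peak_match_radius_mm a study peak closer than this (strict) to a
#'   region counts as hitting it.
#' @param region_match_fraction minimum fraction (>=) of a subnetwork's
#'   regions a study must hit to match.
#' @param short_distance_mm node pairs closer than this can be excluded from
#'   connectivity.
#' @param min_cluster_area_mm2 contiguous clusters must exceed this area to
#'   become graph nodes / regions.
#' @param graph_density starting edge density for spring-graph export.
#' @param graph_density_step escalation increment when a network is
#'   disconnected.
#' @param peak_density_radius_mm radius (inclusive) for activation-peak
#'   density maps.
#' @param fdr_alpha FDR level for term significance.
#' @param max_lag_s half-width of the lag search window, seconds.
#' @param lag_band_hz two-element passband for the infraslow filter, Hz.
#' @param lag_min_abs_r minimum peak |r| for a lag estimate to be valid.
#' @param min_community_size communities smaller than this are relabeled 0.
#' @param overlap_fraction fraction (>=) of a community's nodes that must lie
#'   inside the parent network for the community to count as one of its
#'   subnetworks.
#' @param r_max correlations are clipped to +/- r_max before the Fisher
#'   transform (atanh diverges at |r| = 1).
#' @param rng_seed integer seed recorded in run manifests.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(subnetwork_density = 0.001,
                            network_density = 0.01,
                            min_subject_fraction = 0.5,
                            densitymap_min_subjects = 3L,
                            region_fraction_threshold = 0.10,
                            peak_match_radius_mm = 2.0,
                            region_match_fraction = 0.40,
                            short_distance_mm = 20.0,
                            min_cluster_area_mm2 = 20.0,
                            graph_density = 0.10,
                            graph_density_step = 0.05,
                            peak_density_radius_mm = 4.0,
                            fdr_alpha = 0.05,
                            max_lag_s = 8.0,
                            lag_band_hz = c(0.01, 0.1),
                            lag_min_abs_r = 0.1,
                            min_community_size = 10L,
                            overlap_fraction = 0.5,
                            r_max = 0.999999,
                            rng_seed = 1L) {
  cfg <- list(
    subnetwork_density = subnetwork_density,
    network_density = network_density,
    min_subject_fraction = min_subject_fraction,
    densitymap_min_subjects = as.integer(densitymap_min_subjects),
    region_fraction_threshold = region_fraction_threshold,
    peak_match_radius_mm = peak_match_radius_mm,
    region_match_fraction = region_match_fraction,
    short_distance_mm = short_distance_mm,
    min_cluster_area_mm2 = min_cluster_area_mm2,
    graph_density = graph_density,
    graph_density_step = graph_density_step,
    peak_density_radius_mm = peak_density_radius_mm,
    fdr_alpha = fdr_alpha,
    max_lag_s = max_lag_s,
    lag_band_hz = as.numeric(lag_band_hz),
    lag_min_abs_r = lag_min_abs_r,
    min_community_size = as.integer(min_community_size),
    overlap_fraction = overlap_fraction,
    r_max = r_max,
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_config <- function(cfg) {
  fracs <- c("subnetwork_density", "network_density", "min_subject_fraction",
             "region_fraction_threshold", "region_match_fraction",
             "graph_density", "graph_density_step", "fdr_alpha",
             "overlap_fraction")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1)
      stop(sprintf("config field '%s' must be a fraction in (0, 1], got %s",
                   f, format(v)), call. = FALSE)
  }
  pos <- c("peak_match_radius_mm", "min_cluster_area_mm2",
           "peak_density_radius_mm", "max_lag_s")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("config field '%s' must be > 0", f), call. = FALSE)
  }
  if (cfg$short_distance_mm < 0)
    stop("config field 'short_distance_mm' must be >= 0", call. = FALSE)
  if (length(cfg$lag_band_hz) != 2L || any(cfg$lag_band_hz <= 0) ||
      diff(cfg$lag_band_hz) <= 0)
    stop("config field 'lag_band_hz' must be an increasing positive pair",
         call. = FALSE)
  if (cfg$r_max <= 0 || cfg$r_max >= 1)
    stop("config field 'r_max' must lie in (0, 1)", call. = FALSE)
  invisible(cfg)
}

#' Read / write an analysis configuration as JSON
#'
#' Unknown keys are rejected so that typos fail loudly rather than silently
#' falling back to defaults.
#'
#' @param path file path.
#' @param cfg an `analysis_config`.
#' @return `read_config` returns an `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
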