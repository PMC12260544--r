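#' Run manifests
#'
#' Every stage output directory contains exactly one `manifest.json`
#' recording the command, the resolved configuration, the RNG seed, input
#' file digests, the package version and a timestamp, so that reruns with
#' identical manifests reproduce identical outputs for deterministic
#' stages.
#'
#' @param dir output directory.
#' @param command stage name.
#' @param config resolved `analysis_config` (or list).
#' @param inputs character vector of input file paths (digested with md5).
#' @param rng_seed seed used by the stage.
#' @export
write_manifest <- function(dir, command, config, inputs = character(0),
                           rng_seed = NA_integer_) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    command = command,
    config = if (inherits(config, "analysis_config")) unclass(config) else config,
    rng_seed = rng_seed,
    inputs = digests,
    tool_version = as.character(utils::packageVersion("subnetr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_manifest
#' @param path path to a `manifest.json`.
#' @export
read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

require_stage <- function(out_root, stage, file) {
  p <- file.path(out_root, stage, file)
  if (!file.exists(p))
    stop(sprintf("missing upstream output '%s': run the '%s' stage first",
                 p, stage), call. = FALSE)
  p
}

#' Analysis configuration for the 400-node synthetic scale
#'
#' The canonical 0.1% row/column density is calibrated to dense cortical
#' connectomes (~60k nodes, where it retains ~60 partners per row). On the
#' 400-node synthetic grid the same rule keeps a single partner and any
#' graph fragments, so the synthetic-scale configuration keeps an
#' equivalent neighborhood size instead: 5% density (~20 partners) at the
#' subnetwork tier and 25% at the network tier. The network-tier density
#' obeys a capacity rule: the retained per-row neighborhood `k = ceil(d *
#' (N - 1))` must not exceed the number of same-network partners a node has
#' (~132 here, so d <= 0.33); past that bound every node is forced to keep
#' cross-network edges and community detection destabilizes.
#'
#' @param ... overrides passed to [analysis_config()].
#' @export
synthetic_config <- function(...) {
  analysis_config(subnetwork_density = 0.05, network_density = 0.25, ...)
}

#' Default end-to-end synthetic study design
#'
#' Ten subjects on the 400-node grid with 10% topographic jitter, planted
#' signal lags across the four parent-network subnetworks, three planted
#' term associations, and two task conditions.
#'
#' @param rng_seed base seed.
#' @param n_subjects,n_frames study size.
#' @param ... further overrides passed to [planted_design()].
#' @export
pipeline_design <- function(rng_seed = 1L, n_subjects = 10L,
                            n_frames = 800L, ...) {
  planted_design(
    n_subjects = n_subjects, n_frames = n_frames,
    planted_lags = c(`1` = -1.5, `2` = -0.5, `3` = 0.5, `4` = 1.5),
    lag_snr = 0.5, ar1_phi = 0.3,
    planted_terms = data.frame(term = c("term_001", "term_002", "term_003"),
                               subnetwork = 1:3, shift = 0.2),
    rng_seed = rng_seed, ...)
}

#' Run pipeline stages on a synthetic study
#'
#' Orchestrates `simulate -> detect -> match -> mana -> profile -> lag ->
#' report` over an output directory tree, one subdirectory and one manifest
#' per stage. Stages read only the on-disk outputs of earlier stages, so
#' any prefix of the stage list can be rerun; a missing upstream output
#' names the stage to run first.
#'
#' @param out_root output directory root.
#' @param design a `planted_design` (simulate stage).
#' @param config an `analysis_config`; defaults to [synthetic_config()].
#' @param stages character vector of stages to run, in order.
#' @param task_effects named list of per-condition planted subnetwork
#'   effects (length-8 numeric vectors) for the simulate stage.
#' @return invisible list of per-stage results.
#' @export
run_pipeline <- function(out_root,
                         design = pipeline_design(),
                         config = synthetic_config(),
                         stages = c("simulate", "detect", "match", "mana",
                                    "profile", "lag", "report"),
                         task_effects = list(
                           motor = c(0, 1, 0, 0, 0, 0, 0, 0),
                           cognitive = c(1, 0.5, 0, 0, 0, 0, 0, 0))) {
  known <- c("simulate", "detect", "match", "mana", "profile", "lag", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  validate_config(config)
  results <- list()
  for (st in stages) {
    results[[st]] <- switch(st,
      simulate = stage_simulate(out_root, design, config, task_effects),
      detect = stage_detect(out_root, config),
      match = stage_match(out_root, config),
      mana = stage_mana(out_root, config),
      profile = stage_profile(out_root, config),
      lag = stage_lag(out_root, config),
      report = stage_report(out_root, config))
  }
  invisible(results)
}

stage_dir <- function(out_root, stage) {
  d <- file.path(out_root, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

stage_simulate <- function(out_root, design, config, task_effects) {
  d <- stage_dir(out_root, "simulate")
  write_node_space(design$space, file.path(d, "space"))
  write_label_map(design$truth_subnet, file.path(d, "truth_subnet.tsv"))
  write_label_map(truth_networks(design), file.path(d, "template.tsv"))
  for (s in seq_len(design$n_subjects)) {
    truth <- subject_truth(design, s)
    ts <- simulate_timeseries(design, s, truth)
    write_timeseries_tsv(ts, file.path(d, sprintf("ts_sub-%02d.tsv", s)))
    write_label_map(truth$subnet, file.path(d, sprintf("subnet_sub-%02d.tsv", s)))
    write_label_map(truth$network, file.path(d, sprintf("network_sub-%02d.tsv", s)))
  }
  regions <- regions_from_truth(design, subnet_ids = 1:3)
  db <- simulate_meta_database(design, regions)
  write_meta_database(db, file.path(d, "db"))
  maps <- simulate_task_maps(design, task_effects)
  for (cond in names(maps))
    utils::write.table(maps[[cond]], file.path(d, sprintf("task_%s.tsv", cond)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  truth_json <- list(
    n_subjects = design$n_subjects,
    planted_lags = as.list(design$planted_lags),
    planted_terms = design$planted_terms,
    study_group = attr(db, "group"),
    network_of_subnet = design$network_of_subnet,
    task_effects = task_effects)
  jsonlite::write_json(truth_json, file.path(d, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(d, "simulate", config, rng_seed = design$rng_seed)
  invisible(d)
}

stage_detect <- function(out_root, config) {
  d <- stage_dir(out_root, "detect")
  space <- read_node_space(sub("_nodes.tsv$", "",
                               require_stage(out_root, "simulate", "space_nodes.tsv")))
  template <- read_label_map(require_stage(out_root, "simulate", "template.tsv"))
  ts_files <- sort(list.files(file.path(out_root, "simulate"),
                              pattern = "^ts_sub-[0-9]+\\.tsv$",
                              full.names = TRUE))
  if (!length(ts_files))
    stop("missing upstream output: run the 'simulate' stage first",
         call. = FALSE)
  prov <- list()
  for (f in ts_files) {
    ts <- read_timeseries_tsv(f, space)
    cm <- compute_connectivity(ts, r_max = config$r_max)
    seed <- derive_seed(config$rng_seed, 100L + length(prov))
    net_sol <- detect_communities(
      density_threshold_rowcol(cm, config$network_density),
      method = "map_equation", seed = seed,
      min_size = config$min_community_size)
    parent <- identify_parent_network(net_sol, template, target_label = 1L)
    sub_sol <- detect_communities(
      density_threshold_rowcol(cm, config$subnetwork_density),
      method = "map_equation", seed = seed,
      min_size = config$min_community_size)
    sns <- extract_parent_subnetworks(sub_sol, parent$mask,
                                      subject_id = ts$subject_id,
                                      overlap_fraction = config$overlap_fraction,
                                      density = config$subnetwork_density)
    write_subnetwork_set(sns, file.path(d, sprintf("subnets_%s.json",
                                                   ts$subject_id)))
    prov[[ts$subject_id]] <- list(
      seed = seed, network_quality = net_sol$quality,
      subnetwork_quality = sub_sol$quality,
      n_subnetworks = length(sns$members))
  }
  jsonlite::write_json(prov, file.path(d, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(d, "detect", config, inputs = ts_files,
                 rng_seed = config$rng_seed)
  invisible(d)
}

stage_match <- function(out_root, config) {
  d <- stage_dir(out_root, "match")
  files <- sort(list.files(file.path(out_root, "detect"),
                           pattern = "^subnets_.*\\.json$", full.names = TRUE))
  if (!length(files))
    stop("missing upstream output: run the 'detect' stage first", call. = FALSE)
  sets <- lapply(files, read_subnetwork_set)
  sets <- Filter(function(s) length(s$members) > 0L, sets)
  space <- read_node_space(sub("_nodes.tsv$", "",
                               require_stage(out_root, "simulate", "space_nodes.tsv")))
  om <- overlap_matrix(sets)
  clusters <- cluster_overlap_matrix(
    om, n_subjects = length(files),
    min_subject_fraction = config$min_subject_fraction,
    seed = derive_seed(config$rng_seed, 200L))
  membership <- lapply(clusters, function(cl)
    list(name = cl$name, subjects = cl$subjects,
         members = cl$members))
  jsonlite::write_json(membership, file.path(d, "clusters.json"),
                       auto_unbox = TRUE, digits = NA)
  dms <- lapply(clusters, density_map, n_nodes = n_nodes(space))
  names(dms) <- vapply(clusters, `[[`, "", "name")
  dm_tab <- data.frame(node = seq_len(n_nodes(space)))
  for (nm in names(dms)) dm_tab[[nm]] <- as.integer(dms[[nm]])
  utils::write.table(dm_tab, file.path(d, "density_maps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(dms)) {
    wta <- winner_take_all(dms)
    write_label_map(wta, file.path(d, "winner_take_all.tsv"))
    utils::write.table(data.frame(node = seq_len(n_nodes(space)),
                                  tie = as.integer(attr(wta, "tie"))),
                       file.path(d, "wta_ties.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  # per-subject per-cluster node sets, for the profiling and lag stages
  per_subject <- list()
  for (cl in clusters) {
    for (s in unique(cl$members$subject)) {
      idx <- which(cl$members$subject == s)
      per_subject[[s]][[cl$name]] <-
        sort(unique(unlist(cl$member_nodes[idx])))
    }
  }
  jsonlite::write_json(per_subject, file.path(d, "subject_cluster_nodes.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(d, "match", config, inputs = files,
                 rng_seed = config$rng_seed)
  invisible(d)
}

read_subject_cluster_nodes <- function(out_root) {
  p <- require_stage(out_root, "match", "subject_cluster_nodes.json")
  raw <- jsonlite::read_json(p, simplifyVector = TRUE)
  lapply(raw, function(subj) lapply(subj, as.integer))
}

stage_mana <- function(out_root, config) {
  d <- stage_dir(out_root, "mana")
  space <- read_node_space(sub("_nodes.tsv$", "",
                               require_stage(out_root, "simulate", "space_nodes.tsv")))
  db <- read_meta_database(sub("_activations.tsv$", "",
                               require_stage(out_root, "simulate",
                                             "db_activations.tsv")))
  dm_tab <- utils::read.delim(require_stage(out_root, "match",
                                            "density_maps.tsv"))
  gt <- jsonlite::read_json(file.path(out_root, "simulate",
                                      "ground_truth.json"),
                            simplifyVector = TRUE)
  region_sets <- list()
  for (nm in setdiff(names(dm_tab), "node")) {
    nodes <- threshold_density(dm_tab[[nm]], mode = "fraction",
                               f = config$region_fraction_threshold,
                               n_subjects = gt$n_subjects)
    if (!length(nodes)) next
    rs <- extract_regions(nodes, space, min_area = config$min_cluster_area_mm2)
    if (length(rs)) region_sets[[nm]] <- rs
  }
  tab <- mana_annotate(db, region_sets, space,
                       radius_mm = config$peak_match_radius_mm,
                       fraction = config$region_match_fraction,
                       alpha = config$fdr_alpha)
  utils::write.table(as.data.frame(tab), file.path(d, "term_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- tab[tab$significant, , drop = FALSE]
  cloud <- lapply(seq_len(nrow(sig)), function(i)
    list(term = sig$term[i], subnetwork = sig$assigned[i],
         magnitude = sig$magnitude[i], tier = "fdr"))
  jsonlite::write_json(cloud, file.path(d, "word_cloud.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(d, "mana", config,
                 inputs = file.path(out_root, "match", "density_maps.tsv"),
                 rng_seed = config$rng_seed)
  invisible(d)
}

stage_profile <- function(out_root, config) {
  d <- stage_dir(out_root, "profile")
  space <- read_node_space(sub("_nodes.tsv$", "",
                               require_stage(out_root, "simulate", "space_nodes.tsv")))
  subj_nodes <- read_subject_cluster_nodes(out_root)
  rows <- list()
  for (sid in names(subj_nodes)) {
    ts <- read_timeseries_tsv(file.path(out_root, "simulate",
                                        sprintf("ts_%s.tsv", sid)), space)
    netmap <- read_label_map(file.path(out_root, "simulate",
                                       sprintf("network_%s.tsv", sid)))
    targets <- list(network_2 = label_nodes(netmap, 2L),
                    network_3 = label_nodes(netmap, 3L))
    for (sn in names(subj_nodes[[sid]])) {
      for (nw in names(targets)) {
        z <- suppressWarnings(subnetwork_network_fc(
          ts, subj_nodes[[sid]][[sn]], targets[[nw]], space = space))
        rows[[length(rows) + 1L]] <-
          data.frame(subject = sid, subnetwork = sn, network = nw, z = z)
      }
    }
  }
  prof <- do.call(rbind, rows)
  utils::write.table(prof, file.path(d, "profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stats_out <- list()
  for (nw in unique(prof$network)) {
    sub <- prof[prof$network == nw, ]
    if (length(unique(sub$subnetwork)) < 2L) next
    res <- tryCatch(
      rm_anova(data.frame(subject = sub$subject, level = sub$subnetwork,
                          value = sub$z),
               n_tests = length(unique(prof$network)),
               effect_name = paste0("subnetwork@", nw)),
      error = function(e) NULL)
    if (is.null(res)) next
    wide <- tapply(sub$z, list(sub$subject, sub$subnetwork), mean)
    stats_out[[nw]] <- list(F = res$F, df = res$df, p = res$p,
                            p_bonferroni = res$p_bonferroni,
                            posthoc = posthoc_paired_t(wide))
  }
  jsonlite::write_json(stats_out, file.path(d, "stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  # spring graph for the first subject
  sid <- names(subj_nodes)[1L]
  ts <- read_timeseries_tsv(file.path(out_root, "simulate",
                                      sprintf("ts_%s.tsv", sid)), space)
  netmap <- read_label_map(file.path(out_root, "simulate",
                                     sprintf("network_%s.tsv", sid)))
  groups <- c(subj_nodes[[sid]],
              list(network_2 = label_nodes(netmap, 2L),
                   network_3 = label_nodes(netmap, 3L)))
  cl_rows <- list(); cl_nodes <- list()
  for (gname in names(groups)) {
    rs <- extract_regions(groups[[gname]], space,
                          min_area = config$min_cluster_area_mm2)
    for (r in rs) {
      cl_rows[[length(cl_rows) + 1L]] <-
        data.frame(cluster = sprintf("%s_r%d", gname, length(cl_rows) + 1L),
                   group = gname)
      cl_nodes[[length(cl_nodes) + 1L]] <- r$nodes
    }
  }
  sg <- spring_graph_export(ts, do.call(rbind, cl_rows), cl_nodes,
                            density = config$graph_density,
                            step = config$graph_density_step,
                            r_max = config$r_max)
  write_spring_graph(sg, file.path(d, "spring_graph"))
  write_manifest(d, "profile", config,
                 inputs = file.path(out_root, "match",
                                    "subject_cluster_nodes.json"),
                 rng_seed = config$rng_seed)
  invisible(d)
}

stage_lag <- function(out_root, config) {
  d <- stage_dir(out_root, "lag")
  space <- read_node_space(sub("_nodes.tsv$", "",
                               require_stage(out_root, "simulate", "space_nodes.tsv")))
  subj_nodes <- read_subject_cluster_nodes(out_root)
  lag_maps <- list(); structures <- list()
  for (sid in names(subj_nodes)) {
    ts <- read_timeseries_tsv(file.path(out_root, "simulate",
                                        sprintf("ts_%s.tsv", sid)), space)
    tsf <- bandpass(ts, band_hz = config$lag_band_hz)
    maps <- lapply(subj_nodes[[sid]], function(seed_nodes)
      seed_lag_map(tsf, seed_nodes, max_lag_s = config$max_lag_s,
                   min_abs_r = config$lag_min_abs_r))
    lag_maps[[sid]] <- maps
    structures[[sid]] <- subj_nodes[[sid]]
    delay_tab <- data.frame(node = seq_len(n_nodes(space)))
    for (nm in names(maps)) delay_tab[[nm]] <- maps[[nm]]$delay_s
    utils::write.table(delay_tab, file.path(d, sprintf("lagmap_%s.tsv", sid)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ordering <- group_ordering(lag_maps, structures)
  jsonlite::write_json(
    list(means_s = as.list(ordering$means),
         anova = list(F = ordering$anova$F, df = ordering$anova$df,
                      p = ordering$anova$p),
         posthoc = ordering$posthoc),
    file.path(d, "ordering.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  write_manifest(d, "lag", config,
                 inputs = file.path(out_root, "match",
                                    "subject_cluster_nodes.json"),
                 rng_seed = config$rng_seed)
  invisible(d)
}

stage_report <- function(out_root, config) {
  d <- stage_dir(out_root, "report")
  lines <- c("# Pipeline summary", "")
  cl_path <- file.path(out_root, "match", "clusters.json")
  if (file.exists(cl_path)) {
    cl <- jsonlite::read_json(cl_path, simplifyVector = FALSE)
    lines <- c(lines, sprintf("- Matched subnetwork clusters: %d", length(cl)))
  }
  tt_path <- file.path(out_root, "mana", "term_table.tsv")
  if (file.exists(tt_path)) {
    tt <- utils::read.delim(tt_path)
    nsig <- sum(tt$significant %in% c(TRUE, "TRUE"))
    lines <- c(lines,
               if (nsig == 0L) "- MANA: no significant terms"
               else sprintf("- MANA: %d significant term(s): %s", nsig,
                            paste(tt$term[tt$significant %in% c(TRUE, "TRUE")],
                                  collapse = ", ")))
  }
  ord_path <- file.path(out_root, "lag", "ordering.json")
  if (file.exists(ord_path)) {
    ord <- jsonlite::read_json(ord_path, simplifyVector = TRUE)
    mm <- unlist(ord$means_s)
    lines <- c(lines, sprintf(
      "- Temporal ordering (earliest to latest): %s (ANOVA p = %.3g)",
      paste(names(sort(mm)), collapse = " -> "), ord$anova$p))
  }
  st_path <- file.path(out_root, "profile", "stats.json")
  if (file.exists(st_path)) {
    st <- jsonlite::read_json(st_path, simplifyVector = TRUE)
    lines <- c(lines, sprintf("- Connectivity-profile ANOVAs: %d network(s) tested",
                              length(st)))
  }
  writeLines(lines, file.path(d, "report.md"))
  write_manifest(d, "report", config, rng_seed = config$rng_seed)
  invisible(d)
}
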