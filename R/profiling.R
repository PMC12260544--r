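#' Subnetwork-to-network functional connectivity
#'
#' Correlates the mean time course over the subnetwork's nodes with the
#' mean time course over the target network's nodes, after removing from
#' the target any node overlapping the subnetwork, and Fisher-transforms
#' the result. An empty target after exclusion yields `NA` with a warning.
#'
#' In short-distance exclusion mode the two mean time courses cannot be
#' pair-masked, so the connectivity is instead the mean Fisher z over all
#' node pairs (subnetwork node x target node) farther apart than
#' `short_distance_mm`, computed from node-level time courses.
#'
#' @param ts a `timeseries`.
#' @param subnetwork_nodes,network_nodes integer node-index vectors.
#' @param space `node_space` (required in exclusion mode).
#' @param short_distance_mm pairs closer than this are excluded; `NULL` or 0
#'   disables pair masking (mean-time-course mode).
#' @param r_max clip bound before `atanh`.
#' @return Fisher z scalar (`NA` if undefined).
#' @export
subnetwork_network_fc <- function(ts, subnetwork_nodes, network_nodes,
                                  space = NULL, short_distance_mm = NULL,
                                  r_max = 0.999999) {
  stopifnot(inherits(ts, "timeseries"))
  sn <- unique(as.integer(subnetwork_nodes))
  tgt <- setdiff(unique(as.integer(network_nodes)), sn)
  if (length(tgt) == 0L) {
    warning("target network fully overlaps the subnetwork; connectivity undefined")
    return(NA_real_)
  }
  if (is.null(short_distance_mm) || short_distance_mm <= 0) {
    a <- colMeans(ts$values[sn, , drop = FALSE])
    b <- colMeans(ts$values[tgt, , drop = FALSE])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("constant mean time course; connectivity undefined")
      return(NA_real_)
    }
    r <- stats::cor(a, b)
  } else {
    if (is.null(space)) stop("exclusion mode needs a node space", call. = FALSE)
    d <- pairwise_distances(space, sn, tgt)
    keep <- d >= short_distance_mm
    if (!any(keep)) {
      warning("all node pairs excluded by the distance rule")
      return(NA_real_)
    }
    rmat <- suppressWarnings(stats::cor(t(ts$values[sn, , drop = FALSE]),
                                        t(ts$values[tgt, , drop = FALSE])))
    z <- atanh(pmin(pmax(rmat[keep], -r_max), r_max))
    return(mean(z, na.rm = TRUE))
  }
  atanh(pmin(pmax(r, -r_max), r_max))
}

#' Connectivity profile table across subjects
#'
#' @param ts_list list of `timeseries`, one per subject.
#' @param subnetworks named list (per subject id): subnetwork name -> node
#'   indices.
#' @param networks named list (per subject id): network name -> node
#'   indices.
#' @param ... passed to [subnetwork_network_fc()].
#' @return data frame: subject, subnetwork, network, z.
#' @export
profile_table <- function(ts_list, subnetworks, networks, ...) {
  rows <- list()
  for (ts in ts_list) {
    sid <- ts$subject_id
    for (sn in names(subnetworks[[sid]])) {
      for (nw in names(networks[[sid]])) {
        z <- suppressWarnings(subnetwork_network_fc(
          ts, subnetworks[[sid]][[sn]], networks[[sid]][[nw]], ...))
        rows[[length(rows) + 1L]] <-
          data.frame(subject = sid, subnetwork = sn, network = nw, z = z)
      }
    }
  }
  do.call(rbind, rows)
}

#' Mean task activation per subnetwork
#'
#' Arithmetic mean of a z-map over each subnetwork's nodes; an empty
#' subnetwork yields `NA`.
#'
#' @param zmap numeric per-node activation values.
#' @param subnetworks named list: subnetwork name -> node indices.
#' @return named numeric vector of means.
#' @export
task_condition_means <- function(zmap, subnetworks) {
  vapply(subnetworks, function(nodes) {
    nodes <- unique(as.integer(nodes))
    if (length(nodes) == 0L) NA_real_ else mean(zmap[nodes])
  }, numeric(1L))
}

#' Repeated-measures one-way ANOVA (subject as block)
#'
#' Tests a main effect of level (subnetwork) on subject x level values with
#' subject identity as a blocking factor -- the classical repeated-measures
#' F, realized as a fixed-effects two-way decomposition. Unbalanced data
#' are handled by omitting missing subject-level cells from the sums of
#' squares; levels observed in fewer than 2 subjects are dropped with a
#' warning. A zero residual (within-subject differences exactly constant)
#' yields `F = Inf`, flagged in `degenerate`.
#'
#' @param table numeric matrix, subjects x levels (NA = missing cell), or a
#'   long data frame with columns `subject`, `level`, `value`.
#' @param n_tests Bonferroni family size for `p_bonferroni`.
#' @param effect_name label for the tested effect.
#' @return object of class `stat_result`: `effect`, `F`, `df` (pair), `p`,
#'   `p_bonferroni`, `level_means`, `degenerate`.
#' @export
rm_anova <- function(table, n_tests = 1L, effect_name = "level") {
  long <- as_long_table(table)
  keep <- !is.na(long$value)
  long <- long[keep, , drop = FALSE]
  lvl_n <- tapply(long$subject, long$level, function(s) length(unique(s)))
  drop <- names(lvl_n)[lvl_n < 2L]
  if (length(drop)) {
    warning("dropping level(s) with < 2 subjects: ",
            paste(drop, collapse = ", "))
    long <- long[!long$level %in% drop, , drop = FALSE]
  }
  if (length(unique(long$level)) < 2L || length(unique(long$subject)) < 2L)
    stop("need >= 2 levels and >= 2 subjects", call. = FALSE)
  long$subject <- factor(long$subject)
  long$level <- factor(long$level)
  fit <- stats::lm(value ~ subject + level, data = long)
  an <- suppressWarnings(stats::anova(fit))  # perfect fits handled below
  i <- match("level", rownames(an))
  ssl <- an[i, "Sum Sq"]
  ssr <- an["Residuals", "Sum Sq"]
  dfr <- an["Residuals", "Df"]
  tot <- sum(an[, "Sum Sq"])
  degenerate <- FALSE
  if (ssl <= 1e-12 * max(tot, 1e-300)) {        # no level effect at all
    f <- 0; p <- 1
  } else if (ssr <= 1e-12 * tot) {              # zero residual: flag
    degenerate <- TRUE
    f <- Inf; p <- 0
  } else {
    f <- an[i, "Mean Sq"] / an["Residuals", "Mean Sq"]
    p <- stats::pf(f, an[i, "Df"], dfr, lower.tail = FALSE)
  }
  structure(list(effect = effect_name, F = f, df = c(an[i, "Df"], dfr), p = p,
                 p_bonferroni = min(1, p * n_tests),
                 level_means = tapply(long$value, long$level, mean),
                 degenerate = degenerate),
            class = "stat_result")
}

as_long_table <- function(table) {
  if (is.data.frame(table) &&
      all(c("subject", "level", "value") %in% names(table)))
    return(table[, c("subject", "level", "value")])
  m <- as.matrix(table)
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("l%02d", seq_len(ncol(m)))
  data.frame(subject = rep(rownames(m), times = ncol(m)),
             level = rep(colnames(m), each = nrow(m)),
             value = as.vector(m))
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: F(%d, %d) = %s, p = %.4g (Bonferroni %.4g)%s\n",
              x$effect, x$df[1L], x$df[2L],
              if (is.finite(x$F)) sprintf("%.3f", x$F) else "Inf",
              x$p, x$p_bonferroni,
              if (isTRUE(x$degenerate)) " [degenerate residual]" else ""))
  invisible(x)
}

#' Paired t test on subject-wise differences
#'
#' Pairs with a missing value on either side are dropped.
#'
#' @param a,b numeric vectors aligned by subject.
#' @return list: `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_t <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 2L) stop("need >= 2 complete pairs", call. = FALSE)
  d <- a[keep] - b[keep]
  if (stats::sd(d) == 0) {  # t.test refuses constant differences
    n <- length(d)
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t, df = n - 1L, p = if (t == 0) 1 else 0,
                mean_diff = mean(d), n = n))
  }
  ht <- stats::t.test(a[keep], b[keep], paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate), n = sum(keep))
}

#' Post hoc paired t tests over all level pairs
#'
#' @param table subjects x levels matrix (or long data frame as in
#'   [rm_anova()]).
#' @return data frame: level_a, level_b, t, df, p.
#' @export
posthoc_paired_t <- function(table) {
  long <- as_long_table(table)
  wide <- tapply(long$value, list(long$subject, long$level), mean)
  lv <- colnames(wide)
  rows <- list()
  for (i in seq_len(length(lv) - 1L)) {
    for (j in seq.int(i + 1L, length(lv))) {
      res <- paired_t(wide[, i], wide[, j])
      rows[[length(rows) + 1L]] <- data.frame(
        level_a = lv[i], level_b = lv[j], t = res$t, df = res$df, p = res$p)
    }
  }
  do.call(rbind, rows)
}

#' Spring-graph export of cluster-level connectivity
#'
#' Nodes are contiguous clusters (regions) of the selected subnetworks and
#' networks; edges are the Fisher z of their mean time courses. The edge
#' set keeps the top `density` fraction of pairwise values; if any declared
#' network's clusters are all disconnected from the giant component, the
#' density is raised by `step` and the thresholding retried (10% -> 15% ->
#' 20% ... by default) until every network connects or density reaches 1
#' (then exported with a `disconnected` warning flag). Output is a weighted
#' edge list plus node attributes, ready for external force-directed
#' layout; negative edges are kept in the statistics but the exporter
#' reports them for the caller to drop in visualization.
#'
#' @param ts a `timeseries`.
#' @param clusters data frame: `cluster` (id), `group` (subnetwork/network
#'   name); one row per cluster, aligned with `cluster_nodes`.
#' @param cluster_nodes list of node-index vectors per cluster.
#' @param density starting edge density.
#' @param step escalation increment.
#' @param r_max clip bound before `atanh`.
#' @return list of class `spring_graph`: `nodes` (data frame), `edges`
#'   (data frame from, to, weight), `density` (final), `escalations`,
#'   `disconnected` (logical).
#' @export
spring_graph_export <- function(ts, clusters, cluster_nodes,
                                density = 0.10, step = 0.05,
                                r_max = 0.999999) {
  stopifnot(inherits(ts, "timeseries"), nrow(clusters) == length(cluster_nodes))
  k <- length(cluster_nodes)
  if (k < 2L) stop("need >= 2 clusters", call. = FALSE)
  mts <- t(vapply(cluster_nodes, function(nodes)
    colMeans(ts$values[unique(as.integer(nodes)), , drop = FALSE]),
    numeric(ncol(ts$values))))
  r <- suppressWarnings(stats::cor(t(mts)))
  z <- atanh(pmin(pmax(r, -r_max), r_max))
  diag(z) <- NA_real_
  ut <- which(upper.tri(z), arr.ind = TRUE)
  vals <- z[upper.tri(z)]
  n_edges_total <- length(vals)
  groups <- unique(clusters$group)
  d <- density
  escalations <- 0L
  repeat {
    m <- max(1L, ceiling(d * n_edges_total))
    ord <- order(-vals, ut[, 1L], ut[, 2L])
    sel <- ord[seq_len(min(m, n_edges_total))]
    g <- igraph::graph_from_data_frame(
      data.frame(from = ut[sel, 1L], to = ut[sel, 2L]),
      directed = FALSE, vertices = data.frame(name = seq_len(k)))
    comp <- igraph::components(g)
    giant <- which.max(comp$csize)
    in_giant <- comp$membership == giant
    network_connected <- vapply(groups, function(gr)
      any(in_giant[which(clusters$group == gr)]), logical(1L))
    if (all(network_connected) || d >= 1) break
    d <- min(1, d + step)
    escalations <- escalations + 1L
  }
  disconnected <- !all(network_connected)
  if (disconnected)
    warning("graph still disconnected at density 1.0; exporting as is")
  edges <- data.frame(from = ut[sel, 1L], to = ut[sel, 2L],
                      weight = vals[sel])
  nodes <- data.frame(id = seq_len(k), cluster = clusters$cluster,
                      group = clusters$group,
                      size = vapply(cluster_nodes, length, 1L))
  structure(list(nodes = nodes, edges = edges, density = d,
                 escalations = escalations, disconnected = disconnected),
            class = "spring_graph")
}

#' Write a spring graph as weighted edge-list TSV and GEXF
#'
#' @param sg a `spring_graph`.
#' @param stem path stem; writes `<stem>_edges.tsv`, `<stem>_nodes.tsv`,
#'   and `<stem>.gexf`.
#' @export
write_spring_graph <- function(sg, stem) {
  stopifnot(inherits(sg, "spring_graph"))
  utils::write.table(sg$edges, paste0(stem, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sg$nodes, paste0(stem, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gexf <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '<graph mode="static" defaultedgetype="undirected">',
    '<nodes>',
    sprintf('<node id="%d" label="%s (%s)" />',
            sg$nodes$id, sg$nodes$cluster, sg$nodes$group),
    '</nodes>',
    '<edges>',
    sprintf('<edge id="%d" source="%d" target="%d" weight="%.6f" />',
            seq_len(nrow(sg$edges)), sg$edges$from, sg$edges$to,
            sg$edges$weight),
    '</edges>',
    '</graph>', '</gexf>')
  writeLines(gexf, paste0(stem, ".gexf"))
  invisible(stem)
}
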