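#' Community detection on a thresholded connectivity graph
#'
#' Runs flow-based (map equation / Infomap) or modularity-based (multilevel
#' Louvain) community detection on a sparsified graph, treating the
#' optimizer as a pluggable contract: both must recover well-separated
#' planted partitions, and results are deterministic given `seed`.
#' Communities smaller than `min_size` are relabeled 0 (unassigned).
#'
#' @param graph symmetric nonnegative matrix (typically the 0/1 output of
#'   [density_threshold_rowcol()]) or an `igraph` object.
#' @param method `"map_equation"` (Infomap) or `"modularity"` (Louvain).
#' @param seed integer RNG seed.
#' @param min_size minimum community size; smaller communities get label 0.
#' @return object of class `community_solution`: `labels` (a `label_map`),
#'   `method`, `quality` (codelength for Infomap, modularity for Louvain),
#'   `seed`.
#' @export
detect_communities <- function(graph, method = c("map_equation", "modularity"),
                               seed = 1L, min_size = 1L) {
  method <- match.arg(method)
  if (inherits(graph, "igraph")) {
    g <- graph
    n <- igraph::vcount(g)
  } else {
    graph <- as.matrix(graph)
    n <- nrow(graph)
    if (n == 0L) stop("empty graph", call. = FALSE)
    if (any(graph < 0, na.rm = TRUE))
      stop("graph weights must be nonnegative", call. = FALSE)
    graph[is.na(graph)] <- 0
    g <- igraph::graph_from_adjacency_matrix(graph, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
  }
  if (igraph::ecount(g) == 0L) stop("empty graph (no edges)", call. = FALSE)
  set.seed(seed)
  comm <- if (method == "map_equation") {
    igraph::cluster_infomap(g, e.weights = igraph::E(g)$weight)
  } else {
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  }
  lab <- igraph::membership(comm)
  quality <- if (method == "map_equation") {
    igraph::code_len(comm)
  } else {
    igraph::modularity(g, lab, weights = igraph::E(g)$weight)
  }
  lab <- as.integer(lab)
  sizes <- table(lab)
  small <- as.integer(names(sizes)[sizes < min_size])
  lab[lab %in% small] <- 0L
  # compact nonzero labels to 1..k in order of first appearance
  nz <- lab != 0L
  lab[nz] <- as.integer(factor(lab[nz], levels = unique(lab[nz])))
  structure(list(labels = label_map(lab), method = method,
                 quality = as.numeric(quality), seed = as.integer(seed)),
            class = "community_solution")
}

#' @export
print.community_solution <- function(x, ...) {
  k <- length(unique(x$labels$label[x$labels$label > 0L]))
  cat(sprintf("<community_solution> %s: %d communities over %d nodes (quality %.4f)\n",
              x$method, k, n_nodes(x$labels), x$quality))
  invisible(x)
}

#' A subject's set of subnetworks
#'
#' @param subject_id subject identifier.
#' @param members list of integer node-index vectors, one per subnetwork.
#' @param density the graph density the communities were detected at.
#' @export
subnetwork_set <- function(subject_id, members, density = NA_real_) {
  stopifnot(is.list(members))
  members <- lapply(members, function(m) sort(unique(as.integer(m))))
  if (any(vapply(members, length, 1L) == 0L))
    stop("empty subnetwork member set", call. = FALSE)
  structure(list(subject_id = as.character(subject_id), members = members,
                 density = density), class = "subnetwork_set")
}

#' @export
print.subnetwork_set <- function(x, ...) {
  cat(sprintf("<subnetwork_set> %s: %d subnetworks (sizes %s)\n",
              x$subject_id, length(x$members),
              paste(vapply(x$members, length, 1L), collapse = ", ")))
  invisible(x)
}

#' Extract the subnetworks of a parent network
#'
#' Keeps the communities of a sparse-tier solution whose overlap with the
#' parent-network mask is at least `overlap_fraction` of the community's
#' nodes (>= at the boundary); each kept community becomes one subnetwork
#' consisting of its own nodes. An empty result is a warning, not an error.
#'
#' @param solution `community_solution` at the subnetwork-tier density.
#' @param parent_mask logical vector or integer node indices marking the
#'   parent network.
#' @param subject_id subject identifier for the returned set.
#' @param overlap_fraction minimum in-mask fraction (default 0.5).
#' @param density recorded in the output.
#' @return a `subnetwork_set`.
#' @export
extract_parent_subnetworks <- function(solution, parent_mask,
                                       subject_id = "sub-01",
                                       overlap_fraction = 0.5,
                                       density = NA_real_) {
  stopifnot(inherits(solution, "community_solution"))
  lab <- solution$labels$label
  mask <- if (is.logical(parent_mask)) which(parent_mask)
          else as.integer(parent_mask)
  keep <- list()
  for (k in sort(unique(lab[lab > 0L]))) {
    nodes <- which(lab == k)
    if (length(intersect(nodes, mask)) / length(nodes) >= overlap_fraction)
      keep[[length(keep) + 1L]] <- nodes
  }
  if (length(keep) == 0L) {
    warning("no community overlaps the parent network at fraction ",
            overlap_fraction)
    return(structure(list(subject_id = as.character(subject_id),
                          members = list(), density = density),
                     class = "subnetwork_set"))
  }
  subnetwork_set(subject_id, keep, density = density)
}

#' Identify a template network among detected communities
#'
#' Assigns each detected community the template label maximizing Jaccard
#' overlap and returns the node mask of the community (or communities)
#' assigned to `target_label`. Communities overlapping no template label are
#' left unassigned with a warning.
#'
#' @param solution network-tier `community_solution`.
#' @param template canonical network `label_map`.
#' @param target_label template label whose mask is wanted.
#' @return list: `mask` (integer node indices of the target network),
#'   `assignment` (data frame community -> template label, Jaccard).
#' @export
identify_parent_network <- function(solution, template, target_label) {
  stopifnot(inherits(solution, "community_solution"),
            inherits(template, "label_map"))
  lab <- solution$labels$label
  comms <- sort(unique(lab[lab > 0L]))
  tlabs <- sort(unique(template$label[template$label > 0L]))
  rows <- lapply(comms, function(k) {
    nodes <- which(lab == k)
    j <- vapply(tlabs, function(tl)
      jaccard(nodes, label_nodes(template, tl)), numeric(1L))
    best <- which.max(j)
    data.frame(community = k,
               template_label = if (j[best] > 0) tlabs[best] else NA_integer_,
               jaccard = j[best])
  })
  assignment <- do.call(rbind, rows)
  if (anyNA(assignment$template_label))
    warning("community with zero overlap to every template network left unassigned")
  hit <- assignment$community[!is.na(assignment$template_label) &
                                assignment$template_label == target_label]
  mask <- which(lab %in% hit)
  if (!length(mask))
    warning("no detected community matched template label ", target_label)
  list(mask = mask, assignment = assignment)
}
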