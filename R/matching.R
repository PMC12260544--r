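#' Jaccard coefficient of two node sets
#'
#' `|a intersect b| / |a union b|`. Both sets empty is an error (the
#' coefficient is undefined), not zero.
#'
#' @param a,b integer node-index vectors.
#' @return numeric in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  u <- length(union(a, b))
  if (u == 0L) stop("jaccard of two empty sets is undefined", call. = FALSE)
  length(intersect(a, b)) / u
}

#' Cross-subject subnetwork overlap matrix
#'
#' Pairwise spatial overlap (Jaccard) between every subnetwork instance of
#' every subject, yielding an instance x instance matrix with diagonal 1.
#' Within-subject pairs are included; disjoint within-subject subnetworks
#' contribute zeros.
#'
#' @param sets list of `subnetwork_set`, one per subject.
#' @param cortex_nodes optional integer node indices to restrict the
#'   comparison to (cortex-first matching); `NULL` uses all nodes.
#' @return object of class `overlap_matrix`: `values` (symmetric Jaccard
#'   matrix), `subject` and `subnetwork` instance index vectors.
#' @export
overlap_matrix <- function(sets, cortex_nodes = NULL) {
  stopifnot(all(vapply(sets, inherits, logical(1L), "subnetwork_set")))
  subject <- character(0); subnetwork <- integer(0); members <- list()
  for (s in sets) {
    for (k in seq_along(s$members)) {
      m <- s$members[[k]]
      if (!is.null(cortex_nodes)) m <- intersect(m, cortex_nodes)
      if (length(m) == 0L) next
      subject <- c(subject, s$subject_id)
      subnetwork <- c(subnetwork, k)
      members[[length(members) + 1L]] <- m
    }
  }
  n <- length(members)
  if (n == 0L) stop("no subnetwork instances to match", call. = FALSE)
  v <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      v[i, j] <- v[j, i] <- jaccard(members[[i]], members[[j]])
    }
  }
  structure(list(values = v, subject = subject, subnetwork = subnetwork,
                 members = members), class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix> %d instances from %d subjects\n",
              length(x$subject), length(unique(x$subject))))
  invisible(x)
}

#' Cluster the overlap matrix into matched subnetworks
#'
#' Runs multilevel Louvain on the Jaccard-weighted instance graph,
#' iteratively (reshuffling the seeded node order each round) until the
#' modularity of the clustering no longer exceeds that of the previous
#' round, then discards clusters represented in fewer than
#' `min_subject_fraction` of subjects (the half-of-subjects rule by
#' default). Deterministic given `seed`.
#'
#' @param om an `overlap_matrix`.
#' @param n_subjects total number of subjects in the study (the filter
#'   denominator); defaults to the number of distinct subjects in `om`.
#' @param min_subject_fraction retention threshold (>=).
#' @param seed integer RNG seed.
#' @param max_iter safety cap on Louvain rounds.
#' @return list of `matched_cluster` objects (class `matched_clusters`),
#'   each with `members` (data frame: subject, subnetwork, instance index),
#'   `subjects`, `name`. The full (unfiltered) instance assignment is kept
#'   in attribute `"assignment"`; an empty result warns.
#' @export
cluster_overlap_matrix <- function(om, n_subjects = NULL,
                                   min_subject_fraction = 0.5, seed = 1L,
                                   max_iter = 100L) {
  stopifnot(inherits(om, "overlap_matrix"))
  if (is.null(n_subjects)) n_subjects <- length(unique(om$subject))
  n <- nrow(om$values)
  w <- om$values
  diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  best_mod <- -Inf
  best_lab <- seq_len(n)  # no overlap anywhere: every instance its own cluster
  for (it in if (igraph::ecount(g) == 0L) integer(0) else seq_len(max_iter)) {
    perm <- sample(n)  # fresh seeded node order each round
    gp <- igraph::permute(g, perm)
    comm <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight,
                                    resolution = 1.0)
    # igraph::permute maps old vertex i to new id perm[i]
    lab <- as.integer(igraph::membership(comm))[perm]
    mod <- igraph::modularity(g, lab, weights = igraph::E(g)$weight)
    if (mod > best_mod) {
      best_mod <- mod
      best_lab <- lab
    } else break  # modularity no longer higher than the previous round
  }
  assignment <- data.frame(instance = seq_len(n), subject = om$subject,
                           subnetwork = om$subnetwork, cluster = best_lab)
  clusters <- list()
  for (k in sort(unique(best_lab))) {
    idx <- which(best_lab == k)
    subs <- unique(om$subject[idx])
    if (length(subs) < min_subject_fraction * n_subjects) next
    cl <- structure(list(
      name = sprintf("cluster_%d", length(clusters) + 1L),
      members = assignment[idx, c("instance", "subject", "subnetwork")],
      member_nodes = om$members[idx],
      subjects = subs), class = "matched_cluster")
    clusters[[length(clusters) + 1L]] <- cl
  }
  if (length(clusters) == 0L)
    warning("every cluster fell below the minimum subject fraction")
  structure(clusters, class = "matched_clusters",
            assignment = assignment, modularity = best_mod)
}

#' @export
print.matched_clusters <- function(x, ...) {
  cat(sprintf("<matched_clusters> %d retained cluster(s), modularity %.4f\n",
              length(x), attr(x, "modularity")))
  for (cl in x)
    cat(sprintf("  %s: %d instances, %d subjects\n", cl$name,
                nrow(cl$members), length(cl$subjects)))
  invisible(x)
}

#' Cross-subject density map of one matched cluster
#'
#' For every node, the number of distinct subjects whose matched subnetwork
#' covers it. A subject contributing several instances to the cluster still
#' counts once per node (counts are numbers of individuals).
#'
#' @param cluster a `matched_cluster`.
#' @param n_nodes number of nodes in the space.
#' @return integer vector of per-node subject counts (class `density_map`,
#'   with attribute `n_subjects` = subjects represented in the cluster).
#' @export
density_map <- function(cluster, n_nodes) {
  stopifnot(inherits(cluster, "matched_cluster"))
  count <- integer(n_nodes)
  for (s in unique(cluster$members$subject)) {
    idx <- which(cluster$members$subject == s)
    nodes <- unique(unlist(cluster$member_nodes[idx]))
    count[nodes] <- count[nodes] + 1L
  }
  structure(count, class = "density_map",
            n_subjects = length(unique(cluster$members$subject)))
}

#' Threshold a density map
#'
#' `min_subjects` mode keeps nodes with at least `k` subjects (the display
#' convention); `fraction` mode keeps nodes covered in strictly more than
#' `f * n_subjects` subjects (the region-extraction convention, read
#' literally from its ">10% of participants" rule).
#'
#' @param dm a `density_map` (or plain integer vector).
#' @param mode `"min_subjects"` or `"fraction"`.
#' @param k minimum subject count (min_subjects mode).
#' @param f fraction of subjects (fraction mode, strict >).
#' @param n_subjects denominator for fraction mode.
#' @return integer node indices retained.
#' @export
threshold_density <- function(dm, mode = c("min_subjects", "fraction"),
                              k = 3L, f = 0.10, n_subjects = NULL) {
  mode <- match.arg(mode)
  counts <- as.integer(dm)
  if (mode == "min_subjects") {
    which(counts >= k)
  } else {
    if (is.null(n_subjects)) n_subjects <- attr(dm, "n_subjects")
    if (is.null(n_subjects))
      stop("fraction mode needs n_subjects", call. = FALSE)
    which(counts > f * n_subjects)
  }
}

#' Winner-take-all map across matched-cluster density maps
#'
#' Assigns each node to the cluster with the maximal subject count;
#' zero-count nodes stay unassigned (0). Ties are broken deterministically
#' by cluster order and flagged in the `tie` attribute.
#'
#' @param dms list of `density_map`s (same length), named by cluster.
#' @return `label_map` with labels 1..length(dms); logical attribute
#'   `"tie"` marks nodes where the maximum was shared.
#' @export
winner_take_all <- function(dms) {
  stopifnot(length(dms) >= 1L)
  m <- do.call(cbind, lapply(dms, as.integer))
  top <- apply(m, 1L, max)
  lab <- apply(m, 1L, which.max)  # first-listed cluster wins ties
  lab[top == 0L] <- 0L
  tie <- rowSums(m == top) > 1L & top > 0L
  out <- label_map(as.integer(lab))
  attr(out, "tie") <- tie
  out
}
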