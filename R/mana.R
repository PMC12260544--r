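#' Coordinate meta-analytic database
#'
#' Standard layout: an activations table of study peak coordinates (mm) and
#' a study x term weight matrix with weights in [0, 1]. Every study carrying
#' feature weights must report at least one activation peak.
#'
#' @param activations data frame with columns `study_id`, `x`, `y`, `z`.
#' @param features numeric matrix, studies in rows (rownames = study ids),
#'   terms in columns, weights in [0, 1].
#' @return object of class `meta_database`.
#' @export
meta_database <- function(activations, features) {
  need <- c("study_id", "x", "y", "z")
  if (!all(need %in% names(activations)))
    stop("activations must have columns study_id, x, y, z", call. = FALSE)
  features <- as.matrix(features)
  if (nrow(features) > 0L && is.null(rownames(features)))
    stop("features must have study ids as rownames", call. = FALSE)
  if (any(features < 0 | features > 1, na.rm = TRUE))
    stop("term weights must lie in [0, 1]", call. = FALSE)
  missing <- setdiff(rownames(features), unique(activations$study_id))
  if (length(missing))
    stop("featured studies without activation peaks: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  structure(list(activations = activations, features = features),
            class = "meta_database")
}

#' @export
print.meta_database <- function(x, ...) {
  cat(sprintf("<meta_database> %d peaks, %d studies, %d terms\n",
              nrow(x$activations), nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Extract connected regions of a thresholded density map
#'
#' Connected components of the node set under the mesh adjacency; each
#' component is a region with node set, area-weighted centroid, and summed
#' area. Components not larger than `min_area` mm^2 are dropped.
#'
#' @param nodes integer node indices (e.g. from [threshold_density()]).
#' @param space a `node_space`.
#' @param min_area area threshold in mm^2 (keep strictly larger).
#' @return object of class `region_set`: list of regions, each
#'   `list(nodes, centroid, area)`.
#' @export
extract_regions <- function(nodes, space, min_area = 20) {
  stopifnot(inherits(space, "node_space"))
  nodes <- sort(unique(as.integer(nodes)))
  if (length(nodes) == 0L) stop("empty node set", call. = FALSE)
  a <- space$adjacency
  keep <- a[, 1L] %in% nodes & a[, 2L] %in% nodes
  idx <- match(a[keep, , drop = FALSE], nodes)
  g <- igraph::graph_from_edgelist(matrix(idx, ncol = 2L), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(nodes) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  regions <- list()
  for (k in seq_len(max(comp))) {
    rn <- nodes[comp == k]
    area <- sum(space$area[rn])
    if (area <= min_area) next
    w <- space$area[rn] / area
    centroid <- colSums(space$coord[rn, , drop = FALSE] * w)
    regions[[length(regions) + 1L]] <-
      list(nodes = rn, centroid = centroid, area = area)
  }
  structure(regions, class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d region(s), areas: %s mm^2\n", length(x),
              paste(round(vapply(x, `[[`, 1.0, "area")), collapse = ", ")))
  invisible(x)
}

#' Match database studies to a distributed region set
#'
#' A region is hit when any of a study's peaks lies strictly closer than
#' `radius_mm` (Euclidean, mm) to any node of that region; a study matches
#' the subnetwork when it hits at least `ceiling(fraction * n_regions)`
#' regions. So a study must report activity near a substantial share of the
#' subnetwork's regions, not just one location. Monotone: enlarging the
#' radius or shrinking the fraction never removes a match.
#'
#' @param db a `meta_database`.
#' @param regions a `region_set` (nonempty).
#' @param space the `node_space` the regions live in.
#' @param radius_mm peak-to-region distance bound (strict <).
#' @param fraction minimum fraction of regions hit (>= after ceiling).
#' @param use_centroids measure peak distance to region centroids instead of
#'   region nodes (alternative reading; default uses nodes).
#' @return character vector of matched study ids.
#' @export
match_studies <- function(db, regions, space, radius_mm = 2.0,
                          fraction = 0.40, use_centroids = FALSE) {
  stopifnot(inherits(db, "meta_database"), inherits(regions, "region_set"))
  if (length(regions) == 0L) stop("region set is empty", call. = FALSE)
  need <- ceiling(fraction * length(regions))
  peaks <- as.matrix(db$activations[, c("x", "y", "z")])
  study <- db$activations$study_id
  region_pts <- lapply(regions, function(r) {
    if (use_centroids) matrix(r$centroid, ncol = 3L)
    else space$coord[r$nodes, , drop = FALSE]
  })
  matched <- character(0)
  for (sid in unique(study)) {
    p <- peaks[study == sid, , drop = FALSE]
    hits <- 0L
    for (pts in region_pts) {
      d2 <- outer(rowSums(p^2), rowSums(pts^2), "+") - 2 * tcrossprod(p, pts)
      if (min(d2) < radius_mm^2) hits <- hits + 1L
    }
    if (hits >= need) matched <- c(matched, sid)
  }
  matched
}

#' One-way term ANOVA across matched subnetworks
#'
#' The term's study weights, grouped by which subnetwork the study matched,
#' enter a one-way fixed-effects ANOVA; a significant term is associated
#' with the subnetwork exhibiting the largest average weight. The display
#' magnitude is that maximal group mean minus the grand mean. A study
#' matching several subnetworks contributes its weight to each group.
#' Degenerate groupings (fewer than 2 groups with 2 studies, or zero
#' variance everywhere) return `NULL` (term skipped), with a message.
#'
#' @param db a `meta_database`.
#' @param matches named list: subnetwork name -> matched study ids.
#' @param term term (column of the features table).
#' @return list: `term`, `F`, `df` (pair), `p`, `group_means`, `assigned`,
#'   `magnitude`; or `NULL` when skipped.
#' @export
term_anova <- function(db, matches, term) {
  stopifnot(inherits(db, "meta_database"))
  if (!term %in% colnames(db$features))
    stop("unknown term: ", term, call. = FALSE)
  w <- list(); g <- list()
  for (nm in names(matches)) {
    ids <- intersect(matches[[nm]], rownames(db$features))
    if (length(ids) < 2L) next
    w[[nm]] <- db$features[ids, term]
    g[[nm]] <- rep(nm, length(ids))
  }
  if (length(w) < 2L) {
    message("term ", term, " skipped: fewer than 2 usable groups")
    return(NULL)
  }
  weights <- unlist(w, use.names = FALSE)
  group <- factor(unlist(g, use.names = FALSE), levels = names(w))
  if (stats::var(weights) == 0) {
    message("term ", term, " skipped: zero variance")
    return(NULL)
  }
  fit <- stats::lm(weights ~ group)
  an <- stats::anova(fit)
  gm <- tapply(weights, group, mean)
  assigned <- names(gm)[which.max(gm)]  # first-listed wins exact ties
  list(term = term,
       F = an[1L, "F value"], df = c(an[1L, "Df"], an[2L, "Df"]),
       p = an[1L, "Pr(>F)"], group_means = gm,
       assigned = assigned, magnitude = max(gm) - mean(weights))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up control of the false discovery rate; q values are monotone in p
#' and satisfy q >= p.
#'
#' @param p numeric p values.
#' @param alpha FDR level.
#' @return list: `q` (adjusted values), `reject` (logical).
#' @export
fdr_correct <- function(p, alpha = 0.05) {
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = q <= alpha)
}

#' Full term annotation table for a set of subnetworks
#'
#' Matches studies to each subnetwork's regions, runs the per-term ANOVA
#' over a curated term list, applies FDR, and assigns each term to its
#' argmax-mean subnetwork.
#'
#' @param db a `meta_database`.
#' @param region_sets named list: subnetwork name -> `region_set`.
#' @param space the `node_space`.
#' @param terms terms to test; defaults to all feature columns.
#' @param radius_mm,fraction,use_centroids see [match_studies()].
#' @param alpha FDR level.
#' @return data frame (class `term_table`): term, F, df1, df2, p, q,
#'   significant (FDR), assigned subnetwork, magnitude. Attribute
#'   `"matches"` carries the per-subnetwork matched study lists and
#'   `"multi_match_count"` the number of studies matching several
#'   subnetworks.
#' @export
mana_annotate <- function(db, region_sets, space, terms = NULL,
                          radius_mm = 2.0, fraction = 0.40,
                          use_centroids = FALSE, alpha = 0.05) {
  if (is.null(terms)) terms <- colnames(db$features)
  matches <- lapply(region_sets, function(rs)
    match_studies(db, rs, space, radius_mm = radius_mm, fraction = fraction,
                  use_centroids = use_centroids))
  names(matches) <- names(region_sets)
  multi <- sum(table(unlist(matches)) > 1L)
  rows <- list()
  for (tm in terms) {
    res <- suppressMessages(term_anova(db, matches, tm))
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- data.frame(
      term = tm, F = res$F, df1 = res$df[1L], df2 = res$df[2L], p = res$p,
      assigned = res$assigned, magnitude = res$magnitude)
  }
  if (length(rows) == 0L) {
    out <- data.frame(term = character(0), F = numeric(0), df1 = integer(0),
                      df2 = integer(0), p = numeric(0), q = numeric(0),
                      significant = logical(0), assigned = character(0),
                      magnitude = numeric(0))
  } else {
    out <- do.call(rbind, rows)
    fdr <- fdr_correct(out$p, alpha)
    out$q <- fdr$q
    out$significant <- fdr$reject
    out <- out[, c("term", "F", "df1", "df2", "p", "q", "significant",
                   "assigned", "magnitude")]
  }
  attr(out, "matches") <- matches
  attr(out, "multi_match_count") <- multi
  class(out) <- c("term_table", class(out))
  out
}

#' Activation-peak density map
#'
#' For each node, the number of database activation peaks within
#' `radius_mm` (inclusive). Highlights how unevenly the literature samples
#' the space.
#'
#' @param db a `meta_database`.
#' @param space a `node_space`.
#' @param radius_mm count radius (<=).
#' @return integer per-node peak counts.
#' @export
peak_density_map <- function(db, space, radius_mm = 4.0) {
  stopifnot(inherits(db, "meta_database"), inherits(space, "node_space"))
  peaks <- as.matrix(db$activations[, c("x", "y", "z")])
  if (nrow(peaks) == 0L) return(integer(n_nodes(space)))
  co <- space$coord
  d2 <- outer(rowSums(co^2), rowSums(peaks^2), "+") - 2 * tcrossprod(co, peaks)
  as.integer(rowSums(d2 <= radius_mm^2 + 1e-9))
}

#' Curate a term list with include/exclude lexicons
#'
#' Curation is data, not code: the caller supplies the lexicons. Duplicates
#' are collapsed; an include lexicon (when given) is applied before the
#' exclude lexicon.
#'
#' @param terms character vector.
#' @param include optional lexicon of terms to keep.
#' @param exclude optional lexicon of terms to drop.
#' @return curated character vector.
#' @export
term_filter <- function(terms, include = NULL, exclude = NULL) {
  out <- unique(terms)
  if (!is.null(include)) out <- out[out %in% include]
  if (!is.null(exclude)) out <- out[!out %in% exclude]
  out
}
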