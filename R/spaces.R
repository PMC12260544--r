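#' Node spaces, timeseries, and label maps
#'
#' A `node_space` is the geometric substrate shared by every stage: node
#' coordinates in mm, an undirected mesh adjacency, a per-node surface area,
#' and a structure tag (left cortex, right cortex, subcortex). A
#' `timeseries` holds one subject's node x time signal matrix; a `label_map`
#' assigns each node a nonnegative integer label (0 = unassigned) with a
#' label table carrying names and colors.
#'
#' @name data-model
NULL

#' Construct a node space
#'
#' @param coord numeric n x 3 matrix of mm coordinates.
#' @param adjacency two-column integer matrix of undirected node pairs
#'   (1-based indices); stored symmetrized and irreflexive.
#' @param area per-node surface area in mm^2; defaults to 1 mm^2 per node
#'   (with a warning) when the input carries no geometry.
#' @param structure character vector per node, one of `"cortex_left"`,
#'   `"cortex_right"`, `"subcortex"`.
#' @return object of class `node_space`.
#' @export
node_space <- function(coord, adjacency = NULL, area = NULL,
                       structure = NULL) {
  coord <- as.matrix(coord)
  if (ncol(coord) != 3L) stop("coord must be an n x 3 matrix", call. = FALSE)
  if (!all(is.finite(coord))) stop("coordinates must be finite", call. = FALSE)
  n <- nrow(coord)
  if (is.null(adjacency)) {
    adjacency <- matrix(integer(0), ncol = 2L)
  } else {
    adjacency <- as.matrix(adjacency)
    storage.mode(adjacency) <- "integer"
    if (ncol(adjacency) != 2L)
      stop("adjacency must be a two-column matrix of node pairs", call. = FALSE)
    if (any(adjacency < 1L | adjacency > n))
      stop("adjacency indices out of range 1..", n, call. = FALSE)
    if (any(adjacency[, 1L] == adjacency[, 2L]))
      stop("adjacency must be irreflexive (no self-pairs)", call. = FALSE)
    # canonical order + dedupe, stored as (low, high)
    adjacency <- unique(cbind(pmin(adjacency[, 1L], adjacency[, 2L]),
                              pmax(adjacency[, 1L], adjacency[, 2L])))
  }
  if (is.null(area)) {
    warning("node areas not supplied; defaulting to 1 mm^2 per node")
    area <- rep(1, n)
  }
  if (length(area) != n) stop("area length must match node count", call. = FALSE)
  if (is.null(structure)) structure <- rep("cortex_left", n)
  if (length(structure) == 1L) structure <- rep(structure, n)
  ok <- structure %in% c("cortex_left", "cortex_right", "subcortex")
  if (!all(ok))
    stop("structure tags must be cortex_left, cortex_right or subcortex",
         call. = FALSE)
  if (length(structure) != n)
    stop("structure length must match node count", call. = FALSE)
  cortical <- structure != "subcortex"
  if (any(area[cortical] <= 0))
    stop("cortical node areas must be > 0", call. = FALSE)
  structure(list(coord = coord, adjacency = adjacency,
                 area = as.numeric(area), structure = structure),
            class = "node_space")
}

#' @export
print.node_space <- function(x, ...) {
  cat(sprintf("<node_space> %d nodes, %d edges, total area %.0f mm^2\n",
              n_nodes(x), nrow(x$adjacency), sum(x$area)))
  invisible(x)
}

#' Number of nodes in a space / labels / timeseries
#' @param x object.
#' @export
n_nodes <- function(x) UseMethod("n_nodes")
#' @export
n_nodes.node_space <- function(x) nrow(x$coord)
#' @export
n_nodes.timeseries <- function(x) nrow(x$values)
#' @export
n_nodes.label_map <- function(x) length(x$label)

#' Regular grid node space
#'
#' A planar sheet of nodes with rook adjacency, used by the synthetic-data
#' generator as a stand-in for a cortical surface patch. Node area is
#' `spacing_mm^2`.
#'
#' @param nx,ny grid dimensions.
#' @param spacing_mm grid spacing in mm.
#' @return `node_space` with `nx * ny` nodes (x fastest).
#' @export
grid_node_space <- function(nx, ny, spacing_mm = 6) {
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  coord <- cbind((ix - 1) * spacing_mm, (iy - 1) * spacing_mm, 0)
  id <- function(x, y) (y - 1L) * nx + x
  right <- cbind(id(ix, iy), id(ix + 1L, iy))[ix < nx, , drop = FALSE]
  up <- cbind(id(ix, iy), id(ix, iy + 1L))[iy < ny, , drop = FALSE]
  node_space(coord, rbind(right, up), area = rep(spacing_mm^2, nx * ny))
}

#' Construct a timeseries
#'
#' @param values node x time numeric matrix.
#' @param tr sampling interval in seconds (> 0).
#' @param subject_id subject identifier.
#' @param run_boundaries ordered 1-based frame indices at which runs start;
#'   first element must be 1.
#' @param space optional `node_space`; when given, the node dimension is
#'   checked against it.
#' @return object of class `timeseries`.
#' @export
timeseries <- function(values, tr, subject_id = "sub-01",
                       run_boundaries = 1L, space = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("tr must be a positive scalar (seconds)", call. = FALSE)
  if (anyNA(values))
    stop("timeseries has missing frames inside a run", call. = FALSE)
  run_boundaries <- as.integer(run_boundaries)
  if (length(run_boundaries) < 1L || run_boundaries[1L] != 1L ||
      is.unsorted(run_boundaries, strictly = TRUE) ||
      any(run_boundaries > ncol(values)))
    stop("run_boundaries must be strictly increasing frame indices starting at 1",
         call. = FALSE)
  if (!is.null(space) && nrow(values) != n_nodes(space))
    stop(sprintf("timeseries has %d nodes but node space has %d (node axis mismatch)",
                 nrow(values), n_nodes(space)), call. = FALSE)
  structure(list(values = values, tr = tr,
                 subject_id = as.character(subject_id),
                 run_boundaries = run_boundaries),
            class = "timeseries")
}

#' @export
print.timeseries <- function(x, ...) {
  cat(sprintf("<timeseries> %s: %d nodes x %d frames, tr = %g s, %d run(s)\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$tr,
              length(x$run_boundaries)))
  invisible(x)
}

#' Per-run frame index list of a timeseries
#' @param ts a `timeseries`.
#' @return list of integer frame-index vectors, one per run.
#' @export
run_frames <- function(ts) {
  starts <- ts$run_boundaries
  ends <- c(starts[-1L] - 1L, ncol(ts$values))
  Map(seq.int, starts, ends)
}

#' Construct a label map
#'
#' @param label integer vector, one nonnegative label per node (0 =
#'   unassigned).
#' @param label_table data frame with columns `label`, `name`, `color`; every
#'   nonzero label in `label` must appear. Auto-generated when omitted.
#' @return object of class `label_map`.
#' @export
label_map <- function(label, label_table = NULL) {
  label <- as.integer(label)
  if (any(is.na(label)) || any(label < 0L))
    stop("labels must be nonnegative integers", call. = FALSE)
  used <- sort(unique(label[label > 0L]))
  if (is.null(label_table)) {
    label_table <- data.frame(label = used,
                              name = sprintf("label_%d", used),
                              color = grDevices::hcl.colors(max(length(used), 1L))[
                                seq_along(used)],
                              stringsAsFactors = FALSE)
  }
  missing <- setdiff(used, label_table$label)
  if (length(missing))
    stop("labels missing from label_table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(label = label, label_table = label_table),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  k <- sum(x$label_table$label %in% x$label)
  cat(sprintf("<label_map> %d nodes, %d labels in use (%d unassigned)\n",
              length(x$label), k, sum(x$label == 0L)))
  invisible(x)
}

#' Node set of one label
#' @param lm a `label_map`.
#' @param lab label value.
#' @return integer node indices.
#' @export
label_nodes <- function(lm, lab) which(lm$label == lab)

pairwise_distances <- function(space, idx_a = NULL, idx_b = NULL) {
  a <- if (is.null(idx_a)) space$coord else space$coord[idx_a, , drop = FALSE]
  b <- if (is.null(idx_b)) space$coord else space$coord[idx_b, , drop = FALSE]
  # |a - b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
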