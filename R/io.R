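#' Plain-text readers and writers
#'
#' Every container round-trips through documented TSV schemas (with a JSON
#' sidecar where a table cannot carry metadata). Integer labels round-trip
#' bit-exactly; floats to better than 1e-6. Malformed input fails with a
#' message naming the offending file and axis.
#'
#' Schemas:
#' \describe{
#'   \item{node space}{`<stem>_nodes.tsv`: columns `node`, `x`, `y`, `z`,
#'     `area`, `structure`; `<stem>_edges.tsv`: columns `from`, `to`.}
#'   \item{timeseries}{matrix TSV, nodes in rows, frames in columns, plus a
#'     JSON sidecar `<path>.json` holding `subject_id`, `tr`,
#'     `run_boundaries`.}
#'   \item{label map}{two-column TSV `node`, `label` plus JSON sidecar with
#'     the label table.}
#'   \item{meta-analytic database}{`<stem>_activations.tsv`: `study_id`,
#'     `x`, `y`, `z`; `<stem>_features.tsv`: `study_id` then one column per
#'     term, weights in [0, 1].}
#' }
#' @name io
NULL

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s (%s): missing column(s) %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

check_numeric_col <- function(df, col, path, what) {
  v <- df[[col]]
  num <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(num) & !is.na(v))
  if (length(bad))
    stop(sprintf("%s (%s): non-numeric value in column '%s' at row %d",
                 what, path, col, bad[1L]), call. = FALSE)
  num
}

#' Write / read a node space as TSV
#'
#' @param space a `node_space`.
#' @param stem path stem; writes `<stem>_nodes.tsv` and `<stem>_edges.tsv`.
#' @return `read_node_space` returns a `node_space`.
#' @export
write_node_space <- function(space, stem) {
  stopifnot(inherits(space, "node_space"))
  nodes <- data.frame(node = seq_len(n_nodes(space)),
                      x = space$coord[, 1L], y = space$coord[, 2L],
                      z = space$coord[, 3L], area = space$area,
                      structure = space$structure)
  utils::write.table(nodes, paste0(stem, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  edges <- data.frame(from = space$adjacency[, 1L], to = space$adjacency[, 2L])
  utils::write.table(edges, paste0(stem, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' @rdname write_node_space
#' @export
read_node_space <- function(stem) {
  npath <- paste0(stem, "_nodes.tsv")
  nodes <- read_tsv_checked(npath, c("node", "x", "y", "z"), "node table")
  coord <- cbind(check_numeric_col(nodes, "x", npath, "node table"),
                 check_numeric_col(nodes, "y", npath, "node table"),
                 check_numeric_col(nodes, "z", npath, "node table"))
  ord <- order(nodes$node)
  coord <- coord[ord, , drop = FALSE]
  area <- if ("area" %in% names(nodes))
    check_numeric_col(nodes, "area", npath, "node table")[ord] else NULL
  struct <- if ("structure" %in% names(nodes)) nodes$structure[ord] else NULL
  epath <- paste0(stem, "_edges.tsv")
  adjacency <- NULL
  if (file.exists(epath)) {
    edges <- read_tsv_checked(epath, c("from", "to"), "edge table")
    if (nrow(edges)) adjacency <- cbind(edges$from, edges$to)
  }
  node_space(coord, adjacency, area = area, structure = struct)
}

#' Write / read a timeseries as matrix TSV + JSON sidecar
#'
#' @param ts a `timeseries`.
#' @param path TSV path (nodes in rows); sidecar written to `<path>.json`.
#' @param space optional `node_space` to validate the node axis on read.
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "timeseries"))
  utils::write.table(format(ts$values, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(subject_id = ts$subject_id, tr = ts$tr,
                            run_boundaries = ts$run_boundaries),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path, space = NULL) {
  if (!file.exists(path))
    stop("timeseries file not found: ", path, call. = FALSE)
  values <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(values) <- NULL
  if (!is.numeric(values))
    stop(sprintf("timeseries (%s): non-numeric values", path), call. = FALSE)
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("timeseries sidecar not found: ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  timeseries(values, tr = meta$tr, subject_id = meta$subject_id,
             run_boundaries = meta$run_boundaries, space = space)
}

#' Write / read a label map as two-column TSV + JSON sidecar
#'
#' @param lm a `label_map`.
#' @param path TSV path; label table sidecar at `<path>.json`.
#' @export
write_label_map <- function(lm, path) {
  stopifnot(inherits(lm, "label_map"))
  utils::write.table(data.frame(node = seq_along(lm$label), label = lm$label),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(lm$label_table, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  df <- read_tsv_checked(path, c("node", "label"), "label map")
  lab <- check_numeric_col(df, "label", path, "label map")
  lab <- lab[order(df$node)]
  side <- paste0(path, ".json")
  tab <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  label_map(lab, tab)
}

#' Write / read a meta-analytic database (Neurosynth-layout TSVs)
#'
#' @param db a `meta_database` (see [meta_database()]).
#' @param stem path stem; writes `<stem>_activations.tsv` and
#'   `<stem>_features.tsv`.
#' @export
write_meta_database <- function(db, stem) {
  stopifnot(inherits(db, "meta_database"))
  utils::write.table(db$activations, paste0(stem, "_activations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  feat <- data.frame(study_id = rownames(db$features), db$features,
                     check.names = FALSE)
  utils::write.table(feat, paste0(stem, "_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stem)
}

#' @rdname write_meta_database
#' @export
read_meta_database <- function(stem) {
  apath <- paste0(stem, "_activations.tsv")
  act <- read_tsv_checked(apath, c("study_id", "x", "y", "z"), "activations")
  for (col in c("x", "y", "z"))
    act[[col]] <- check_numeric_col(act, col, apath, "activations")
  fpath <- paste0(stem, "_features.tsv")
  feat <- read_tsv_checked(fpath, "study_id", "features")
  m <- as.matrix(feat[, setdiff(names(feat), "study_id"), drop = FALSE])
  rownames(m) <- as.character(feat$study_id)
  meta_database(act, m)
}

#' Write a subnetwork set / read it back
#'
#' JSON layout: subject id, density, and one integer node-index array per
#' subnetwork.
#' @param sns a `subnetwork_set`.
#' @param path JSON path.
#' @export
write_subnetwork_set <- function(sns, path) {
  stopifnot(inherits(sns, "subnetwork_set"))
  jsonlite::write_json(list(subject_id = sns$subject_id,
                            density = sns$density,
                            members = sns$members),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_subnetwork_set
#' @export
read_subnetwork_set <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  members <- raw$members
  if (is.matrix(members))  # jsonlite collapses equal-length member arrays
    members <- lapply(seq_len(nrow(members)), function(i) members[i, ])
  members <- lapply(members, as.integer)
  subnetwork_set(raw$subject_id, members, density = raw$density)
}
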