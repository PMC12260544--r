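#' Fisher-z connectivity matrix from a timeseries
#'
#' Node-by-node Pearson correlation of the signal rows, Fisher transformed
#' (`atanh`). Correlations are clipped to `+/- r_max` first so duplicated
#' rows yield a large finite z rather than infinity. Constant rows have no
#' defined correlation: their rows/columns are set to `NA` and their indices
#' reported in the `undefined_nodes` attribute (with a warning), never
#' silently zeroed. The diagonal is `NA` and excluded from all density
#' computations.
#'
#' @param ts a `timeseries` (>= 2 frames).
#' @param r_max clip bound for |r| before `atanh`.
#' @return object of class `connectivity_matrix`: list with `values`
#'   (symmetric node x node z matrix) and `undefined_nodes`.
#' @export
compute_connectivity <- function(ts, r_max = 0.999999) {
  stopifnot(inherits(ts, "timeseries"))
  x <- ts$values
  if (ncol(x) < 2L) stop("need >= 2 frames to correlate", call. = FALSE)
  sds <- apply(x, 1L, stats::sd)
  const <- which(sds == 0 | !is.finite(sds))
  r <- suppressWarnings(stats::cor(t(x)))
  r <- pmin(pmax(r, -r_max), r_max)
  z <- atanh(r)
  if (length(const)) {
    warning(sprintf("%d constant row(s) have undefined connectivity: %s",
                    length(const), paste(utils::head(const, 10L), collapse = ", ")))
    z[const, ] <- NA_real_
    z[, const] <- NA_real_
  }
  diag(z) <- NA_real_
  connectivity_matrix(z, undefined_nodes = const)
}

#' Construct a connectivity matrix object
#'
#' @param values symmetric numeric node x node matrix of Fisher-z values
#'   (`NA` marks undefined or excluded entries; the diagonal is ignored).
#' @param undefined_nodes integer indices of nodes with undefined rows.
#' @export
connectivity_matrix <- function(values, undefined_nodes = integer(0)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("connectivity matrix must be square", call. = FALSE)
  off <- values[upper.tri(values)]
  if (any(!is.finite(off) & !is.na(off)))
    stop("off-diagonal entries must be finite or NA", call. = FALSE)
  tv <- t(values)
  ut <- upper.tri(values)
  na_match <- is.na(values)[ut] == is.na(tv)[ut]
  val_match <- values[ut] == tv[ut]
  val_match[is.na(val_match)] <- TRUE  # NA-pattern already compared above
  if (!all(na_match) || !all(val_match))
    stop("connectivity matrix must be symmetric", call. = FALSE)
  diag(values) <- NA_real_
  structure(list(values = values,
                 undefined_nodes = as.integer(undefined_nodes)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d, %d undefined node(s)\n",
              nrow(x$values), ncol(x$values), length(x$undefined_nodes)))
  invisible(x)
}

#' Row/column density thresholding
#'
#' Sparsifies a connectivity matrix so that each row and each column retains
#' its top fraction of values: an entry is kept iff it is among the
#' `ceiling(density * (N - 1))` largest in its row or in its column (union
#' rule), then the kept mask is symmetrized. Ties at the cutoff are broken
#' by descending value then ascending partner index, so results are
#' deterministic. `NA` entries (undefined or excluded) are never retained.
#'
#' @param cm `connectivity_matrix` (or plain symmetric matrix).
#' @param density fraction in (0, 1] of off-diagonal entries kept per row.
#' @return symmetric 0/1 integer matrix (diagonal 0), with attribute
#'   `k` = retained count per row guaranteed by the rule.
#' @export
density_threshold_rowcol <- function(cm, density) {
  v <- if (inherits(cm, "connectivity_matrix")) cm$values else as.matrix(cm)
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  if (!is.numeric(density) || density <= 0 || density > 1)
    stop("density must lie in (0, 1]", call. = FALSE)
  k <- as.integer(ceiling(density * (n - 1L)))
  if (k < 1L) stop("density retains 0 entries per row", call. = FALSE)
  diag(v) <- NA_real_
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    row <- v[i, ]
    ok <- which(!is.na(row))
    if (length(ok) == 0L) next
    ord <- ok[order(-row[ok], ok)]
    keep[i, ord[seq_len(min(k, length(ord)))]] <- TRUE
  }
  mask <- keep | t(keep)  # union over row and column top-k
  out <- matrix(0L, n, n)
  out[mask] <- 1L
  dimnames(out) <- dimnames(v)
  attr(out, "k") <- k
  out
}

#' Exclude short-distance connections
#'
#' Sets to `NA` every entry whose node pair lies closer than `d_mm`
#' (3-D Euclidean distance on the supplied coordinates, strict `<`).
#' Idempotent; all other entries are unchanged. Used to guard connectivity
#' profiles against local signal autocorrelation.
#'
#' @param cm `connectivity_matrix`.
#' @param space `node_space` providing mm coordinates.
#' @param d_mm exclusion distance in mm (default 20).
#' @return `connectivity_matrix` with excluded entries set to `NA`.
#' @export
exclude_short_distance_edges <- function(cm, space, d_mm = 20) {
  stopifnot(inherits(cm, "connectivity_matrix"), inherits(space, "node_space"))
  v <- cm$values
  if (nrow(v) != n_nodes(space))
    stop("connectivity matrix and node space disagree on node count",
         call. = FALSE)
  if (d_mm > 0) {
    d <- pairwise_distances(space)
    v[d < d_mm] <- NA_real_
  }
  connectivity_matrix(v, undefined_nodes = cm$undefined_nodes)
}
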