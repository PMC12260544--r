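#' Planted multi-subject study design
#'
#' Defines the ground truth for every synthetic input the pipeline consumes:
#' a planar grid node space tiled into 8 contiguous subnetworks nested in 3
#' large-scale networks (subnetworks 1-4 form network 1, 5-6 network 2, 7-8
#' network 3), nested block correlation levels, per-subject topographic
#' jitter, optional per-structure signal lags carried by a shared
#' band-limited component, and a coordinate meta-analytic database with
#' planted term-subnetwork associations.
#'
#' Correlation levels must satisfy
#' `0 <= background_r < within_network_r < within_subnetwork_r < 1`.
#'
#' @param n_subjects number of synthetic subjects.
#' @param nx,ny,spacing_mm grid geometry (see [grid_node_space()]).
#' @param n_frames frames per subject; `tr` sampling interval (s).
#' @param within_subnetwork_r,within_network_r,background_r nested block
#'   correlation levels.
#' @param label_jitter_fraction fraction of nodes reassigned among
#'   neighboring labels per subject (topographic variability).
#' @param planted_lags named numeric vector, seconds, indexed by subnetwork
#'   id (as character); structures named here receive a delayed copy of a
#'   shared infraslow component. `NULL` disables the component.
#' @param lag_snr sd of the shared component relative to unit noise.
#' @param lag_band_hz passband of the shared component.
#' @param ar1_phi AR(1) coefficient of the node noise in lag mode.
#' @param planted_terms data frame with columns `term`, `subnetwork`,
#'   `shift`: term weights for studies matched to that subnetwork are
#'   shifted upward by `shift`. `NULL` for a null database.
#' @param n_studies,n_terms database size.
#' @param weight_base_max null term weights are Uniform(0, this); with the
#'   default 0.8 a +0.2 shift stays inside the required [0, 1] range.
#' @param rng_seed base seed; all per-subject seeds derive from it.
#' @return object of class `planted_design`.
#' @export
planted_design <- function(n_subjects = 10L,
                           nx = 20L, ny = 20L, spacing_mm = 6,
                           n_frames = 800L, tr = 1,
                           within_subnetwork_r = 0.6,
                           within_network_r = 0.3,
                           background_r = 0.05,
                           label_jitter_fraction = 0.10,
                           planted_lags = NULL,
                           lag_snr = 1,
                           lag_band_hz = c(0.01, 0.1),
                           ar1_phi = 0,
                           planted_terms = NULL,
                           n_studies = 500L,
                           n_terms = 250L,
                           weight_base_max = 0.8,
                           rng_seed = 1L) {
  if (!(background_r >= 0 && background_r < within_network_r &&
        within_network_r < within_subnetwork_r && within_subnetwork_r < 1))
    stop("need 0 <= background_r < within_network_r < within_subnetwork_r < 1",
         call. = FALSE)
  if (nx %% 4L != 0L || ny %% 2L != 0L)
    stop("grid must tile into 4 x 2 subnetwork blocks (nx divisible by 4, ny by 2)",
         call. = FALSE)
  space <- grid_node_space(nx, ny, spacing_mm)
  # 8 tiles: 4 across x, 2 across y; subnetwork id = row-major tile index
  tx <- nx %/% 4L; ty <- ny %/% 2L
  ix <- rep(seq_len(nx), times = ny); iy <- rep(seq_len(ny), each = nx)
  subnet <- ((iy - 1L) %/% ty) * 4L + ((ix - 1L) %/% tx) + 1L
  network_of_subnet <- c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L)
  design <- structure(list(
    n_subjects = as.integer(n_subjects),
    space = space, nx = as.integer(nx), ny = as.integer(ny),
    spacing_mm = spacing_mm,
    n_frames = as.integer(n_frames), tr = tr,
    within_subnetwork_r = within_subnetwork_r,
    within_network_r = within_network_r,
    background_r = background_r,
    label_jitter_fraction = label_jitter_fraction,
    planted_lags = planted_lags,
    lag_snr = lag_snr, lag_band_hz = as.numeric(lag_band_hz),
    ar1_phi = ar1_phi,
    planted_terms = planted_terms,
    n_studies = as.integer(n_studies), n_terms = as.integer(n_terms),
    weight_base_max = weight_base_max,
    truth_subnet = label_map(subnet),
    network_of_subnet = network_of_subnet,
    rng_seed = as.integer(rng_seed)), class = "planted_design")
  design
}

#' @export
print.planted_design <- function(x, ...) {
  cat(sprintf(
    "<planted_design> %d subjects, %d nodes (%dx%d grid), %d frames @ tr=%gs\n",
    x$n_subjects, n_nodes(x$space), x$nx, x$ny, x$n_frames, x$tr))
  cat(sprintf("  r: subnetwork %.2f > network %.2f > background %.2f; jitter %.0f%%\n",
              x$within_subnetwork_r, x$within_network_r, x$background_r,
              100 * x$label_jitter_fraction))
  invisible(x)
}

#' Network-tier truth labels of a design
#' @param design a `planted_design`.
#' @return `label_map` with network labels 1..3.
#' @export
truth_networks <- function(design) {
  label_map(design$network_of_subnet[design$truth_subnet$label])
}

# deterministic per-stream seed derivation (kept below 2^31)
derive_seed <- function(base, stream) {
  as.integer((as.numeric(base) * 48271 + as.numeric(stream)) %% 2147483587)
}

#' Per-subject ground-truth topography
#'
#' The shared subnetwork tiling, jittered independently per subject by
#' [jitter_labels()] to emulate inter-subject topographic variability.
#' Deterministic given the design seed.
#'
#' @param design a `planted_design`.
#' @param subject subject index (1-based).
#' @return list with `subnet` and `network` label maps.
#' @export
subject_truth <- function(design, subject) {
  sn <- jitter_labels(design$truth_subnet, design$label_jitter_fraction,
                      design$space,
                      seed = derive_seed(design$rng_seed, 1000L + subject))
  net <- label_map(design$network_of_subnet[sn$label])
  list(subnet = sn, network = net)
}

#' Jitter a label map among neighboring labels
#'
#' Reassigns exactly `round(fraction * N)` nodes to the label of one of
#' their mesh neighbors carrying a different label (boundary erosion), the
#' standard emulation of topographic variability. Nodes with no
#' differently-labeled neighbor fall back to a uniformly drawn other label.
#' Deterministic given `seed`.
#'
#' @param truth a `label_map`.
#' @param fraction fraction of nodes to reassign, in [0, 1).
#' @param space `node_space` supplying the mesh adjacency.
#' @param seed integer RNG seed.
#' @return jittered `label_map`.
#' @export
jitter_labels <- function(truth, fraction, space, seed = 1L) {
  stopifnot(inherits(truth, "label_map"), inherits(space, "node_space"))
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)", call. = FALSE)
  n <- n_nodes(truth)
  n_move <- round(fraction * n)
  if (n_move == 0L) return(truth)
  lab <- truth$label
  nbr <- adjacency_list(space)
  set.seed(seed)
  diff_nbr <- vapply(seq_len(n), function(i)
    any(lab[nbr[[i]]] != lab[i]), logical(1L))
  cand <- which(diff_nbr)
  if (length(cand) >= n_move) {
    move <- sample(cand, n_move)
  } else {
    move <- c(cand, sample(setdiff(seq_len(n), cand), n_move - length(cand)))
  }
  all_labs <- unique(lab)
  for (i in move) {
    alts <- unique(lab[nbr[[i]]])
    alts <- alts[alts != lab[i]]
    if (length(alts) == 0L) alts <- setdiff(all_labs, lab[i])
    lab[i] <- if (length(alts) == 1L) alts else sample(alts, 1L)
  }
  label_map(lab, truth$label_table)
}

adjacency_list <- function(space) {
  n <- n_nodes(space)
  nbr <- vector("list", n)
  a <- space$adjacency
  for (k in seq_len(nrow(a))) {
    i <- a[k, 1L]; j <- a[k, 2L]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  nbr
}

#' Simulate one subject's timeseries
#'
#' Draws a zero-mean Gaussian whose covariance is block-structured by the
#' subject's (jittered) nested subnetwork/network hierarchy, so sample
#' correlations converge to the design levels as frames grow. When
#' `planted_lags` is set, a shared band-limited component is added to each
#' named structure after a fractional delay (frequency-domain sinc shift),
#' and the node noise is AR(1) with coefficient `ar1_phi`.
#'
#' A requested covariance that is not positive definite is corrected by
#' eigenvalue flooring, with a warning.
#'
#' @param design a `planted_design`.
#' @param subject subject index (1-based).
#' @param truth optional precomputed [subject_truth()] output.
#' @return a `timeseries`.
#' @export
simulate_timeseries <- function(design, subject, truth = NULL) {
  if (is.null(truth)) truth <- subject_truth(design, subject)
  n <- n_nodes(design$space)
  tfr <- design$n_frames
  subnet <- truth$subnet$label
  network <- truth$network$label
  sigma <- matrix(design$background_r, n, n)
  same_net <- outer(network, network, "==")
  sigma[same_net] <- design$within_network_r
  same_sub <- outer(subnet, subnet, "==")
  sigma[same_sub] <- design$within_subnetwork_r
  diag(sigma) <- 1
  ch <- tryCatch(chol(sigma), error = function(e) {
    warning("requested covariance not positive definite; flooring eigenvalues")
    ev <- eigen(sigma, symmetric = TRUE)
    vals <- pmax(ev$values, 1e-8)
    chol(ev$vectors %*% (vals * t(ev$vectors)))
  })
  set.seed(derive_seed(design$rng_seed, 2000L + subject))
  if (is.null(design$planted_lags)) {
    x <- t(matrix(stats::rnorm(tfr * n), tfr, n) %*% ch)
  } else {
    phi <- design$ar1_phi
    noise <- matrix(stats::rnorm(tfr * n), tfr, n)
    if (phi != 0) {
      noise <- apply(noise, 2L, function(e)
        as.numeric(stats::filter(e, phi, method = "recursive")))
      noise <- noise * sqrt(1 - phi^2)  # unit marginal variance
    }
    x <- t(noise %*% ch)
    s <- bandlimited_signal(tfr, design$tr, design$lag_band_hz)
    s <- s / stats::sd(s) * design$lag_snr
    for (id in names(design$planted_lags)) {
      nodes <- which(subnet == as.integer(id))
      if (!length(nodes)) next
      shifted <- shift_signal(s, design$planted_lags[[id]] / design$tr)
      x[nodes, ] <- x[nodes, ] + rep(shifted, each = length(nodes))
    }
  }
  timeseries(x, tr = design$tr, subject_id = sprintf("sub-%02d", subject),
             space = design$space)
}

# white noise restricted to a frequency band (circular, hence exactly
# band-limited: fractional shifts by phase rotation are exact)
bandlimited_signal <- function(n, tr, band_hz) {
  z <- stats::fft(stats::rnorm(n))
  f <- freq_axis(n, tr)
  keep <- abs(f) >= band_hz[1L] & abs(f) <= band_hz[2L]
  if (!any(keep)) stop("band contains no resolvable frequency", call. = FALSE)
  z[!keep] <- 0
  Re(stats::fft(z, inverse = TRUE)) / n
}

freq_axis <- function(n, tr) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * tr)
}

# delay a periodic signal by d frames (possibly fractional) via
# frequency-domain phase rotation: output(t) = input(t - d)
shift_signal <- function(s, d_frames) {
  n <- length(s)
  f <- freq_axis(n, 1)
  Re(stats::fft(stats::fft(s) * exp(-2i * pi * f * d_frames),
                inverse = TRUE)) / n
}

#' Simulate a coordinate meta-analytic database with planted associations
#'
#' Emulates the standard layout of coordinate-based meta-analytic databases:
#' an activations table (study id, x/y/z peak coordinates in mm) and a
#' study-by-term weight table with weights in [0, 1]. Each "associated"
#' study places peaks exactly at a random subset (at least
#' `region_match_fraction` of them) of one subnetwork's region centroids,
#' plus background peaks far from all regions; unassociated studies place
#' only background peaks. Terms planted in the design get their weights
#' shifted upward in studies associated with the planted subnetwork; null
#' term weights are independent of the association group.
#'
#' @param design a `planted_design`.
#' @param subnetwork_regions named list: subnetwork name -> R x 3 matrix of
#'   region centroid coordinates (mm). See [regions_from_truth()].
#' @param region_match_fraction minimum fraction of centroids an associated
#'   study covers.
#' @param match_share fraction of studies associated with each subnetwork.
#' @return a `meta_database`; the planted study group is in attribute
#'   `"group"` (0 = unassociated) and planted terms in `"planted_terms"`.
#' @export
simulate_meta_database <- function(design, subnetwork_regions,
                                   region_match_fraction = 0.40,
                                   match_share = 0.25) {
  stopifnot(is.list(subnetwork_regions), length(subnetwork_regions) >= 1L)
  k <- length(subnetwork_regions)
  if (match_share * k > 1) stop("match_share too large", call. = FALSE)
  set.seed(derive_seed(design$rng_seed, 3000L))
  ns <- design$n_studies
  group <- sample(rep(c(seq_len(k), 0L),
                      c(rep(floor(match_share * ns), k),
                        ns - k * floor(match_share * ns))))
  span <- apply(design$space$coord, 2L, range)
  far_corner <- span[2L, ] + 200  # background peaks live far off the sheet
  acts <- vector("list", ns)
  for (st in seq_len(ns)) {
    peaks <- matrix(stats::runif(3L * 3L), ncol = 3L) %*% diag(c(50, 50, 50))
    peaks <- sweep(peaks, 2L, far_corner, "+")
    if (group[st] > 0L) {
      cent <- subnetwork_regions[[group[st]]]
      r <- nrow(cent)
      m <- sample(seq.int(ceiling(region_match_fraction * r), r), 1L)
      hit <- cent[sample(r, m), , drop = FALSE]
      peaks <- rbind(hit, peaks)
    }
    acts[[st]] <- data.frame(study_id = sprintf("study_%04d", st),
                             x = peaks[, 1L], y = peaks[, 2L], z = peaks[, 3L])
  }
  activations <- do.call(rbind, acts)
  terms <- sprintf("term_%03d", seq_len(design$n_terms))
  w <- matrix(stats::runif(ns * design$n_terms, 0, design$weight_base_max),
              ns, design$n_terms, dimnames = list(sprintf("study_%04d",
                                                         seq_len(ns)), terms))
  pt <- design$planted_terms
  if (!is.null(pt)) {
    for (row in seq_len(nrow(pt))) {
      idx <- match(pt$term[row], terms)
      if (is.na(idx)) stop("planted term not among generated terms",
                           call. = FALSE)
      tgt <- which(group == pt$subnetwork[row])
      w[tgt, idx] <- pmin(w[tgt, idx] + pt$shift[row], 1)
    }
  }
  db <- meta_database(activations, w)
  attr(db, "group") <- group
  attr(db, "planted_terms") <- pt
  db
}

#' Region centroids of planted subnetworks
#'
#' Splits each requested subnetwork's tile into `n_regions` contiguous
#' strips and returns the strip centroids, giving each subnetwork a
#' distributed multi-region footprint for meta-analytic matching.
#'
#' @param design a `planted_design`.
#' @param subnet_ids subnetwork ids to use.
#' @param n_regions regions per subnetwork.
#' @return named list of `n_regions` x 3 centroid matrices.
#' @export
regions_from_truth <- function(design, subnet_ids = 1:3, n_regions = 5L) {
  out <- list()
  for (id in subnet_ids) {
    nodes <- label_nodes(design$truth_subnet, id)
    co <- design$space$coord[nodes, , drop = FALSE]
    ord <- nodes[order(co[, 2L], co[, 1L])]
    parts <- split(ord, cut(seq_along(ord), n_regions, labels = FALSE))
    # centroid snapped to the nearest member node, so a peak placed exactly
    # there sits at distance 0 from the region
    cent <- t(vapply(parts, function(p) {
      co_p <- design$space$coord[p, , drop = FALSE]
      mid <- colMeans(co_p)
      co_p[which.min(rowSums(sweep(co_p, 2L, mid)^2)), ]
    }, numeric(3L)))
    out[[as.character(id)]] <- cent
  }
  out
}

#' Simulate per-condition task activation z-maps
#'
#' One z-map per subject and condition: the planted per-subnetwork effect
#' plus unit Gaussian noise, on the subject's own (jittered) topography.
#'
#' @param design a `planted_design`.
#' @param effects named list: condition -> numeric vector of effects indexed
#'   by subnetwork id.
#' @return list: condition -> subjects x nodes matrix of z values.
#' @export
simulate_task_maps <- function(design, effects) {
  n <- n_nodes(design$space)
  out <- list()
  for (cond in names(effects)) {
    eff <- effects[[cond]]
    m <- matrix(NA_real_, design$n_subjects, n)
    for (s in seq_len(design$n_subjects)) {
      truth <- subject_truth(design, s)
      set.seed(derive_seed(design$rng_seed,
                           4000L + s * 100L + match(cond, names(effects))))
      m[s, ] <- eff[truth$subnet$label] + stats::rnorm(n)
    }
    out[[cond]] <- m
  }
  out
}
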