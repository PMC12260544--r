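# Shared fixture builders; everything is generated in code at test time.

ari <- function(a, b) igraph::compare(a, b, method = "adjusted.rand")

# small symmetric matrix with NA diagonal
random_sym_matrix <- function(n, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n * n), n)
  v <- (v + t(v)) / 2
  diag(v) <- NA_real_
  v
}

# brute-force row/column top-k union oracle, independent of the implementation
brute_rowcol_threshold <- function(v, density) {
  n <- nrow(v)
  k <- ceiling(density * (n - 1))
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    row <- v[i, ]
    ok <- which(!is.na(row))
    ord <- ok[order(-row[ok], ok)]
    keep[i, ord[seq_len(min(k, length(ord)))]] <- TRUE
  }
  out <- matrix(0L, n, n)
  out[keep | t(keep)] <- 1L
  out
}

# brute-force one-way ANOVA from sums of squares
brute_oneway_F <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1.0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0))
  df1 <- length(groups) - 1L
  df2 <- length(all) - length(groups)
  list(F = (ssb / df1) / (ssw / df2), df = c(df1, df2),
       p = pf((ssb / df1) / (ssw / df2), df1, df2, lower.tail = FALSE))
}

# brute-force blocked (repeated-measures) ANOVA on a complete subjects x
# levels table
brute_rm_F <- function(m) {
  gm <- mean(m)
  ss_sub <- ncol(m) * sum((rowMeans(m) - gm)^2)
  ss_lvl <- nrow(m) * sum((colMeans(m) - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_res <- ss_tot - ss_sub - ss_lvl
  df_lvl <- ncol(m) - 1L
  df_res <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(F = (ss_lvl / df_lvl) / (ss_res / df_res), df = c(df_lvl, df_res))
}

# brute-force Benjamini-Hochberg rejection set (step-up on i * alpha / m)
brute_bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  below <- which(p[ord] <= seq_len(m) * alpha / m)
  rej <- logical(m)
  if (length(below)) rej[ord[seq_len(max(below))]] <- TRUE
  rej
}

# build the matching fixture: n_subjects with the 4 parent subnetworks,
# plus one rare subnetwork present in the first `rare_in` subjects
matching_fixture <- function(design, rare_in = 3L) {
  sets <- list()
  for (s in seq_len(design$n_subjects)) {
    tr <- subject_truth(design, s)
    members <- lapply(1:4, function(k) label_nodes(tr$subnet, k))
    truth_ids <- 1:4
    if (s <= rare_in) {
      members <- c(members, list(label_nodes(tr$subnet, 5L)))
      truth_ids <- c(truth_ids, 5L)
    }
    sets[[s]] <- subnetwork_set(sprintf("sub-%02d", s), members)
    attr(sets[[s]], "truth_ids") <- truth_ids
  }
  sets
}

# tiny meta-database with explicit weights per group, all peaks matching the
# named region sets by construction
grouped_weight_db <- function(weights_by_group, region_centroids) {
  stopifnot(length(weights_by_group) == length(region_centroids))
  acts <- list(); ids <- character(0); n <- 0L
  for (g in seq_along(weights_by_group)) {
    for (w in seq_along(weights_by_group[[g]])) {
      n <- n + 1L
      id <- sprintf("study_%03d", n)
      ids <- c(ids, id)
      cent <- region_centroids[[g]]
      acts[[n]] <- data.frame(study_id = id, x = cent[, 1], y = cent[, 2],
                              z = cent[, 3])
    }
  }
  w <- unlist(weights_by_group)
  features <- matrix(w, ncol = 1, dimnames = list(ids, "term_x"))
  meta_database(do.call(rbind, acts), features)
}
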