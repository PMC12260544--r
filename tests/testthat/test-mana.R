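test_that("region extraction splits disconnected blobs and applies the area rule", {
  sp <- grid_node_space(10, 10, spacing_mm = 3)  # node area 9 mm^2
  one_blob <- c(1:3, 11:13)
  rs <- extract_regions(one_blob, sp, min_area = 20)
  expect_equal(length(rs), 1L)
  expect_equal(sort(rs[[1]]$nodes), sort(one_blob))
  expect_equal(rs[[1]]$area, 6 * 9)

  two_blobs <- c(1:3, 51:53)  # separated by unlabeled rows
  rs2 <- extract_regions(two_blobs, sp, min_area = 20)
  expect_equal(length(rs2), 2L)

  # a 2-node blob has area 18 < 20 mm^2 and is dropped
  rs3 <- extract_regions(c(1:3, 99:100), sp, min_area = 20)
  expect_equal(length(rs3), 1L)
  expect_error(extract_regions(integer(0), sp), "empty")
})

test_that("study matching requires peaks near at least 40% of regions", {
  sp <- grid_node_space(30, 5, spacing_mm = 10)
  # five regions: single nodes spread along x
  region_nodes <- c(1L, 7L, 13L, 19L, 25L)
  rs <- structure(lapply(region_nodes, function(n)
    list(nodes = n, centroid = sp$coord[n, ], area = 100)),
    class = "region_set")
  peak_at <- function(nodes, id) data.frame(study_id = id,
                                            x = sp$coord[nodes, 1],
                                            y = sp$coord[nodes, 2],
                                            z = sp$coord[nodes, 3])
  acts <- rbind(peak_at(c(1L, 7L), "two_hits"),
                peak_at(13L, "one_hit"),
                peak_at(region_nodes, "all_hits"))
  feats <- matrix(0.5, 3, 1, dimnames = list(c("two_hits", "one_hit",
                                               "all_hits"), "t"))
  db <- meta_database(acts, feats)
  m <- match_studies(db, rs, sp, radius_mm = 2, fraction = 0.40)
  expect_true("two_hits" %in% m)   # 2 of 5 regions = 40%
  expect_true("all_hits" %in% m)
  expect_false("one_hit" %in% m)   # 20% < 40%
  # peak exactly at a node: distance 0 < 2 mm counts
  expect_true("one_hit" %in% match_studies(db, rs, sp, fraction = 0.20))
})

test_that("study matching is monotone in radius and fraction", {
  d <- planted_design(n_subjects = 1, n_studies = 60, n_terms = 5,
                      rng_seed = 31)
  regions <- regions_from_truth(d, 1:2)
  db <- simulate_meta_database(d, regions)
  rs <- extract_regions(label_nodes(d$truth_subnet, 1L), d$space,
                        min_area = 20)
  base <- match_studies(db, rs, d$space, radius_mm = 2, fraction = 0.40)
  wider <- match_studies(db, rs, d$space, radius_mm = 8, fraction = 0.40)
  looser <- match_studies(db, rs, d$space, radius_mm = 2, fraction = 0.20)
  expect_true(all(base %in% wider))
  expect_true(all(base %in% looser))
})

test_that("term ANOVA reproduces the brute-force oracle and handles degeneracy", {
  groups <- list(g1 = c(1, 2, 3) / 10, g2 = c(2, 3, 4) / 10,
                 g3 = c(4, 5, 6) / 10)
  cents <- list(matrix(c(0, 0, 0), 1), matrix(c(100, 0, 0), 1),
                matrix(c(200, 0, 0), 1))
  db <- grouped_weight_db(groups, cents)
  matches <- split(rownames(db$features), rep(c("g1", "g2", "g3"), each = 3))
  res <- term_anova(db, matches, "term_x")
  oracle <- brute_oneway_F(groups)
  expect_equal(res$F, oracle$F, tolerance = 1e-10)
  expect_equal(res$F, 7.0, tolerance = 1e-10)   # SSB = 14, SSW = 6 (scaled)
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_equal(res$assigned, "g3")
  expect_equal(res$magnitude, max(vapply(groups, mean, 1.0)) -
                 mean(unlist(groups)), tolerance = 1e-12)

  # constant weights: skipped, not an error
  dbc <- grouped_weight_db(list(rep(0.5, 3), rep(0.5, 3)), cents[1:2])
  expect_message(resc <- term_anova(dbc, split(rownames(dbc$features),
                                               rep(1:2, each = 3)), "term_x"),
                 "zero variance")
  expect_null(resc)
})

test_that("permuting group labels leaves the F distribution unchanged under the null", {
  set.seed(44)
  w <- runif(30, 0, 1)
  cents <- list(matrix(c(0, 0, 0), 1), matrix(c(100, 0, 0), 1),
                matrix(c(200, 0, 0), 1))
  db <- grouped_weight_db(split(w, rep(1:3, each = 10)), cents)
  ids <- rownames(db$features)
  f_obs <- term_anova(db, split(ids, rep(1:3, each = 10)), "term_x")$F
  f_perm <- replicate(200, {
    term_anova(db, split(ids, sample(rep(1:3, each = 10))), "term_x")$F
  })
  # observed F is an unremarkable draw from the permutation distribution
  expect_gt(mean(f_perm >= f_obs), 0.05)
})

test_that("Benjamini-Hochberg matches the brute-force step-up rule", {
  p <- c(0.001, 0.02, 0.03, 0.2)
  res <- fdr_correct(p, alpha = 0.05)
  expect_equal(res$reject, brute_bh_reject(p, 0.05))
  expect_equal(sum(res$reject), 3L)
  expect_true(all(res$q >= p))
  expect_equal(fdr_correct(rep(1, 5))$reject, rep(FALSE, 5))
  expect_equal(fdr_correct(0.03)$q, 0.03)  # m = 1: q = p
  set.seed(10)
  pr <- runif(100)^2
  expect_equal(fdr_correct(pr, 0.05)$reject, brute_bh_reject(pr, 0.05))
})

test_that("peak density map equals an exhaustive pairwise-distance census", {
  sp <- grid_node_space(6, 6, spacing_mm = 5)
  set.seed(3)
  peaks <- data.frame(study_id = sprintf("s%d", 1:20),
                      x = runif(20, -5, 30), y = runif(20, -5, 30),
                      z = runif(20, -2, 2))
  db <- meta_database(peaks, matrix(0.5, 20, 1,
                                    dimnames = list(peaks$study_id, "t")))
  got <- peak_density_map(db, sp, radius_mm = 4)
  brute <- vapply(seq_len(36), function(i)
    sum(sqrt((peaks$x - sp$coord[i, 1])^2 + (peaks$y - sp$coord[i, 2])^2 +
               (peaks$z - sp$coord[i, 3])^2) <= 4), 0L)
  expect_equal(got, brute)
  empty <- meta_database(peaks[0, ],
                         matrix(numeric(0), 0, 0,
                                dimnames = list(character(0), character(0))))
  expect_equal(peak_density_map(empty, sp), integer(36))
})

test_that("term curation applies lexicons and collapses duplicates", {
  terms <- c("pain", "pain", "motor", "male", "occipital")
  expect_equal(term_filter(terms), c("pain", "motor", "male", "occipital"))
  expect_equal(term_filter(terms, exclude = c("male", "occipital")),
               c("pain", "motor"))
  expect_equal(term_filter(terms, include = c("pain", "motor"),
                           exclude = "motor"), "pain")
})

test_that("planted associations are detected and assigned to the true subnetwork", {
  d <- planted_design(n_subjects = 1, n_studies = 300, n_terms = 50,
                      planted_terms = data.frame(
                        term = c("term_010", "term_020"),
                        subnetwork = c(1, 3), shift = 0.2),
                      rng_seed = 77)
  regions <- regions_from_truth(d, 1:3)
  db <- simulate_meta_database(d, regions)
  region_sets <- lapply(1:3, function(id)
    extract_regions(label_nodes(d$truth_subnet, id), d$space, min_area = 20))
  names(region_sets) <- c("1", "2", "3")
  tab <- mana_annotate(db, region_sets, d$space)
  sig <- tab[tab$significant, ]
  expect_true(all(c("term_010", "term_020") %in% sig$term))
  expect_equal(sig$assigned[sig$term == "term_010"], "1")
  expect_equal(sig$assigned[sig$term == "term_020"], "3")
})
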