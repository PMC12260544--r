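test_that("subnetwork-network connectivity excludes overlap and flags degenerate targets", {
  set.seed(21)
  x <- matrix(rnorm(20 * 300), 20, 300)
  ts <- timeseries(x, tr = 1)
  # identical target: fully excluded -> undefined
  expect_warning(z <- subnetwork_network_fc(ts, 1:5, 1:5), "overlaps")
  expect_true(is.na(z))
  # independent signals: z near zero
  z0 <- subnetwork_network_fc(ts, 1:5, 6:10)
  expect_lt(abs(z0), atanh(0.25))
  # overlap excluded before averaging
  z1 <- subnetwork_network_fc(ts, 1:5, c(1:3, 6:10))
  expect_equal(z1, z0, tolerance = 1e-12)
  # duplicated mean signals hit the clip bound
  ts2 <- timeseries(rbind(x[1, ], x[1, ]), tr = 1)
  expect_equal(subnetwork_network_fc(ts2, 1, 2), atanh(0.999999))
})

test_that("distance-excluded profiles agree with plain profiles when no pair is short", {
  set.seed(22)
  sp <- grid_node_space(10, 2, spacing_mm = 30)  # all pairs >= 30 mm
  x <- matrix(rnorm(20 * 400), 20, 400)
  # correlated structure so both modes measure the same signal
  x[11:20, ] <- x[11:20, ] + rep(colMeans(x[1:10, ]), each = 10)
  ts <- timeseries(x, tr = 1)
  plain_pairmean <- mean(atanh(pmin(pmax(
    cor(t(x[1:5, ]), t(x[11:15, ])), -0.999999), 0.999999)))
  masked <- subnetwork_network_fc(ts, 1:5, 11:15, space = sp,
                                  short_distance_mm = 20)
  expect_equal(masked, plain_pairmean, tolerance = 1e-12)
  # everything excluded -> undefined with warning
  sp_close <- grid_node_space(10, 2, spacing_mm = 1)
  expect_warning(z <- subnetwork_network_fc(ts, 1:5, 11:15, space = sp_close,
                                            short_distance_mm = 20),
                 "excluded")
  expect_true(is.na(z))
})

test_that("task condition means average over subnetwork nodes", {
  zmap <- c(rep(2, 5), rep(-1, 5))
  got <- task_condition_means(zmap, list(a = 1:5, b = 6:10, c = integer(0)))
  expect_equal(got, c(a = 2, b = -1, c = NA_real_))
})

test_that("repeated-measures ANOVA matches the brute-force blocked oracle", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(rnorm(5 * 4), 5, 4) + outer(rnorm(5), rep(1, 4))
    res <- rm_anova(m)
    oracle <- brute_rm_F(m)
    expect_equal(res$F, oracle$F, tolerance = 1e-10)
    expect_equal(res$df, oracle$df)
  }
})

test_that("repeated-measures ANOVA handles degenerate and identical-level cases", {
  # identical values across levels: F = 0
  m0 <- matrix(rep(c(1, 5, 2), 3), 3, 3)
  res0 <- rm_anova(m0)
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  # constant within-subject differences: zero residual -> Inf, flagged
  m1 <- cbind(c(1, 2, 3), c(2, 3, 4))
  res1 <- rm_anova(m1)
  expect_true(is.infinite(res1$F))
  expect_true(res1$degenerate)
  # unbalanced: missing cells omitted, still finite
  m2 <- matrix(rnorm(12), 4, 3)
  m2[1, 2] <- NA
  expect_true(is.finite(rm_anova(m2)$F))
  # level observed in < 2 subjects is dropped with a warning
  m3 <- matrix(rnorm(12), 4, 3)
  m3[2:4, 3] <- NA
  expect_warning(res3 <- rm_anova(m3), "dropping")
  expect_equal(res3$df[1], 1)
})

test_that("label shuffling within subjects preserves the null F distribution", {
  set.seed(32)
  m <- matrix(rnorm(8 * 3), 8, 3) + outer(rnorm(8), rep(1, 3))
  f_obs <- rm_anova(m)$F
  f_perm <- replicate(100, {
    ms <- t(apply(m, 1, sample))
    rm_anova(ms)$F
  })
  expect_gt(mean(f_perm >= f_obs), 0.02)
})

test_that("Bonferroni correction never decreases p and caps at 1", {
  res <- rm_anova(matrix(rnorm(12), 4, 3), n_tests = 6)
  expect_gte(res$p_bonferroni, res$p)
  expect_lte(res$p_bonferroni, 1)
  res2 <- rm_anova(matrix(rnorm(12), 4, 3), n_tests = 1000)
  expect_equal(res2$p_bonferroni, 1)
})

test_that("paired t test matches its closed form and is antisymmetric", {
  a <- c(2, 4, 6); b <- c(1, 2, 3)  # differences 1, 2, 3
  res <- paired_t(a, b)
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)  # 3.4641
  expect_equal(res$t, 3.464, tolerance = 1e-3)
  expect_equal(res$df, 2)
  expect_equal(paired_t(a, a)$t, 0)
  expect_equal(paired_t(b, a)$t, -res$t, tolerance = 1e-12)
  # missing pairs dropped
  res2 <- paired_t(c(a, NA), c(b, 1))
  expect_equal(res2$n, 3)
})

test_that("spring graph keeps density when connected and escalates 10 -> 15 on an isolate", {
  set.seed(41)
  base <- matrix(rnorm(9 * 300), 9, 300)
  shared <- colMeans(base[1:6, ])
  x <- base
  x[1:6, ] <- x[1:6, ] + rep(shared, each = 6)     # well-connected core
  iso <- colMeans(base[7:9, ])
  x[7:9, ] <- 0.2 * x[7:9, ] + rep(iso, each = 3)  # own cluster, weak link
  ts <- timeseries(x, tr = 1)
  clusters <- data.frame(cluster = sprintf("c%d", 1:9),
                         group = rep(c("netA", "netB", "netC"), each = 3))
  nodes <- as.list(1:9)
  sg_all <- spring_graph_export(ts, clusters, nodes, density = 1, step = 0.05)
  expect_equal(sg_all$density, 1)
  expect_false(sg_all$disconnected)

  # fully connected already at 10%: density stays. Phase-shifted tones give
  # adjacent clusters the highest correlations, so the top 10% of the 210
  # pairwise edges contains the spanning chain of 20 adjacent pairs.
  t_ax <- seq_len(300)
  chain <- t(sapply(seq_len(21), function(i)
    cos(2 * pi * 0.03 * t_ax + 0.2 * i)))
  dense_ts <- timeseries(chain, tr = 1)
  clusters21 <- data.frame(cluster = sprintf("c%d", 1:21),
                           group = rep(c("nA", "nB", "nC"), each = 7))
  sg10 <- spring_graph_export(dense_ts, clusters21, as.list(1:21),
                              density = 0.10, step = 0.05)
  expect_equal(sg10$density, 0.10)
  expect_equal(sg10$escalations, 0L)

  # constructed isolate: netC disconnected at 10%, joined after escalation
  sg <- spring_graph_export(ts, clusters, nodes, density = 0.10, step = 0.05)
  expect_gte(sg$escalations, 1L)
  expect_equal(sg$density, 0.10 + 0.05 * sg$escalations)
  expect_false(sg$disconnected)
})

test_that("spring graph files are written in edge-list and GEXF form", {
  set.seed(42)
  ts <- timeseries(matrix(rnorm(6 * 100), 6, 100), tr = 1)
  clusters <- data.frame(cluster = sprintf("c%d", 1:6),
                         group = rep(c("a", "b"), each = 3))
  sg <- spring_graph_export(ts, clusters, as.list(1:6), density = 0.5)
  tmp <- withr::local_tempdir()
  write_spring_graph(sg, file.path(tmp, "g"))
  edges <- read.delim(file.path(tmp, "g_edges.tsv"))
  expect_equal(nrow(edges), nrow(sg$edges))
  gexf <- readLines(file.path(tmp, "g.gexf"))
  expect_true(any(grepl("<gexf", gexf)))
  expect_equal(sum(grepl("<edge ", gexf)), nrow(sg$edges))
})
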