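test_that("node space validates geometry and symmetrizes adjacency", {
  sp <- node_space(cbind(0:2, 0, 0), adjacency = rbind(c(2, 1), c(2, 3)),
                   area = rep(1, 3))
  expect_equal(sp$adjacency, cbind(c(1L, 2L), c(2L, 3L)))
  expect_error(node_space(cbind(c(0, Inf), 0, 0), area = c(1, 1)), "finite")
  expect_error(node_space(cbind(0:1, 0, 0), adjacency = rbind(c(1, 1)),
                          area = c(1, 1)), "irreflexive")
  expect_error(node_space(cbind(0:1, 0, 0), area = c(0, 1)), "> 0")
  expect_warning(node_space(cbind(0:1, 0, 0)), "1 mm\\^2")
})

test_that("timeseries enforces run structure and node-axis agreement", {
  sp <- grid_node_space(2, 2)
  expect_error(timeseries(matrix(1:6, 3), tr = 1, space = sp), "mismatch")
  expect_error(timeseries(matrix(c(1, NA, 3, 4), 2), tr = 1), "missing frames")
  expect_error(timeseries(matrix(1:4, 2), tr = 0), "positive")
  ts <- timeseries(matrix(rnorm(20), 4, 5), tr = 2, run_boundaries = c(1, 4),
                   space = grid_node_space(2, 2))
  expect_equal(run_frames(ts), list(1:3, 4:5))
})

test_that("Fisher-z connectivity matches direct evaluation and handles edge cases", {
  set.seed(42)
  x <- matrix(rnorm(4 * 200), 4, 200)
  ts <- timeseries(x, tr = 1)
  cm <- compute_connectivity(ts)
  expect_equal(cm$values[1, 2], atanh(cor(x[1, ], x[2, ])), tolerance = 1e-12)
  expect_equal(cm$values, t(cm$values))
  expect_true(all(is.na(diag(cm$values))))

  # duplicated rows: r = 1 clipped to the configured bound before atanh
  x2 <- rbind(x[1, ], x[1, ], x[3:4, ])
  z <- compute_connectivity(timeseries(x2, tr = 1))$values
  expect_equal(z[1, 2], atanh(0.999999))

  # constant row reported as undefined, not zeroed
  x3 <- rbind(rep(1, 200), x[2:4, ])
  expect_warning(cm3 <- compute_connectivity(timeseries(x3, tr = 1)),
                 "constant")
  expect_equal(cm3$undefined_nodes, 1L)
  expect_true(all(is.na(cm3$values[1, ])))
})

test_that("z of independent noise is near zero; r = 0.5 transforms exactly", {
  # sampling-distribution oracle: z ~ N(0, 1/sqrt(n-3)) for independent rows
  set.seed(7)
  n <- 10000
  ts <- timeseries(rbind(rnorm(n), rnorm(n)), tr = 1)
  expect_lt(abs(compute_connectivity(ts)$values[1, 2]), 0.05)
  expect_equal(atanh(0.5), 0.549306144334055, tolerance = 1e-12)
})

test_that("connectivity is equivariant under node permutation", {
  set.seed(8)
  x <- matrix(rnorm(6 * 100), 6, 100)
  z <- compute_connectivity(timeseries(x, tr = 1))$values
  perm <- sample(6)
  zp <- compute_connectivity(timeseries(x[perm, ], tr = 1))$values
  expect_equal(zp, z[perm, perm], tolerance = 1e-12)
})

test_that("row/column density thresholding matches a brute-force oracle", {
  for (seed in 1:5) {
    n <- sample(10:50, 1)
    v <- random_sym_matrix(n, seed = seed)
    for (density in c(0.05, 0.2, 0.34)) {
      got <- density_threshold_rowcol(connectivity_matrix(v), density)
      expect_equal(got, brute_rowcol_threshold(v, density),
                   ignore_attr = TRUE)
      k <- ceiling(density * (n - 1))
      expect_true(all(rowSums(got) >= k))  # per-row guarantee of the union rule
    }
  }
})

test_that("density thresholding keeps everything at density 1 and breaks ties by index", {
  v <- random_sym_matrix(6, seed = 3)
  all_kept <- density_threshold_rowcol(connectivity_matrix(v), 1)
  expect_equal(sum(all_kept), 6 * 5)

  tied <- matrix(1, 4, 4); diag(tied) <- NA
  got <- density_threshold_rowcol(connectivity_matrix(tied), 0.34)
  # each row keeps its lowest-index partners deterministically
  expect_equal(got, density_threshold_rowcol(connectivity_matrix(tied), 0.34))
  expect_true(got[1, 2] == 1L)
  expect_true(got[3, 4] == 0L)  # neither 3 nor 4 ranks the other in its top-2
  expect_equal(got, t(got))
})

test_that("short-distance exclusion removes exactly the close pairs and is idempotent", {
  set.seed(9)
  sp <- node_space(matrix(runif(30 * 3, 0, 60), ncol = 3), area = rep(1, 30))
  v <- random_sym_matrix(30, seed = 9)
  cm <- connectivity_matrix(v)
  ex <- exclude_short_distance_edges(cm, sp, 20)
  d <- as.matrix(dist(sp$coord))
  for (i in 1:29) for (j in (i + 1):30) {
    if (d[i, j] < 20) expect_true(is.na(ex$values[i, j]))
    else expect_equal(ex$values[i, j], v[i, j])
  }
  ex2 <- exclude_short_distance_edges(ex, sp, 20)
  expect_identical(ex2$values, ex$values)
  # d = 0 leaves the matrix unchanged
  expect_equal(exclude_short_distance_edges(cm, sp, 0)$values, cm$values)
})

test_that("containers round-trip through their TSV formats", {
  tmp <- withr::local_tempdir()
  sp <- grid_node_space(4, 3, spacing_mm = 2.5)
  write_node_space(sp, file.path(tmp, "space"))
  sp2 <- read_node_space(file.path(tmp, "space"))
  expect_equal(sp2$coord, sp$coord)
  expect_equal(sp2$adjacency, sp$adjacency)
  expect_equal(sp2$area, sp$area)

  ts <- timeseries(matrix(rnorm(12 * 7), 12, 7), tr = 1.5,
                   subject_id = "sub-09", run_boundaries = c(1, 5))
  write_timeseries_tsv(ts, file.path(tmp, "ts.tsv"))
  ts2 <- read_timeseries_tsv(file.path(tmp, "ts.tsv"), space = sp)
  expect_equal(ts2$values, ts$values, tolerance = 1e-6)
  expect_equal(ts2$tr, 1.5)
  expect_equal(ts2$run_boundaries, c(1L, 5L))

  lm0 <- label_map(c(0L, 2L, 2L, 5L))
  write_label_map(lm0, file.path(tmp, "labels.tsv"))
  expect_identical(read_label_map(file.path(tmp, "labels.tsv"))$label,
                   lm0$label)
})

test_that("malformed inputs fail with messages naming file and axis", {
  tmp <- withr::local_tempdir()
  writeLines(c("node\tx\ty\tz", "1\t0\toops\t0"), file.path(tmp, "bad_nodes.tsv"))
  expect_error(read_node_space(file.path(tmp, "bad")), "row 1")
  writeLines(c("node\tx"), file.path(tmp, "cols_nodes.tsv"))
  expect_error(read_node_space(file.path(tmp, "cols")), "missing column")
  sp <- grid_node_space(2, 2)
  ts <- timeseries(matrix(rnorm(12), 3, 4), tr = 1)
  write_timeseries_tsv(ts, file.path(tmp, "ts3.tsv"))
  expect_error(read_timeseries_tsv(file.path(tmp, "ts3.tsv"), space = sp),
               "node axis mismatch|mismatch")
})

test_that("analysis config validates fractions and round-trips as JSON", {
  cfg <- analysis_config()
  expect_equal(cfg$subnetwork_density, 0.001)
  expect_equal(cfg$peak_match_radius_mm, 2.0)
  expect_error(analysis_config(fdr_alpha = 0), "fraction")
  expect_error(analysis_config(max_lag_s = -1), "> 0")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, tmp)
  expect_equal(read_config(tmp)$short_distance_mm, 20)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(not_a_key = 1), bad, auto_unbox = TRUE)
  expect_error(read_config(bad), "not_a_key")
})
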