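test_that("per-pixel deduplication keeps the first record per cell", {
  st <- env_stack(matrix(0, 100, 1), nrow = 10, ncol = 10)
  occ <- occurrence_set(x = c(1.2, 1.4, 1.8, 5.5), y = c(1.2, 1.6, 1.3, 5.5))
  out <- dedupe_per_cell(occ, st)
  expect_equal(nrow(out), 2)
  expect_equal(out$id, c(1L, 4L)) # first-by-input-order kept
  # all-distinct input is unchanged
  occ2 <- occurrence_set(x = c(0.5, 3.5, 7.5), y = c(0.5, 3.5, 7.5))
  expect_equal(nrow(dedupe_per_cell(occ2, st)), 3)
  # empty input passes through
  expect_equal(nrow(dedupe_per_cell(occ2[0, ], st)), 0)
})

test_that("deduplication equals brute-force grouping by cell", {
  st <- env_stack(matrix(0, 400, 1), nrow = 20, ncol = 20)
  set.seed(13)
  occ <- occurrence_set(x = runif(200, 0, 20), y = runif(200, 0, 20))
  out <- dedupe_per_cell(occ, st)
  cells <- cell_from_xy(st, occ$x, occ$y)
  brute <- occ[!duplicated(cells), ]
  expect_equal(out$id, brute$id)
})

test_that("thinning solves the collinear 0/3/6 km case optimally", {
  # three points on a meridian, 3 km apart (1 km ~ 1/111.2 degree)
  step <- 3 / 111.1949
  occ <- occurrence_set(x = c(0, 0, 0), y = c(0, step, 2 * step),
                        crs = "geographic")
  out <- thin_min_distance(occ, dmin = 5, seed = 1)
  expect_equal(sort(out$id), c(1L, 3L)) # brute-force optimum keeps the ends
})

test_that("thinning respects dmin, is a subset, and is idempotent", {
  set.seed(17)
  occ <- occurrence_set(x = runif(80, 0, 50), y = runif(80, 0, 50))
  out <- thin_min_distance(occ, dmin = 5, seed = 2)
  expect_true(all(out$id %in% occ$id))
  d <- as.matrix(dist(cbind(out$x, out$y)))
  diag(d) <- Inf
  expect_gte(min(d), 5)
  # idempotent
  again <- thin_min_distance(out, dmin = 5, seed = 3)
  expect_equal(again$id, out$id)
  # already-thin input returned unchanged
  spread <- occurrence_set(x = c(0, 10, 20), y = c(0, 0, 0))
  expect_equal(thin_min_distance(spread, 5)$id, spread$id)
  # coincident pair: exactly one survives
  dup <- occurrence_set(x = c(1, 1), y = c(2, 2))
  expect_equal(nrow(thin_min_distance(dup, 1)), 1)
})

test_that("polygon sampling honours containment, spacing and seed", {
  square <- data.frame(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))
  pts <- sample_polygon_points(square, n = 10, dmin = 5, seed = 4)
  expect_equal(nrow(pts), 10)
  expect_true(all(pts$x >= 0 & pts$x <= 100 & pts$y >= 0 & pts$y <= 100))
  d <- as.matrix(dist(cbind(pts$x, pts$y)))
  diag(d) <- Inf
  expect_gte(min(d), 5)
  expect_identical(sample_polygon_points(square, 10, 5, seed = 4)$x, pts$x)
  # spacing beyond the polygon diameter: one point plus a warning
  expect_warning(
    one <- sample_polygon_points(square, n = 2, dmin = 200, seed = 5,
                                 max_tries = 50),
    "retry budget")
  expect_equal(nrow(one), 1)
  line <- data.frame(x = c(0, 1, 2), y = c(0, 0, 0))
  expect_error(sample_polygon_points(line, 5), "degenerate")
})

test_that("Welch comparison matches the textbook computation", {
  # six cells in a row, one record in each, layer values 1..6
  st <- env_stack(cbind(bio = 1:6), nrow = 1, ncol = 6)
  xy <- xy_from_cell(st, 1:6)
  occ_a <- occurrence_set(xy$x[1:3], xy$y[1:3])
  occ_b <- occurrence_set(xy$x[4:6], xy$y[4:6])
  res <- welch_compare(occ_a, occ_b, st)
  # hand evaluation: means 2 and 5, both variances 1, n = 3
  se <- sqrt(1 / 3 + 1 / 3)
  t_hand <- (2 - 5) / se
  df_hand <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  expect_equal(res$t, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p, 2 * pt(t_hand, df_hand))
  # swapping groups flips t, keeps p
  rev <- welch_compare(occ_b, occ_a, st)
  expect_equal(rev$t, -res$t)
  expect_equal(rev$p, res$p)
})

test_that("Welch comparison flags degenerate layers and supports Bonferroni", {
  st <- env_stack(cbind(flat = rep(1, 6), ok = 1:6, ok2 = c(1, 4, 2, 9, 8, 7)),
                  nrow = 1, ncol = 6)
  xy <- xy_from_cell(st, 1:6)
  occ_a <- occurrence_set(xy$x[1:3], xy$y[1:3])
  occ_b <- occurrence_set(xy$x[4:6], xy$y[4:6])
  res <- welch_compare(occ_a, occ_b, st, adjust = "bonferroni")
  expect_true(is.na(res$p[res$layer == "flat"]))
  expect_match(res$flag[res$layer == "flat"], "zero variance")
  # family = the two testable layers
  ok <- res[res$layer %in% c("ok", "ok2"), ]
  expect_equal(ok$p_adj, pmin(ok$p * 2, 1))
  # identical samples with spread: t = 0, p = 1
  same <- welch_compare(occ_a, occ_a, st)
  expect_equal(same$t[same$layer == "ok"], 0)
  expect_equal(same$p[same$layer == "ok"], 1)
})
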