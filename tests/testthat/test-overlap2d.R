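make_tiny_grid <- function(o, e = matrix(1, nrow(o), ncol(o))) {
  nichekit:::new_occupancy_grid(o, e, seq_len(nrow(o)), seq_len(ncol(o)))
}

test_that("Schoener's D matches direct evaluation on hand-built grids", {
  # three occupied cells, background available everywhere
  g1 <- make_tiny_grid(matrix(c(0.5, 0.5, 0, 0, 0, 0, 0, 0, 0, 0), 10, 10))
  g2 <- make_tiny_grid(matrix(c(0, 0.5, 0.5, 0, 0, 0, 0, 0, 0, 0), 10, 10))
  expect_equal(schoener_d(g1, g2), 0.5)
  expect_equal(schoener_d(g1, g1), 1)
  # disjoint supports
  g3 <- make_tiny_grid(matrix(c(0, 0, 0, 0.3, 0.7, 0, 0, 0, 0, 0), 10, 10))
  expect_equal(schoener_d(g1, g3), 0)
  # symmetry
  expect_equal(schoener_d(g1, g2), schoener_d(g2, g1))
  # mismatched geometry is an error
  g4 <- nichekit:::new_occupancy_grid(g1$o, g1$e, seq_len(10) + 5,
                                      seq_len(10))
  expect_error(schoener_d(g1, g4), "share")
})

test_that("equivalency test: identical ranges give maximal conservatism p
           at the +1-corrected minimum", {
  bg <- fix_uniform_bg()
  set.seed(51)
  occ <- MASS::mvrnorm(60, c(0.4, 0.2), diag(c(0.2, 0.2)))
  res <- equivalency_test(occ, occ, bg, bg, R = 50, reps = 49, seed = 1)
  expect_equal(res$D_observed, 1)
  expect_equal(res$p_conservatism, 1 / 50)
  expect_equal(res$p_divergence, 1)
  expect_length(res$null_D, 49)
  expect_true(all(res$null_D >= 0 & res$null_D <= 1))
})

test_that("equivalency test detects separated niches", {
  bg <- fix_uniform_bg()
  set.seed(52)
  s1 <- MASS::mvrnorm(70, c(1.2, 1.0), diag(c(0.15, 0.15)))
  s2 <- MASS::mvrnorm(70, c(-1.2, -1.0), diag(c(0.15, 0.15)))
  res <- equivalency_test(s1, s2, bg, bg, R = 60, reps = 99, seed = 2)
  expect_lte(res$p_divergence, 0.05)
  expect_error(equivalency_test(s1[1:3, ], s2, bg, bg), ">= 5")
  expect_error(equivalency_test(s1, s2, bg, bg, reps = 5), "reps")
})

test_that("similarity test p-values have 1/(reps+1) granularity and detect
           conserved identical niches", {
  bg <- fix_uniform_bg()
  set.seed(53)
  occ <- MASS::mvrnorm(60, c(0.8, 0.6), diag(c(0.15, 0.15)))
  res <- similarity_test(occ, occ, bg, bg, R = 50, reps = 99, seed = 3)
  expect_lte(res$p_conservatism, 0.05)
  # granularity: with 99 replicates p is a multiple of 1/100, minimum 0.01
  expect_equal(res$p_conservatism * 100, round(res$p_conservatism * 100))
  expect_gte(res$p_conservatism, 0.01)
  expect_s3_class(tidy(res), "tbl_df")
})

test_that("a niche occupying its whole background is not flagged divergent
           by the similarity test", {
  bg <- fix_uniform_bg(3000)
  set.seed(54)
  occ <- bg[sample.int(nrow(bg), 80), ] # uses the entire envelope
  res <- similarity_test(occ, occ, bg, bg, R = 50, reps = 49, seed = 4)
  expect_gt(res$p_divergence, 0.05)
})

test_that("niche dynamics indices honour their identities", {
  bg <- fix_uniform_bg()
  set.seed(55)
  sa <- MASS::mvrnorm(80, c(0.9, 0.9), diag(c(0.2, 0.2)))
  sb <- MASS::mvrnorm(80, c(-0.9, -0.9), diag(c(0.2, 0.2)))
  grids <- nichekit:::pair_grids(sa, sb, bg, bg, R = 60)
  same <- niche_dynamics(grids$g1, grids$g1)
  expect_equal(same$expansion, 0)
  expect_equal(same$stability, 1)
  expect_equal(same$unfilling, 0)
  dyn <- niche_dynamics(grids$g1, grids$g2)
  expect_equal(dyn$expansion + dyn$stability, 1, tolerance = 1e-9)
  expect_true(all(unlist(dyn[1, 1:3]) >= 0 & unlist(dyn[1, 1:3]) <= 1))
  # fully disjoint supports: complete expansion and unfilling
  far1 <- MASS::mvrnorm(60, c(2.2, 2.2), diag(c(0.05, 0.05)))
  far2 <- MASS::mvrnorm(60, c(-2.2, -2.2), diag(c(0.05, 0.05)))
  gf <- nichekit:::pair_grids(far1, far2, bg, bg, R = 60)
  df <- niche_dynamics(gf$g1, gf$g2)
  expect_equal(df$expansion, 1)
  expect_equal(df$stability, 0)
  expect_equal(df$unfilling, 1)
})

test_that("the two-range comparison table is shaped like a niche table and
           skips tests when reps = 0", {
  bg <- fix_uniform_bg()
  set.seed(56)
  s1 <- MASS::mvrnorm(60, c(0.5, 0.5), diag(c(0.2, 0.2)))
  s2 <- MASS::mvrnorm(60, c(-0.5, -0.5), diag(c(0.2, 0.2)))
  tab <- overlap2d_table(s1, s2, bg, bg, R = 50, reps = 0,
                         labels = c("west", "east"))
  expect_equal(tab$comparison, c("west-east", "east-west"))
  expect_true(all(is.na(tab$similarity_p_div)))
  expect_equal(tab$d[1], tab$d[2])
  expect_equal(tab$stability + tab$expansion, c(1, 1), tolerance = 1e-9)
  expect_equal(tab$unfilling[1], {
    g <- nichekit:::pair_grids(s1, s2, bg, bg, R = 50)
    niche_dynamics(g$g1, g$g2)$unfilling
  })
})
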