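test_that("convex hulls recover exact volumes", {
  cube <- cube_points()
  h <- hull_niche(cube)
  expect_equal(h$volume, 1, tolerance = 1e-12)
  expect_equal(nrow(h$normals), 6) # six distinct supporting planes
  # regular tetrahedron with unit edges
  s <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
             c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  expect_equal(hull_niche(s)$volume, sqrt(2) / 12, tolerance = 1e-12)
  # interior points change nothing
  set.seed(61)
  inner <- matrix(runif(150, 0.05, 0.95), ncol = 3)
  h2 <- hull_niche(rbind(cube, inner))
  expect_equal(h2$volume, 1, tolerance = 1e-12)
  expect_setequal(h2$hull_vertices, 1:8)
})

test_that("degenerate point sets are rejected with a named deficiency", {
  flat <- cbind(runif(20), runif(20), 0)
  expect_error(hull_niche(flat), "coplanar")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(hull_niche(line), "collinear")
  expect_error(hull_niche(cube_points()[1:3, ]), "k \\+ 1")
})

test_that("hull overlap is exact on cube geometry and handles limits", {
  a <- hull_niche(cube_points())
  b <- hull_niche(cube_points(offset = c(0.5, 0, 0)))
  ov <- hull_overlap(a, b)
  expect_equal(ov$shared_volume, 0.5, tolerance = 1e-9)
  expect_equal(ov$pct_a_in_b, 50, tolerance = 1e-7)
  expect_equal(ov$pct_b_in_a, 50, tolerance = 1e-7)
  self <- hull_overlap(a, a)
  expect_equal(self$pct_a_in_b, 100, tolerance = 1e-7)
  expect_equal(self$shared_volume, 1, tolerance = 1e-9)
  far <- hull_niche(cube_points(offset = c(10, 0, 0)))
  none <- hull_overlap(a, far)
  expect_equal(none$shared_volume, 0)
  expect_equal(none$pct_a_in_b, 0)
})

test_that("Monte-Carlo hull overlap agrees with the exact route", {
  set.seed(62)
  P <- matrix(rnorm(360), ncol = 3)
  a <- hull_niche(P)
  b <- hull_niche(sweep(P, 2, c(0.8, 0, 0), `+`))
  exact <- hull_overlap(a, b, exact_max_planes = 1000)
  mc <- hull_overlap(a, b, exact_max_planes = 1, n_mc = 2e5, seed = 3)
  expect_equal(mc$method, "monte-carlo")
  expect_equal(exact$method, "exact")
  expect_equal(mc$shared_volume, exact$shared_volume,
               tolerance = 6 * mc$mc_se / exact$shared_volume)
  # overlap percentages are bounded and directional in general
  expect_true(all(c(exact$pct_a_in_b, exact$pct_b_in_a) <= 100))
})

test_that("2-D hull overlap clips polygons exactly", {
  sq <- as.matrix(expand.grid(0:1, 0:1))
  a <- hull_niche(sq, k = 2)
  b <- hull_niche(sweep(sq, 2, c(0.5, 0), `+`), k = 2)
  ov <- hull_overlap(a, b)
  expect_equal(ov$shared_volume, 0.5, tolerance = 1e-12)
})

test_that("posterior niche draws are centred on the data and concentrate
           with sample size", {
  set.seed(63)
  X <- MASS::mvrnorm(300, c(1, -1, 0), diag(c(1, 2, 0.5)))
  post <- posterior_niche(X, n_draws = 3000, seed = 5)
  expect_equal(colMeans(post$mu), colMeans(X), tolerance = 0.02)
  expect_identical(posterior_niche(X, n_draws = 50, seed = 9)$mu,
                   posterior_niche(X, n_draws = 50, seed = 9)$mu)
  # covariance draws shrink toward the sample covariance as n grows
  rel_err <- function(n) {
    Xn <- MASS::mvrnorm(n, c(0, 0, 0), diag(3))
    p <- posterior_niche(Xn, n_draws = 400, seed = 11)
    mean(vapply(seq_len(400), function(i) {
      norm(p$Sigma[, , i] - p$data_summary$cov, "F") /
        norm(p$data_summary$cov, "F")
    }, numeric(1)))
  }
  set.seed(64)
  expect_lt(rel_err(2000), rel_err(60))
  expect_error(posterior_niche(X[1:3, ]), "k \\+ 1")
})

test_that("ellipsoid overlap reproduces the niche-region definition", {
  # degenerate posteriors isolate the overlap integrator from data noise
  a <- fixed_ellipsoid_niche(c(0, 0, 0), diag(3))
  b <- fixed_ellipsoid_niche(c(1, 0, 0), diag(3))
  self <- ellipsoid_overlap(a, a, alpha = 0.95, nprob = 500, seed = 6)
  expect_equal(self$mean, 0.95, tolerance = 0.01)
  # region nesting: alpha = 0.99 region contains the 0.95 region
  o95 <- ellipsoid_overlap(a, b, 0.95, nprob = 500, seed = 7)
  o99 <- ellipsoid_overlap(a, b, 0.99, nprob = 500, seed = 7)
  expect_gt(o99$mean, o95$mean)
  expect_true(all(o99$samples >= o95$samples))
  expect_true(o95$ci[1] <= o95$mean && o95$mean <= o95$ci[2])
  expect_error(ellipsoid_overlap(a, b, alpha = 1.5), "alpha")
})

test_that("1-D ellipsoid overlap matches the normal-CDF oracle", {
  a1 <- fixed_ellipsoid_niche(0, matrix(1), n_draws = 3000)
  b1 <- fixed_ellipsoid_niche(2, matrix(1), n_draws = 3000)
  est <- ellipsoid_overlap(a1, b1, alpha = 0.95, nprob = 1000, seed = 8)
  truth <- analytic_overlap(virtual_species(0, matrix(1)),
                            virtual_species(2, matrix(1)), 0.95)
  expect_equal(est$mean, truth, tolerance = 0.01)
})

test_that("overlap is directional between unequal niches", {
  set.seed(65)
  small <- MASS::mvrnorm(200, c(0, 0, 0), diag(3) * 0.2)
  big <- MASS::mvrnorm(200, c(0.3, 0, 0), diag(3) * 2)
  ps <- posterior_niche(small, n_draws = 400, seed = 12)
  pb <- posterior_niche(big, n_draws = 400, seed = 13)
  fwd <- ellipsoid_overlap(ps, pb, 0.95, nprob = 400, seed = 14)
  rev <- ellipsoid_overlap(pb, ps, 0.95, nprob = 400, seed = 15)
  expect_gt(fwd$mean, rev$mean + 0.2) # small niche sits inside the big one
})

test_that("the 3-D comparison table reports both directions, alphas and
           per-PC overlaps", {
  set.seed(66)
  s1 <- MASS::mvrnorm(80, c(0, 0, 0), diag(3))
  s2 <- MASS::mvrnorm(80, c(1, 0, 0), diag(3))
  tab <- overlap3d_table(s1, s2, alphas = 0.95, n_draws = 200, nprob = 200,
                         seed = 2, labels = c("west", "east"))
  expect_equal(nrow(tab), 8) # 2 directions x 1 alpha x (complete + 3 PCs)
  expect_true(all(tab$ellipsoid_pct_lo <= tab$ellipsoid_pct_mean &
                    tab$ellipsoid_pct_mean <= tab$ellipsoid_pct_hi))
  cm <- tab[tab$axes == "PC1+PC2+PC3", ]
  expect_equal(cm$shared_cpv[1], cm$shared_cpv[2])
  expect_true(all(cm$hull_pct_overlap <= 100))
})
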