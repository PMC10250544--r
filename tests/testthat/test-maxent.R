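fix_bg2 <- function(n = 1500, seed = 71) {
  set.seed(seed)
  data.frame(x1 = rnorm(n), x2 = rnorm(n))
}

test_that("feature construction yields the expected design", {
  bg <- fix_bg2(200)
  expect_equal(nrow(build_features(bg, "lq")$defs), 4) # 2 l + 2 q
  bg3 <- cbind(bg, x3 = runif(200))
  expect_equal(nrow(build_features(bg3, "p")$defs), 3) # C(3,2) products
  expect_error(build_features(bg, character(0)), "non-empty")
  expect_error(build_features(bg["x1"], "p"), ">= 2 predictors")
  # hinge: zero on one side of the knot, linear ramp on the other
  fs <- build_features(bg, "h", n_knots = 3)
  d <- fs$defs[fs$defs$type == "hf", ][1, ]
  j <- which(fs$defs$name == d$name)
  xs <- data.frame(x1 = c(d$knot - 1, d$knot, d$knot + 0.5),
                   x2 = c(0, 0, 0))
  f <- featurize(fs, xs)[, j]
  expect_equal(f[1], 0)
  expect_equal(f[2], 0)
  scale_j <- unname(fs$f_max[j] - fs$f_min[j])
  expect_equal(f[3], 0.5 / scale_j)
  # threshold features are steps at the same knots
  ft <- build_features(bg, "t", n_knots = 3)
  dt <- ft$defs[1, ]
  jt <- 1
  expect_equal(featurize(ft, data.frame(x1 = dt$knot + c(-1, 1),
                                        x2 = c(0, 0)))[, jt], c(0, 1))
})

test_that("heavy regularization collapses to the uniform model", {
  bg <- fix_bg2(800)
  set.seed(72)
  pres <- bg[sample.int(800, 60), ]
  fs <- build_features(bg, "lq")
  m <- fit_maxent(pres, bg, fs, rm = 1e6)
  expect_true(all(m$beta == 0))
  raw <- predict(m, bg, type = "raw")
  expect_equal(raw, rep(1 / 800, 800), tolerance = 1e-12)
  cc <- predict(m, bg, type = "cloglog")
  expect_equal(unique(round(cc, 10)), round(1 - exp(-1), 10))
})

test_that("a shifted presence sample gets a positive linear coefficient", {
  bg <- fix_bg2(1000)
  set.seed(73)
  w <- exp(1.5 * bg$x1)
  pres <- bg[sample.int(1000, 120, replace = TRUE, prob = w / sum(w)), ]
  m <- fit_maxent(pres, bg, build_features(bg, "l"), rm = 1)
  expect_gt(m$beta[["l_x1"]], 0)
  expect_equal(sum(predict(m, bg, type = "raw")), 1, tolerance = 1e-9)
})

test_that("the optimizer matches a brute-force grid search on a tiny
           instance", {
  set.seed(74)
  bg <- data.frame(x1 = runif(20), x2 = runif(20))
  pres <- bg[sample.int(20, 12, replace = TRUE), ]
  fs <- build_features(bg, "l")
  m <- fit_maxent(pres, bg, fs, rm = 0.5)
  Hp <- featurize(fs, as.matrix(pres))
  Hb <- featurize(fs, as.matrix(bg))
  obj <- function(b) {
    -mean(Hp %*% b) + log(sum(exp(Hb %*% b))) + sum(m$lambda * abs(b))
  }
  grid <- as.matrix(expand.grid(seq(-2, 8, by = 0.05),
                                seq(-6, 6, by = 0.05)))
  brute <- min(apply(grid, 1, obj))
  expect_lte(m$objective, brute + 1e-4)
  expect_equal(m$objective, obj(m$beta), tolerance = 1e-10)
})

test_that("the L1 norm of the fit is non-increasing along the
           regularization path", {
  bg <- fix_bg2(600)
  set.seed(75)
  w <- exp(2 * bg$x1)
  pres <- bg[sample.int(600, 150, replace = TRUE, prob = w / sum(w)), ]
  fs <- build_features(bg, "lq")
  l1 <- vapply(c(0.1, 0.5, 1, 2, 5, 10), function(rm) {
    sum(abs(fit_maxent(pres, bg, fs, rm = rm)$beta))
  }, numeric(1))
  expect_true(all(diff(l1) <= 1e-6))
})

test_that("suitability ranks recover a planted log-linear niche", {
  bg <- fix_bg2(2000, seed = 76)
  set.seed(77)
  eta_true <- 2 * bg$x1 - 1 * bg$x2
  w <- exp(eta_true)
  pres <- bg[sample.int(2000, 500, replace = TRUE, prob = w / sum(w)), ]
  m <- fit_maxent(pres, bg, build_features(bg, "lq"), rm = 1)
  cc <- predict(m, bg, type = "cloglog")
  expect_gte(cor(cc, eta_true, method = "spearman"), 0.9)
})

test_that("prediction masks or clamps out-of-range cells", {
  bg <- fix_bg2(500, seed = 78)
  set.seed(79)
  pres <- bg[sample.int(500, 50), ]
  m <- fit_maxent(pres, bg, build_features(bg, "l"), rm = 1)
  new <- data.frame(x1 = c(0, 99), x2 = c(0, 0))
  masked <- predict(m, new, type = "cloglog", extrapolation = "mask")
  expect_false(is.na(masked[1]))
  expect_true(is.na(masked[2]))
  clamped <- predict(m, new, type = "cloglog", extrapolation = "clamp")
  edge <- data.frame(x1 = max(bg$x1), x2 = 0)
  expect_equal(clamped[2], predict(m, edge, type = "cloglog"))
  # identical scenario masks nothing
  same <- predict(m, bg, type = "cloglog", extrapolation = "mask")
  expect_false(any(is.na(same)))
  expect_warning(predict(m, data.frame(x1 = 99, x2 = 99)), "masked")
  # stack input returns a suitability map in [0, 1]
  st <- env_stack(as.matrix(fix_bg2(100, seed = 80)), nrow = 10, ncol = 10)
  map <- predict(m, st)
  expect_s3_class(map, "suitability_map")
  v <- map$values[, "suitability"]
  expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))
})
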