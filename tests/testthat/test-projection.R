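fix_sdm_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) {
      set.seed(91)
      st <- make_landscape(landscape_spec(40, 40, n_layers = 2,
                                          autocorr_range = 4, seed = 91))
      colnames(st$values) <- c("PC1", "PC2")
      bg <- as.data.frame(st$values)
      sp <- virtual_species(c(0.4, 0.4), diag(c(0.2, 0.2)))
      suit <- nichekit:::gaussian_suitability(sp, st$values)
      pres <- bg[sample.int(nrow(bg), 150, prob = suit), ]
      w <<- list(stack = st, bg = bg, pres = pres)
    }
    w
  }
})

test_that("single-replicate transfer equals a plain prediction", {
  w <- fix_sdm_world()
  fs <- build_features(w$bg, "lq")
  m <- fit_maxent(w$pres, w$bg, fs, rm = 1)
  plain <- predict(m, w$stack, type = "cloglog", extrapolation = "mask")
  tr <- transfer(w$pres, w$bg, "lq", 1, w$stack, replicates = 1, seed = 1)
  expect_equal(tr$values[, "suitability"], plain$values[, "suitability"],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("bootstrap-mean maps stay within per-replicate envelopes and
           deep extrapolation triggers heavy masking", {
  w <- fix_sdm_world()
  tr <- transfer(w$pres, w$bg, "lq", 1, w$stack, replicates = 4, seed = 2)
  v <- tr$values[, "suitability"]
  expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 1))
  expect_true(all(tr$values[!is.na(v), "sd"] >= 0))
  far <- w$stack
  far$values <- far$values + 50
  expect_warning(
    transfer(w$pres, w$bg, "lq", 1, far, replicates = 2, seed = 3),
    "outside the calibration range")
  bad <- w$stack
  colnames(bad$values) <- c("PC1", "PC9")
  expect_error(transfer(w$pres, w$bg, "lq", 1, bad), "lacks predictor")
})

test_that("agreement maps count jointly suitable cells", {
  grid <- function(v) {
    s <- env_stack(cbind(suitability = v), nrow = 4, ncol = 4)
    class(s) <- c("suitability_map", class(s))
    s
  }
  v1 <- c(rep(0.8, 8), rep(0.2, 8))
  v2 <- c(rep(0.8, 4), rep(0.1, 8), rep(0.9, 4))
  ag <- agreement_map(grid(v1), grid(v2))
  expect_equal(ag$common_cell_count, sum(v1 >= 0.5 & v2 >= 0.5))
  # self agreement is the thresholded footprint
  self <- agreement_map(grid(v1), grid(v1))
  expect_equal(self$map$values[, 1], as.numeric(v1 >= 0.5))
  # complementary maps share (almost) nothing at 0.5
  comp <- agreement_map(grid(v1), grid(1 - v1))
  expect_equal(comp$common_cell_count, 0)
  small <- env_stack(cbind(suitability = 1), nrow = 1, ncol = 1)
  expect_error(agreement_map(grid(v1), small), "grid mismatch")
})

test_that("spread classification implements the four categories with the
           boundary on the high side", {
  maps <- function(lv, cv) {
    mk <- function(v) {
      s <- env_stack(cbind(suitability = rep(v, 4)), nrow = 2, ncol = 2)
      class(s) <- c("suitability_map", class(s))
      s
    }
    list(local = mk(lv), cont = mk(cv))
  }
  occ <- occurrence_set(x = 0.5, y = 0.5)
  cat_of <- function(lv, cv) {
    m <- maps(lv, cv)
    as.character(classify_spread(occ, m$local, m$cont)$category[1])
  }
  expect_equal(cat_of(0.7, 0.6), "stabilizing")
  expect_equal(cat_of(0.7, 0.3), "adaptation")
  expect_equal(cat_of(0.3, 0.7), "colonization")
  expect_equal(cat_of(0.2, 0.1), "sink")
  expect_equal(cat_of(0.5, 0.5), "stabilizing") # boundary counts as high
})

test_that("spread classification is order-invariant, complete, and
           flags masked cells", {
  set.seed(92)
  n <- 40
  mk <- function(v) {
    s <- env_stack(cbind(suitability = v), nrow = 8, ncol = 8)
    class(s) <- c("suitability_map", class(s))
    s
  }
  lm <- mk(runif(64))
  cm <- mk(runif(64))
  xy <- xy_from_cell(lm, sample.int(64, n))
  occ <- occurrence_set(xy$x, xy$y)
  cls <- classify_spread(occ, lm, cm)
  expect_equal(sum(tidy(cls)$n), n)
  shuffled <- classify_spread(occ[sample.int(n), ], lm, cm)
  expect_equal(as.character(shuffled$category[order(shuffled$id)]),
               as.character(cls$category))
  # threshold 0 puts everything at or above it
  all_high <- classify_spread(occ, lm, cm, threshold = 0)
  expect_true(all(all_high$category == "stabilizing"))
  # masked local suitability leads to unscored records
  lmna <- lm
  lmna$values[, 1] <- NA
  expect_warning(cls_na <- classify_spread(occ, lmna, cm), "unscored")
  expect_true(all(cls_na$category == "unscored"))
})
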