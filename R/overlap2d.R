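#' Schoener's D niche overlap between two occupancy grids
#'
#' `D = 1 - 0.5 * sum(|Z1 - Z2|)` over grid cells, where `Z` is the
#' normalized occupancy (corrected by background availability by default).
#' 0 means no overlap, 1 identical niches.
#'
#' @param g1,g2 [occupancy_grid()]s sharing resolution and axis ranges.
#' @param corrected use availability-corrected occupancy (`Z`) or the
#'   uncorrected occurrence density (`Z_uncor`).
#' @return D in \[0, 1\].
#' @export
schoener_d <- function(g1, g2, corrected = TRUE) {
  stopifnot(inherits(g1, "occupancy_grid"), inherits(g2, "occupancy_grid"))
  if (g1$R != g2$R ||
      max(abs(unlist(g1$axis_ranges) - unlist(g2$axis_ranges))) > 1e-9) {
    stop("grids do not share resolution/axis ranges", call. = FALSE)
  }
  Z1 <- if (corrected) g1$Z else g1$Z_uncor
  Z2 <- if (corrected) g2$Z else g2$Z_uncor
  1 - 0.5 * sum(abs(Z1 - Z2))
}

# Shared grid geometry for a two-range comparison: axis ranges from the
# pooled background envelope (+5% margin), background densities computed
# once per range.
espace_pair_setup <- function(bg1, bg2, R, pad = 0.05) {
  bgp <- rbind(as.matrix(bg1)[, 1:2], as.matrix(bg2)[, 1:2])
  sp <- apply(bgp, 2, range)
  margin <- pad * (sp[2, ] - sp[1, ])
  list(x = c(sp[1, 1] - margin[1], sp[2, 1] + margin[1]),
       y = c(sp[1, 2] - margin[2], sp[2, 2] + margin[2]))
}

pair_grids <- function(s1, s2, bg1, bg2, R = 100, pad = 0.05) {
  ranges <- espace_pair_setup(bg1, bg2, R, pad)
  list(g1 = occupancy_grid(s1, bg1, R = R, axis_ranges = ranges),
       g2 = occupancy_grid(s2, bg2, R = R, axis_ranges = ranges),
       ranges = ranges)
}

occ_grid_from_e <- function(scores, e_grid, xg, yg) {
  so <- as.matrix(scores)[, 1:2, drop = FALSE]
  bw <- c(silverman_bw(so[, 1]), silverman_bw(so[, 2]))
  o <- kde_on_grid(so, xg, yg, bw[1], bw[2])
  new_occupancy_grid(o, e_grid, xg, yg, bw)
}

new_overlap_test_result <- function(test, D_observed, null_D, n_reps,
                                    direction) {
  p_div <- (sum(null_D <= D_observed) + 1) / (n_reps + 1)
  p_con <- (sum(null_D >= D_observed) + 1) / (n_reps + 1)
  structure(list(test = test, D_observed = D_observed, null_D = null_D,
                 p_divergence = p_div, p_conservatism = p_con,
                 n_reps = n_reps, direction = direction),
            class = "overlap_test_result")
}

#' @export
print.overlap_test_result <- function(x, ...) {
  cat("<", x$test, " test> D = ", round(x$D_observed, 3),
      ", p(divergence) = ", round(x$p_divergence, 4),
      ", p(conservatism) = ", round(x$p_conservatism, 4),
      " (", x$n_reps, " reps)\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.overlap_test_result <- function(x, ...) {
  tibble::tibble(test = x$test, direction = paste(x$direction, collapse = "-"),
                 d = x$D_observed, p_divergence = x$p_divergence,
                 p_conservatism = x$p_conservatism, n_reps = x$n_reps)
}

#' @exportS3Method generics::glance
glance.overlap_test_result <- function(x, ...) tidy.overlap_test_result(x)

#' Niche equivalency permutation test
#'
#' Asks whether the two niches are interchangeable: the null distribution
#' of D is built by pooling the occurrence scores of both ranges, randomly
#' re-splitting them into groups of the original sizes, rebuilding the
#' occupancy grids against the fixed backgrounds, and recomputing D.
#' `p_divergence` is the +1-corrected fraction of null D values at or below
#' the observed D (small = niches less equivalent than random re-splits);
#' `p_conservatism` is its upper-tail counterpart. Ties count toward the
#' extreme set.
#'
#' @param scores1,scores2 two-column PC score tables of the two ranges'
#'   occurrences (each >= 5 rows).
#' @param bg1,bg2 two-column PC score tables of the two backgrounds.
#' @param R grid resolution per axis.
#' @param reps number of permutation replicates (>= 19).
#' @param seed integer seed.
#' @param corrected availability-corrected occupancy for D.
#' @return An `overlap_test_result`.
#' @export
equivalency_test <- function(scores1, scores2, bg1, bg2, R = 100,
                             reps = 100, seed = 1, corrected = TRUE) {
  s1 <- as.matrix(scores1)[, 1:2, drop = FALSE]
  s2 <- as.matrix(scores2)[, 1:2, drop = FALSE]
  if (nrow(s1) < 5 || nrow(s2) < 5) {
    stop("each occurrence set needs >= 5 records", call. = FALSE)
  }
  if (reps < 19) stop("`reps` must be >= 19", call. = FALSE)
  ranges <- espace_pair_setup(bg1, bg2, R)
  xg <- seq(ranges$x[1], ranges$x[2], length.out = R)
  yg <- seq(ranges$y[1], ranges$y[2], length.out = R)
  e1 <- occupancy_grid(s1, bg1, R = R, axis_ranges = ranges)$e
  e2 <- occupancy_grid(s2, bg2, R = R, axis_ranges = ranges)$e
  g1 <- occ_grid_from_e(s1, e1, xg, yg)
  g2 <- occ_grid_from_e(s2, e2, xg, yg)
  D_obs <- schoener_d(g1, g2, corrected)
  pool <- rbind(s1, s2)
  n1 <- nrow(s1)
  set.seed(seed)
  null_D <- vapply(seq_len(reps), function(r) {
    idx <- sample.int(nrow(pool), n1)
    schoener_d(occ_grid_from_e(pool[idx, , drop = FALSE], e1, xg, yg),
               occ_grid_from_e(pool[-idx, , drop = FALSE], e2, xg, yg),
               corrected)
  }, numeric(1))
  new_overlap_test_result("equivalency", D_obs, null_D, reps,
                          direction = c("1", "2"))
}

#' Niche similarity (background) randomization test
#'
#' Asks whether the observed overlap differs from what random placement of
#' one niche within its own background would produce: per replicate, the
#' shifted range's occurrence scores are translated by a uniform random
#' offset (toroidal wrap within the shared grid extent), shifts that move
#' more than `max_off_support` of the occurrence density off that range's
#' background support are rejected and redrawn, the occupancy grid is
#' rebuilt and D recomputed. p-values as in [equivalency_test()].
#'
#' @inheritParams equivalency_test
#' @param shift which range's niche is translated (`"second"` or
#'   `"first"`); run both directions for a two-row comparison table.
#' @param max_off_support maximum tolerated fraction of occurrence density
#'   off the background support for a candidate shift.
#' @return An `overlap_test_result`.
#' @export
similarity_test <- function(scores1, scores2, bg1, bg2, R = 100, reps = 100,
                            seed = 1, shift = c("second", "first"),
                            corrected = TRUE, max_off_support = 0.5) {
  shift <- match.arg(shift)
  s1 <- as.matrix(scores1)[, 1:2, drop = FALSE]
  s2 <- as.matrix(scores2)[, 1:2, drop = FALSE]
  if (nrow(s1) < 5 || nrow(s2) < 5) {
    stop("each occurrence set needs >= 5 records", call. = FALSE)
  }
  if (reps < 19) stop("`reps` must be >= 19", call. = FALSE)
  ranges <- espace_pair_setup(bg1, bg2, R)
  xg <- seq(ranges$x[1], ranges$x[2], length.out = R)
  yg <- seq(ranges$y[1], ranges$y[2], length.out = R)
  e1 <- occupancy_grid(s1, bg1, R = R, axis_ranges = ranges)$e
  e2 <- occupancy_grid(s2, bg2, R = R, axis_ranges = ranges)$e
  g1 <- occ_grid_from_e(s1, e1, xg, yg)
  g2 <- occ_grid_from_e(s2, e2, xg, yg)
  D_obs <- schoener_d(g1, g2, corrected)
  moving <- if (shift == "second") s2 else s1
  e_mov <- if (shift == "second") e2 else e1
  g_fix <- if (shift == "second") g1 else g2
  span <- c(ranges$x[2] - ranges$x[1], ranges$y[2] - ranges$y[1])
  lo <- c(ranges$x[1], ranges$y[1])
  set.seed(seed)
  null_D <- numeric(reps)
  budget <- 50 * reps
  for (r in seq_len(reps)) {
    repeat {
      budget <- budget - 1
      if (budget < 0) {
        stop("background too small to translate the niche within it",
             call. = FALSE)
      }
      off <- stats::runif(2, 0, span)
      shifted <- sweep(moving, 2, lo)
      shifted <- sweep(shifted, 2, off, `+`) %% rep(span, each = nrow(moving))
      shifted <- sweep(shifted, 2, lo, `+`)
      g_shift <- occ_grid_from_e(shifted, e_mov, xg, yg)
      off_mass <- sum(g_shift$o[e_mov == 0]) / sum(g_shift$o)
      if (off_mass <= max_off_support) break
    }
    null_D[r] <- schoener_d(g_fix, g_shift, corrected)
  }
  new_overlap_test_result("similarity", D_obs, null_D, reps,
                          direction = if (shift == "second") c("1", "2")
                                      else c("2", "1"))
}

#' Expansion / stability / unfilling niche dynamics
#'
#' With `S_A` the cells occupied in range A (`z_A > 0`) and `S_B` likewise,
#' optionally restricted to analogue environments (cells available in both
#' backgrounds): expansion is the share of B's occupancy in cells B uses
#' but A does not; stability is its complement (`expansion + stability =
#' 1`); unfilling is the share of A's occupancy in cells A uses but B does
#' not.
#'
#' @param gA,gB [occupancy_grid()]s on a shared grid; A is the source
#'   range, B the comparison range.
#' @param analogue_only restrict all sets to cells with `e > 0` in both
#'   backgrounds (default TRUE).
#' @param occupancy_quantile tail trim defining "occupied": a range's
#'   occupied set keeps its highest-occupancy cells until `1 -
#'   occupancy_quantile` of its occupancy mass is enclosed, discarding the
#'   thin kernel tails that would otherwise blanket the grid. 0 uses the
#'   full `z > 0` support.
#' @return A `niche_dynamics` tibble row: `expansion`, `stability`,
#'   `unfilling`, `analogue_restricted`.
#' @export
niche_dynamics <- function(gA, gB, analogue_only = TRUE,
                           occupancy_quantile = 0.05) {
  stopifnot(inherits(gA, "occupancy_grid"), inherits(gB, "occupancy_grid"))
  if (gA$R != gB$R ||
      max(abs(unlist(gA$axis_ranges) - unlist(gB$axis_ranges))) > 1e-9) {
    stop("grids do not share resolution/axis ranges", call. = FALSE)
  }
  zA <- gA$z; zB <- gB$z
  keep <- matrix(TRUE, gA$R, gA$R)
  if (analogue_only) keep <- gA$e > 0 & gB$e > 0
  # occupied set: cells carrying the top 1-q of the range's occurrence
  # density, so thin kernel tails do not blanket the grid; the index
  # weights stay on the corrected occupancy z
  occupied <- function(g) {
    o <- g$o
    if (occupancy_quantile <= 0) return(o > 0 & g$z > 0)
    v <- sort(o[o > 0], decreasing = TRUE)
    lvl <- v[which(cumsum(v) >= (1 - occupancy_quantile) * sum(v))[1]]
    o >= lvl & g$z > 0
  }
  SA <- occupied(gA) & keep
  SB <- occupied(gB) & keep
  if (!any(SA) || !any(SB)) stop("empty occupancy", call. = FALSE)
  expansion <- sum(zB[SB & !SA]) / sum(zB[SB])
  unfilling <- sum(zA[SA & !SB]) / sum(zA[SA])
  out <- tibble::tibble(expansion = expansion, stability = 1 - expansion,
                        unfilling = unfilling,
                        analogue_restricted = analogue_only)
  class(out) <- c("niche_dynamics", class(out))
  out
}

#' Two-range 2-D niche comparison table
#'
#' Runs the full 2-D comparison in both directions and returns a tidy
#' table shaped like a niche-comparison results table: one row per
#' direction with D, similarity and equivalency p-values (divergence and
#' conservatism), and the unfilling/stability/expansion indices.
#'
#' @inheritParams equivalency_test
#' @param labels length-2 character, names of the two ranges.
#' @param reps permutation replicates for both tests (0 skips the tests
#'   and leaves the p-value columns `NA`).
#' @return A tibble with two rows (A vs B and B vs A).
#' @export
overlap2d_table <- function(scores1, scores2, bg1, bg2, R = 100, reps = 100,
                            seed = 1, corrected = TRUE,
                            labels = c("A", "B")) {
  grids <- pair_grids(scores1, scores2, bg1, bg2, R = R)
  D <- schoener_d(grids$g1, grids$g2, corrected)
  dyn12 <- niche_dynamics(grids$g1, grids$g2)
  dyn21 <- niche_dynamics(grids$g2, grids$g1)
  if (reps > 0) {
    eq <- equivalency_test(scores1, scores2, bg1, bg2, R, reps, seed,
                           corrected)
    si12 <- similarity_test(scores1, scores2, bg1, bg2, R, reps, seed,
                            shift = "second", corrected = corrected)
    si21 <- similarity_test(scores1, scores2, bg1, bg2, R, reps, seed + 1,
                            shift = "first", corrected = corrected)
    eqp <- c(eq$p_divergence, eq$p_conservatism)
    sim <- list(c(si12$p_divergence, si12$p_conservatism),
                c(si21$p_divergence, si21$p_conservatism))
  } else {
    eqp <- c(NA_real_, NA_real_)
    sim <- list(c(NA_real_, NA_real_), c(NA_real_, NA_real_))
  }
  tibble::tibble(
    comparison = c(paste(labels[1], labels[2], sep = "-"),
                   paste(labels[2], labels[1], sep = "-")),
    d = D,
    similarity_p_div = c(sim[[1]][1], sim[[2]][1]),
    similarity_p_con = c(sim[[1]][2], sim[[2]][2]),
    equivalency_p_div = eqp[1],
    equivalency_p_con = eqp[2],
    unfilling = c(dyn12$unfilling, dyn21$unfilling),
    stability = c(dyn12$stability, dyn21$stability),
    expansion = c(dyn12$expansion, dyn21$expansion))
}
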