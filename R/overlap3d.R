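#' Convex-polyhedron niche
#'
#' Expresses a niche in k-dimensional PC space as the convex polytope
#' connecting the extreme occurrences — a conservative envelope of the
#' conditions used. Supported in two and three dimensions.
#'
#' @param scores n x k matrix/data frame of occurrence PC scores.
#' @param k dimension (2 or 3); defaults to the column count.
#' @return A `convex_niche`: `points`, `hull_vertices` (row indices of the
#'   input on the hull), `volume` (area for k = 2), and the supporting
#'   half-space system (`normals`, `offsets`).
#' @export
hull_niche <- function(scores, k = NULL) {
  P <- as.matrix(scores)
  if (is.null(k)) k <- ncol(P)
  if (!k %in% c(2, 3)) stop("k must be 2 or 3", call. = FALSE)
  P <- P[, seq_len(k), drop = FALSE]
  if (nrow(P) < k + 1) stop("need at least k + 1 points", call. = FALSE)
  h <- if (k == 3) hull3d(P) else hull2d(P)
  pl <- if (k == 3) distinct_planes(h$normals, h$offsets)
        else list(normals = h$normals, offsets = h$offsets)
  structure(
    list(points = P, k = k,
         hull_vertices = if (k == 3) h$vertices else h$vertices_idx,
         faces = if (k == 3) h$faces else NULL,
         normals = pl$normals, offsets = pl$offsets,
         volume = h$volume, interior = h$interior, tol = h$tol),
    class = "convex_niche")
}

#' @export
print.convex_niche <- function(x, ...) {
  cat("<convex_niche> ", x$k, "-D, ", length(x$hull_vertices),
      " hull vertices, volume ", signif(x$volume, 5), "\n", sep = "")
  invisible(x)
}

#' Point containment in a convex niche
#'
#' @param niche a `convex_niche`.
#' @param pts matrix/data frame of points (k columns).
#' @return Logical vector.
#' @export
in_hull <- function(niche, pts) {
  pts <- as.matrix(pts)[, seq_len(niche$k), drop = FALSE]
  in_halfspaces(pts, niche$normals, niche$offsets, tol = niche$tol * 10)
}

#' Directional overlap of two convex-polyhedron niches
#'
#' Computes the intersection volume of the two polytopes and reports it
#' both as a shared volume and as the percentage of each niche contained
#' in the other. In 2-D the intersection is clipped exactly. In 3-D it is
#' exact (half-space vertex enumeration) while the combined number of
#' distinct facet planes is at most `exact_max_planes`; beyond that a
#' seeded Monte-Carlo volume estimate is used and its standard error
#' reported.
#'
#' @param a,b `convex_niche`s of the same dimension.
#' @param exact_max_planes plane-count cutoff for the exact 3-D route.
#' @param n_mc Monte-Carlo sample size for the sampling route.
#' @param seed integer seed (Monte-Carlo route only).
#' @return A tibble row: `pct_a_in_b`, `pct_b_in_a`, `shared_volume`,
#'   `method`, `mc_se`.
#' @export
hull_overlap <- function(a, b, exact_max_planes = 90, n_mc = 1e6, seed = 1) {
  stopifnot(inherits(a, "convex_niche"), inherits(b, "convex_niche"))
  if (a$k != b$k) stop("dimension mismatch", call. = FALSE)
  mc_se <- NA_real_
  if (a$k == 2) {
    inter <- clip_convex_polygon(a$points[a$hull_vertices, , drop = FALSE],
                                 b$normals, b$offsets)
    shared <- poly_area(inter)
    method <- "exact"
  } else {
    normals <- rbind(a$normals, b$normals)
    offsets <- c(a$offsets, b$offsets)
    if (nrow(normals) <= exact_max_planes) {
      shared <- halfspace_intersection_volume(normals, offsets,
                                              tol = 10 * max(a$tol, b$tol))
      method <- "exact"
    } else {
      # sample inside the smaller hull's bounding box; the hull with the
      # smaller volume conditions the ratio estimate better
      base <- if (a$volume <= b$volume) a else b
      other <- if (a$volume <= b$volume) b else a
      set.seed(seed)
      box <- apply(base$points[base$hull_vertices, , drop = FALSE], 2, range)
      pts <- cbind(stats::runif(n_mc, box[1, 1], box[2, 1]),
                   stats::runif(n_mc, box[1, 2], box[2, 2]),
                   stats::runif(n_mc, box[1, 3], box[2, 3]))
      inb <- in_hull(base, pts)
      nin <- sum(inb)
      p <- if (nin == 0) 0 else
        sum(in_hull(other, pts[inb, , drop = FALSE])) / nin
      shared <- base$volume * p
      mc_se <- base$volume * sqrt(p * (1 - p) / max(nin, 1))
      method <- "monte-carlo"
    }
  }
  tibble::tibble(pct_a_in_b = 100 * shared / a$volume,
                 pct_b_in_a = 100 * shared / b$volume,
                 shared_volume = shared, method = method, mc_se = mc_se)
}

#' Posterior sample of a multivariate-normal niche
#'
#' Bayesian estimate of an ellipsoidal niche: draws from the conjugate
#' normal–inverse-Wishart posterior under the noninformative reference
#' prior, given the occurrence PC scores. Covariance draws follow
#' inverse-Wishart((n-1) S, n-1) and, given a covariance draw, the mean
#' follows normal(sample mean, covariance / n).
#'
#' @param scores n x k matrix/data frame of PC scores (n > k + 1).
#' @param n_draws number of Monte-Carlo posterior draws.
#' @param seed integer seed.
#' @return An `ellipsoid_niche`: `mu` (draws x k), `Sigma` (k x k x draws),
#'   `n_draws`, `data_summary` (n, sample mean, sample covariance).
#' @export
posterior_niche <- function(scores, n_draws = 10000, seed = 1) {
  X <- as.matrix(scores)
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 1) stop("need n > k + 1 occurrences", call. = FALSE)
  xbar <- colMeans(X)
  S <- stats::cov(X)
  ch <- tryCatch(chol(S), error = function(e) {
    stop("singular sample covariance", call. = FALSE)
  })
  set.seed(seed)
  W <- stats::rWishart(n_draws, df = n - 1, Sigma = chol2inv(chol((n - 1) * S)))
  mu <- matrix(NA_real_, n_draws, k)
  Sigma <- array(NA_real_, c(k, k, n_draws))
  for (i in seq_len(n_draws)) {
    Sig <- chol2inv(chol(W[, , i]))
    Sigma[, , i] <- Sig
    mu[i, ] <- xbar + drop(t(chol(Sig)) %*% stats::rnorm(k)) / sqrt(n)
  }
  structure(
    list(mu = mu, Sigma = Sigma, n_draws = n_draws, k = k,
         data_summary = list(n = n, mean = xbar, cov = S)),
    class = "ellipsoid_niche")
}

#' @export
print.ellipsoid_niche <- function(x, ...) {
  cat("<ellipsoid_niche> ", x$k, "-D, ", x$n_draws,
      " posterior draws (n = ", x$data_summary$n, ")\n", sep = "")
  invisible(x)
}

#' Posterior niche-region overlap of two ellipsoidal niches
#'
#' For each paired posterior draw, samples `nprob` points from niche A's
#' normal distribution and records the fraction falling inside niche B's
#' alpha-probability ellipsoid (Mahalanobis distance within the chi-squared
#' quantile). The resulting posterior sample of overlap fractions is
#' summarized by its mean and an equal-tailed credible interval. Restrict
#' `axes` to a single PC for the one-dimensional per-predictor overlaps.
#'
#' @param a,b `ellipsoid_niche`s of matching dimension.
#' @param alpha niche-region size (e.g. 0.95 or 0.99).
#' @param nprob points sampled from A per posterior draw.
#' @param seed integer seed.
#' @param axes integer vector of PC indices to use (default all).
#' @param ci_level credibility level of the equal-tailed interval.
#' @return An `overlap_posterior`: `samples`, `mean`, `ci`, `alpha`,
#'   `axes`, `ci_level`.
#' @export
ellipsoid_overlap <- function(a, b, alpha = 0.95, nprob = 1000, seed = 1,
                              axes = NULL, ci_level = 0.95) {
  stopifnot(inherits(a, "ellipsoid_niche"), inherits(b, "ellipsoid_niche"))
  if (a$k != b$k) stop("dimension mismatch", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  if (is.null(axes)) axes <- seq_len(a$k)
  k <- length(axes)
  m <- min(a$n_draws, b$n_draws)
  q <- stats::qchisq(alpha, k)
  set.seed(seed)
  samples <- numeric(m)
  for (i in seq_len(m)) {
    Sa <- a$Sigma[axes, axes, i, drop = FALSE]; dim(Sa) <- c(k, k)
    Sb <- b$Sigma[axes, axes, i, drop = FALSE]; dim(Sb) <- c(k, k)
    X <- matrix(stats::rnorm(nprob * k), nprob, k) %*% chol(Sa)
    X <- sweep(X, 2, a$mu[i, axes], `+`)
    d <- sweep(X, 2, b$mu[i, axes])
    Qb <- chol2inv(chol(Sb))
    samples[i] <- mean(rowSums((d %*% Qb) * d) <= q)
  }
  lo <- (1 - ci_level) / 2
  structure(
    list(samples = samples, mean = mean(samples),
         ci = unname(stats::quantile(samples, c(lo, 1 - lo))),
         alpha = alpha, axes = axes, ci_level = ci_level),
    class = "overlap_posterior")
}

#' @export
print.overlap_posterior <- function(x, ...) {
  cat("<overlap_posterior> alpha = ", x$alpha, ": mean ",
      round(100 * x$mean, 1), "%, ", round(100 * x$ci_level), "% CI [",
      round(100 * x$ci[1], 1), ", ", round(100 * x$ci[2], 1), "]%\n",
      sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.overlap_posterior <- function(x, ...) {
  tibble::tibble(alpha = x$alpha,
                 axes = paste(x$axes, collapse = "+"),
                 mean = x$mean, ci_low = x$ci[1], ci_high = x$ci[2],
                 ci_level = x$ci_level, n_draws = length(x$samples))
}

#' @exportS3Method ggplot2::autoplot
autoplot.overlap_posterior <- function(object, ...) {
  df <- tibble::tibble(overlap = object$samples)
  ggplot2::ggplot(df, ggplot2::aes(.data$overlap)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = c(object$mean, object$ci),
                        linetype = c("solid", "dashed", "dashed")) +
    ggplot2::labs(x = paste0("overlap fraction (alpha = ", object$alpha, ")"),
                  y = "posterior draws")
}

#' Two-range 3-D overlap comparison table
#'
#' Runs both directions of the 3-D comparison: convex-polyhedron volumes
#' and containment percentages, and Bayesian ellipsoid overlaps (posterior
#' mean and credible interval) for the full PC set and each individual PC,
#' at each requested niche-region size.
#'
#' @param scores1,scores2 n x 3 PC score tables for the two ranges.
#' @param alphas niche-region sizes.
#' @param n_draws posterior draws per niche.
#' @param nprob points per posterior draw in the overlap estimate.
#' @param seed integer seed.
#' @param labels length-2 range names.
#' @return A tibble, one row per direction x alpha x axis set.
#' @export
overlap3d_table <- function(scores1, scores2, alphas = c(0.95, 0.99),
                            n_draws = 10000, nprob = 1000, seed = 1,
                            labels = c("A", "B")) {
  h1 <- hull_niche(scores1, k = 3)
  h2 <- hull_niche(scores2, k = 3)
  hv <- hull_overlap(h1, h2, seed = seed)
  e1 <- posterior_niche(scores1, n_draws = n_draws, seed = seed)
  e2 <- posterior_niche(scores2, n_draws = n_draws, seed = seed + 1)
  axis_sets <- c(list(1:3), as.list(1:3))
  axis_names <- c("PC1+PC2+PC3", "PC1", "PC2", "PC3")
  dirs <- list(list(from = 1, a = e1, b = e2,
                    cmp = paste(labels[1], labels[2], sep = "-"),
                    hull_pct = hv$pct_a_in_b, vol = h1$volume),
               list(from = 2, a = e2, b = e1,
                    cmp = paste(labels[2], labels[1], sep = "-"),
                    hull_pct = hv$pct_b_in_a, vol = h2$volume))
  purrr::map_dfr(dirs, function(d) {
    purrr::map_dfr(alphas, function(al) {
      purrr::map_dfr(seq_along(axis_sets), function(ai) {
        ov <- ellipsoid_overlap(d$a, d$b, alpha = al, nprob = nprob,
                                seed = seed + 13 * ai, axes = axis_sets[[ai]])
        tibble::tibble(
          comparison = d$cmp, alpha = al, axes = axis_names[ai],
          hull_pct_overlap = ifelse(ai == 1, d$hull_pct, NA_real_),
          cpv = ifelse(ai == 1, d$vol, NA_real_),
          shared_cpv = ifelse(ai == 1, hv$shared_volume, NA_real_),
          ellipsoid_pct_mean = 100 * ov$mean,
          ellipsoid_pct_lo = 100 * ov$ci[1],
          ellipsoid_pct_hi = 100 * ov$ci[2])
      })
    })
  })
}
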