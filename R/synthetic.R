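#' Virtual species with a Gaussian climatic niche
#'
#' A virtual species is defined directly in environmental space by a
#' multivariate-normal suitability surface: suitability at environment `x` is
#' `exp(-0.5 * (x - mu)' Sigma^-1 (x - mu))`, scaled by `detection_scale`.
#' Because the niche is analytically known, every downstream overlap or
#' distribution estimate can be checked against ground truth.
#'
#' @param niche_mean numeric vector, niche optimum in environment units.
#' @param niche_cov symmetric positive-definite covariance matrix giving the
#'   niche breadth along and across environmental axes.
#' @param detection_scale multiplier in (0, 1] applied to suitability.
#' @param label free-text species/ecotype label.
#' @return An object of class `virtual_species`.
#' @export
virtual_species <- function(niche_mean, niche_cov,
                            detection_scale = 1, label = "virtual") {
  niche_mean <- as.numeric(niche_mean)
  niche_cov <- as.matrix(niche_cov)
  k <- length(niche_mean)
  if (!all(dim(niche_cov) == k)) {
    stop("`niche_cov` must be ", k, " x ", k, call. = FALSE)
  }
  if (max(abs(niche_cov - t(niche_cov))) > 1e-8) {
    stop("`niche_cov` must be symmetric", call. = FALSE)
  }
  ev <- eigen(niche_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("`niche_cov` must be positive definite", call. = FALSE)
  if (detection_scale <= 0 || detection_scale > 1) {
    stop("`detection_scale` must be in (0, 1]", call. = FALSE)
  }
  structure(list(niche_mean = niche_mean, niche_cov = niche_cov,
                 detection_scale = detection_scale, label = label),
            class = "virtual_species")
}

#' Specification of a synthetic landscape
#'
#' Describes a square-celled grid of spatially autocorrelated environmental
#' layers. Layers are built by smoothing white noise with a Gaussian kernel
#' (standard deviation `autocorr_range` map units), standardized to mean 0
#' and unit variance, and mixed so their cross-layer correlation matrix is
#' approximately `inter_layer_corr`.
#'
#' @param n_rows,n_cols grid size in cells (at least 10 each).
#' @param cell_size cell side length in map units.
#' @param n_layers number of environmental layers.
#' @param autocorr_range smoothing-kernel standard deviation in map units
#'   (larger = smoother landscapes); must be positive.
#' @param inter_layer_corr `n_layers` x `n_layers` correlation matrix.
#' @param seed integer seed making the landscape reproducible.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(n_rows, n_cols, cell_size = 1, n_layers = 2,
                           autocorr_range = 5 * cell_size,
                           inter_layer_corr = diag(n_layers), seed = 1) {
  if (n_rows < 10 || n_cols < 10) {
    stop("`n_rows` and `n_cols` must be >= 10", call. = FALSE)
  }
  if (autocorr_range <= 0) stop("`autocorr_range` must be > 0", call. = FALSE)
  R <- as.matrix(inter_layer_corr)
  if (!all(dim(R) == n_layers) || max(abs(R - t(R))) > 1e-8 ||
      max(abs(diag(R) - 1)) > 1e-8) {
    stop("`inter_layer_corr` must be a symmetric correlation matrix with ",
         "unit diagonal", call. = FALSE)
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-12) {
    stop("`inter_layer_corr` is not positive definite", call. = FALSE)
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, n_layers = as.integer(n_layers),
                 autocorr_range = autocorr_range, inter_layer_corr = R,
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

# Smoothed standard-normal random field on an (nr x nc) grid.
# sigma_cells is the Gaussian smoothing sd in cell units; values are
# standardized to mean 0, sd 1 after smoothing.
smooth_field <- function(nr, nc, sigma_cells) {
  half <- max(1L, ceiling(3 * sigma_cells))
  if (sigma_cells < 1e-8) {
    f <- matrix(stats::rnorm(nr * nc), nr, nc)
    return((f - mean(f)) / stats::sd(f))
  }
  kern <- stats::dnorm(seq(-half, half), sd = sigma_cells)
  kern <- kern / sum(kern)
  big <- matrix(stats::rnorm((nr + 2 * half) * (nc + 2 * half)),
                nr + 2 * half, nc + 2 * half)
  big <- apply(big, 2, function(col) stats::filter(col, kern, sides = 2))
  big <- t(apply(big, 1, function(row) stats::filter(row, kern, sides = 2)))
  f <- big[half + seq_len(nr), half + seq_len(nc)]
  (f - mean(f)) / stats::sd(f)
}

#' Generate a synthetic environmental landscape
#'
#' Realizes the random landscape described by a [landscape_spec()]: each
#' layer is a kernel-smoothed Gaussian noise field (mean 0, sd 1) and the
#' layers are linearly mixed so that their correlation matrix approaches
#' `spec$inter_layer_corr`. Deterministic given `spec$seed`.
#'
#' @param spec a [landscape_spec()].
#' @return An [env_stack()] with `spec$n_layers` layers.
#' @export
make_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(spec$seed)
  sigma_cells <- spec$autocorr_range / spec$cell_size
  Z <- vapply(seq_len(spec$n_layers), function(j) {
    as.vector(t(smooth_field(spec$n_rows, spec$n_cols, sigma_cells)))
  }, numeric(spec$n_rows * spec$n_cols))
  X <- Z %*% chol(spec$inter_layer_corr)
  env_stack(X, nrow = spec$n_rows, ncol = spec$n_cols, xmin = 0, ymin = 0,
            cellsize = spec$cell_size, crs = "projected",
            layers = paste0("env", seq_len(spec$n_layers)))
}

# Gaussian suitability of environment rows `X` (cells x layers) for `sp`.
gaussian_suitability <- function(sp, X) {
  d <- sweep(as.matrix(X), 2, sp$niche_mean)
  Q <- chol2inv(chol(sp$niche_cov))
  s <- exp(-0.5 * rowSums((d %*% Q) * d)) * sp$detection_scale
  s[!stats::complete.cases(X)] <- 0
  s
}

#' Sample occurrence records of a virtual species
#'
#' Draws `n` distinct cells (without replacement) with probability
#' proportional to the species' Gaussian suitability of each cell's
#' environment, restricted to `region_mask`. Records are placed at cell
#' centers, so downstream per-pixel deduplication is exercised meaningfully.
#'
#' @param sp a [virtual_species()].
#' @param stack an [env_stack()] whose layers match the niche dimension.
#' @param n number of occurrence records to draw.
#' @param region_mask logical vector over cells (TRUE = available), or NULL
#'   for the whole grid.
#' @param seed integer seed.
#' @param range_label,variety_label labels attached to the records.
#' @return An occurrence tibble (`id`, `x`, `y`, `range_label`,
#'   `variety_label`) with a `crs` attribute; see [occurrence_set()].
#' @export
sample_occurrences <- function(sp, stack, n, region_mask = NULL, seed = 1,
                               range_label = "A", variety_label = "type") {
  stopifnot(inherits(sp, "virtual_species"), inherits(stack, "env_stack"))
  if (length(sp$niche_mean) != n_layers(stack)) {
    stop("niche dimension (", length(sp$niche_mean),
         ") does not match the number of layers (", n_layers(stack), ")",
         call. = FALSE)
  }
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (is.null(region_mask)) region_mask <- rep(TRUE, n_cells(stack))
  suit <- gaussian_suitability(sp, stack$values)
  ok <- which(region_mask & suit > 0)
  if (length(ok) < n) {
    stop("mask has only ", length(ok),
         " positive-suitability cells but n = ", n, call. = FALSE)
  }
  set.seed(seed)
  cells <- ok[sample.int(length(ok), n, prob = suit[ok])]
  xy <- xy_from_cell(stack, cells)
  occurrence_set(x = xy$x, y = xy$y, range_label = range_label,
                 variety_label = variety_label, crs = stack$crs)
}

#' Perturb a stack into a past-scenario ("paleo") stack
#'
#' Produces a stack on the same grid whose layer `i` equals the original
#' layer plus a constant `shift[i]` plus a spatially autocorrelated noise
#' field with per-cell standard deviation `smooth_noise_sd[i]`. Emulates an
#' alternative climate scenario with the same geography.
#'
#' @param stack an [env_stack()].
#' @param shift numeric vector, one additive offset per layer.
#' @param smooth_noise_sd per-layer noise standard deviation (recycled);
#'   0 adds no noise.
#' @param autocorr_range smoothing range of the noise field in map units.
#' @param seed integer seed.
#' @return An [env_stack()] on the same grid.
#' @export
make_paleo_stack <- function(stack, shift, smooth_noise_sd = 0,
                             autocorr_range = 3 * stack$cellsize, seed = 1) {
  stopifnot(inherits(stack, "env_stack"))
  if (length(shift) != n_layers(stack)) {
    stop("`shift` must have one entry per layer (", n_layers(stack), ")",
         call. = FALSE)
  }
  smooth_noise_sd <- rep_len(smooth_noise_sd, n_layers(stack))
  set.seed(seed)
  out <- stack
  for (j in seq_len(n_layers(stack))) {
    noise <- 0
    if (smooth_noise_sd[j] > 0) {
      f <- smooth_field(stack$nrow, stack$ncol,
                        autocorr_range / stack$cellsize)
      noise <- as.vector(t(f)) * smooth_noise_sd[j]
    }
    out$values[, j] <- stack$values[, j] + shift[j] + noise
  }
  out
}

#' Analytic niche-region overlap between two Gaussian niches
#'
#' Ground-truth counterpart of the estimated niche-region overlap: the
#' probability that a draw from species `a`'s niche distribution falls
#' inside the `alpha`-probability ellipsoid of species `b`'s. Computed in
#' closed form (normal CDF) in one dimension and by Monte-Carlo integration
#' otherwise.
#'
#' @param a,b [virtual_species()] of the same dimension.
#' @param alpha niche-region size in (0, 1).
#' @param n_mc Monte-Carlo sample size (k > 1 only).
#' @param seed integer seed for the Monte-Carlo draw.
#' @return Overlap fraction in \[0, 1\].
#' @export
analytic_overlap <- function(a, b, alpha = 0.95, n_mc = 1e6, seed = 1) {
  stopifnot(inherits(a, "virtual_species"), inherits(b, "virtual_species"))
  k <- length(a$niche_mean)
  if (length(b$niche_mean) != k) stop("dimension mismatch", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (k == 1) {
    z <- sqrt(stats::qchisq(alpha, 1))
    sa <- sqrt(a$niche_cov[1, 1]); sb <- sqrt(b$niche_cov[1, 1])
    return(stats::pnorm((b$niche_mean - a$niche_mean + z * sb) / sa) -
             stats::pnorm((b$niche_mean - a$niche_mean - z * sb) / sa))
  }
  set.seed(seed)
  X <- MASS::mvrnorm(n_mc, a$niche_mean, a$niche_cov)
  d <- sweep(X, 2, b$niche_mean)
  Q <- chol2inv(chol(b$niche_cov))
  mean(rowSums((d %*% Q) * d) <= stats::qchisq(alpha, k))
}

#' Analytic Schoener's D between two Gaussian niches
#'
#' Brute-force integral of `1 - 0.5 * sum(|f_a - f_b|)` for the two
#' normalized Gaussian niche densities, evaluated on a fine rectangular
#' grid covering both niches. Serves as the ground truth against which the
#' kernel-density occupancy estimate of D is validated.
#'
#' @param a,b two-dimensional [virtual_species()].
#' @param n_grid grid resolution per axis for the numerical integral.
#' @param span half-width of the integration box in niche standard
#'   deviations beyond each niche mean.
#' @return D in \[0, 1\].
#' @export
analytic_schoener_d <- function(a, b, n_grid = 400, span = 6) {
  k <- length(a$niche_mean)
  stopifnot(k == 2, length(b$niche_mean) == 2)
  sds <- sqrt(rbind(diag(a$niche_cov), diag(b$niche_cov)))
  lo <- pmin(a$niche_mean - span * sds[1, ], b$niche_mean - span * sds[2, ])
  hi <- pmax(a$niche_mean + span * sds[1, ], b$niche_mean + span * sds[2, ])
  xg <- seq(lo[1], hi[1], length.out = n_grid)
  yg <- seq(lo[2], hi[2], length.out = n_grid)
  grid <- as.matrix(expand.grid(x = xg, y = yg))
  fa <- gaussian_suitability(a, grid); fa <- fa / sum(fa)
  fb <- gaussian_suitability(b, grid); fb <- fb / sum(fb)
  1 - 0.5 * sum(abs(fa - fb))
}
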