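#' Principal component analysis of background climates
#'
#' Fits a PCA on the standardized (centered/scaled) cell values of one or
#' more background stacks pooled together — the common environmental-space
#' calibration used by all 2-D and 3-D niche comparisons. Components are
#' ordered by decreasing explained variance, and each component's sign is
#' fixed so that its largest-magnitude loading is positive.
#'
#' @param stacks an [env_stack()] or a list of stacks sharing layer names.
#' @param masks optional logical cell mask (or list of masks, one per
#'   stack) restricting which cells enter the calibration.
#' @return An `espace_model` with fields `layer_names`, `center`, `scale`,
#'   `loadings` (layers x components, orthonormal columns) and `explained`
#'   (variance fractions).
#' @export
fit_pca <- function(stacks, masks = NULL) {
  if (inherits(stacks, "env_stack")) stacks <- list(stacks)
  if (!is.null(masks) && is.logical(masks)) masks <- list(masks)
  vals <- purrr::map2(stacks, seq_along(stacks), function(s, i) {
    v <- s$values
    if (!is.null(masks)) v <- v[masks[[i]], , drop = FALSE]
    v[stats::complete.cases(v), , drop = FALSE]
  })
  X <- do.call(rbind, vals)
  if (ncol(X) < 2) stop("need >= 2 layers", call. = FALSE)
  if (nrow(X) <= ncol(X)) {
    stop("pooled background has too few cells", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant layer(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  structure(
    list(layer_names = colnames(X), center = pc$center, scale = pc$scale,
         loadings = rot, explained = pc$sdev^2 / sum(pc$sdev^2)),
    class = "espace_model")
}

#' @export
print.espace_model <- function(x, ...) {
  cat("<espace_model> ", length(x$layer_names), " layers -> ",
      ncol(x$loadings), " components\n", sep = "")
  cat("  explained:",
      paste0(round(100 * x$explained, 1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.espace_model <- function(x, ...) {
  tibble::tibble(component = colnames(x$loadings),
                 explained = x$explained,
                 cumulative = cumsum(x$explained))
}

#' Project environments onto principal components
#'
#' Standardizes raw layer values by the model's background center/scale and
#' multiplies by the loadings. A data frame of environment values returns a
#' tibble of scores; an [env_stack()] returns a stack of PC layers (used
#' downstream as SDM predictors).
#'
#' @param model an `espace_model` from [fit_pca()].
#' @param x a data frame with the model's layer columns, or an `env_stack`.
#' @return Score tibble (columns `PC1`, `PC2`, ...) or PC `env_stack`.
#' @export
project_espace <- function(model, x) {
  stopifnot(inherits(model, "espace_model"))
  if (inherits(x, "env_stack")) {
    miss <- setdiff(model$layer_names, layer_names(x))
    if (length(miss) > 0) {
      stop("missing layer(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    sc <- scale(x$values[, model$layer_names, drop = FALSE],
                center = model$center, scale = model$scale) %*% model$loadings
    out <- x
    out$values <- sc
    colnames(out$values) <- colnames(model$loadings)
    return(out)
  }
  x <- as.data.frame(x)
  miss <- setdiff(model$layer_names, names(x))
  if (length(miss) > 0) {
    stop("missing layer(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  sc <- scale(as.matrix(x[, model$layer_names, drop = FALSE]),
              center = model$center, scale = model$scale) %*% model$loadings
  tibble::as_tibble(as.data.frame(sc))
}

#' PC scores of occurrence records
#'
#' Convenience wrapper: extracts the stack's layer values at the occurrence
#' coordinates and projects them with [project_espace()]. Records off the
#' grid are dropped.
#'
#' @param model an `espace_model`.
#' @param occ an occurrence tibble.
#' @param stack the [env_stack()] holding the raw layers.
#' @return A tibble of PC scores, one row per on-grid record.
#' @export
espace_scores <- function(model, occ, stack) {
  env <- extract_env(stack, occ)[, model$layer_names, drop = FALSE]
  project_espace(model, env[stats::complete.cases(env), , drop = FALSE])
}

# Kernel density of 2-D points evaluated on the grid cell centers,
# separable Gaussian kernel. Returns an R x R matrix (x index = rows).
# Values below `flush` * max are flushed to exact zero so occupied /
# unoccupied supports are well defined.
kde_on_grid <- function(pts, xg, yg, hx, hy, flush = 1e-8) {
  Ax <- outer(xg, pts[, 1], function(g, p) stats::dnorm(g - p, sd = hx))
  Ay <- outer(yg, pts[, 2], function(g, p) stats::dnorm(g - p, sd = hy))
  d <- Ax %*% t(Ay)
  d[d < flush * max(d)] <- 0
  d
}

silverman_bw <- function(v) {
  bw <- tryCatch(stats::bw.nrd(v), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) {
    stop("singular bandwidth: scores have (near-)zero spread on one axis",
         call. = FALSE)
  }
  bw
}

#' Gridded kernel-density occupancy of an environmental space
#'
#' The substrate of the 2-D overlap statistics: occurrence and background
#' scores on the first two PCs are smoothed with a Gaussian kernel onto an
#' `R` x `R` grid spanning the background envelope (plus a margin).
#' Occurrence density `o` is corrected by background availability `e` to
#' give the occupancy `z = (o/e)/max(o/e)` on cells with `e > 0` (zero
#' elsewhere); `Z` is `z` normalized to sum to one. An uncorrected variant
#' `z_uncor = o/max(o)` is kept alongside.
#'
#' @param scores_occ two-column matrix/data frame of occurrence scores
#'   (at least 5 rows).
#' @param scores_bg two-column matrix/data frame of background scores.
#' @param R grid cells per axis (>= 10; 100 by default).
#' @param bandwidth numeric length-2 kernel sd per axis, or `NULL` for the
#'   normal-reference (Silverman) rule computed from the occurrence scores.
#' @param pad fractional margin added to the background envelope per axis.
#' @param axis_ranges optional list `(x = c(min,max), y = c(min,max))`
#'   overriding the grid extent (used to put two ranges on one grid).
#' @param e_support relative availability cutoff: cells whose background
#'   density falls below `e_support * max(e)` are treated as outside the
#'   available environment (`e = 0`), keeping the o/e ratio away from
#'   vanishing-availability fringes.
#' @return An `occupancy_grid` with fields `R`, `x_grid`, `y_grid`, `o`,
#'   `e`, `z`, `z_uncor`, `Z`, `Z_uncor`, `bandwidth`, `axis_ranges`.
#' @export
occupancy_grid <- function(scores_occ, scores_bg, R = 100, bandwidth = NULL,
                           pad = 0.05, axis_ranges = NULL,
                           e_support = 1e-4) {
  so <- as.matrix(scores_occ)[, 1:2, drop = FALSE]
  sb <- as.matrix(scores_bg)[, 1:2, drop = FALSE]
  if (nrow(so) < 5) stop("need >= 5 occurrence scores", call. = FALSE)
  if (R < 10) stop("R must be >= 10", call. = FALSE)
  if (is.null(axis_ranges)) {
    sp <- apply(sb, 2, range)
    margin <- pad * (sp[2, ] - sp[1, ])
    axis_ranges <- list(x = c(sp[1, 1] - margin[1], sp[2, 1] + margin[1]),
                        y = c(sp[1, 2] - margin[2], sp[2, 2] + margin[2]))
  }
  xg <- seq(axis_ranges$x[1], axis_ranges$x[2], length.out = R)
  yg <- seq(axis_ranges$y[1], axis_ranges$y[2], length.out = R)
  if (is.null(bandwidth)) {
    bandwidth <- c(silverman_bw(so[, 1]), silverman_bw(so[, 2]))
  }
  if (any(!is.finite(bandwidth)) || any(bandwidth <= 0)) {
    stop("singular bandwidth", call. = FALSE)
  }
  bw_bg <- c(silverman_bw(sb[, 1]), silverman_bw(sb[, 2]))
  o <- kde_on_grid(so, xg, yg, bandwidth[1], bandwidth[2])
  e <- kde_on_grid(sb, xg, yg, bw_bg[1], bw_bg[2])
  e[e < e_support * max(e)] <- 0
  z <- matrix(0, R, R)
  pos <- e > 0
  z[pos] <- o[pos] / e[pos]
  if (max(z) > 0) z <- z / max(z)
  if (sum(z) == 0) {
    stop("occurrences fall entirely outside the background support",
         call. = FALSE)
  }
  z_uncor <- if (max(o) > 0) o / max(o) else o
  structure(
    list(R = as.integer(R), x_grid = xg, y_grid = yg, o = o, e = e,
         z = z, z_uncor = z_uncor,
         Z = z / sum(z), Z_uncor = z_uncor / sum(z_uncor),
         bandwidth = bandwidth, axis_ranges = axis_ranges),
    class = "occupancy_grid")
}

# low-level constructor used by tests and by the permutation machinery
new_occupancy_grid <- function(o, e, x_grid, y_grid, bandwidth = c(NA, NA)) {
  R <- length(x_grid)
  z <- matrix(0, nrow(o), ncol(o))
  pos <- e > 0
  z[pos] <- o[pos] / e[pos]
  if (max(z) > 0) z <- z / max(z)
  z_uncor <- if (max(o) > 0) o / max(o) else o
  norm1 <- function(m) if (sum(m) > 0) m / sum(m) else m
  structure(
    list(R = as.integer(R), x_grid = x_grid, y_grid = y_grid, o = o, e = e,
         z = z, z_uncor = z_uncor,
         Z = norm1(z), Z_uncor = norm1(z_uncor),
         bandwidth = bandwidth,
         axis_ranges = list(x = range(x_grid), y = range(y_grid))),
    class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat("<occupancy_grid> ", x$R, " x ", x$R, " cells, bandwidth (",
      paste(signif(x$bandwidth, 3), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.occupancy_grid <- function(object, what = c("z", "Z", "o", "e"),
                                    ...) {
  what <- match.arg(what)
  df <- tidyr::expand_grid(xi = seq_len(object$R), yi = seq_len(object$R))
  df$x <- object$x_grid[df$xi]
  df$y <- object$y_grid[df$yi]
  df$value <- object[[what]][cbind(df$xi, df$yi)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::labs(x = "PC1", y = "PC2")
}
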