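#' Feature construction for the maximum-entropy model
#'
#' Expands raw predictors into the classical feature classes: linear (`l`,
#' x), quadratic (`q`, x^2), product (`p`, all pairwise products), hinge
#' (`h`, forward and reverse ramps at quantile knots) and threshold (`t`,
#' step functions at the same knots). Features are min-max scaled to
#' \[0, 1\] using the calibration background; features constant over the
#' background are dropped.
#'
#' @param bg_values cells x predictors matrix/data frame of background
#'   environments (defines knots and scaling).
#' @param classes character vector, subset of `c("l","q","p","h","t")`, or
#'   a single string such as `"lqp"`.
#' @param n_knots knots per predictor for hinge/threshold features,
#'   placed at evenly spaced quantiles of the background.
#' @return A `feature_set`.
#' @export
build_features <- function(bg_values, classes, n_knots = 10) {
  X <- as.matrix(bg_values)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(classes) == 1 && nchar(classes[1]) > 1) {
    classes <- strsplit(classes, "")[[1]]
  }
  classes <- unique(classes)
  bad <- setdiff(classes, c("l", "q", "p", "h", "t"))
  if (length(bad) > 0) stop("unknown feature class(es): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  if (length(classes) == 0) stop("`classes` must be non-empty", call. = FALSE)
  if ("p" %in% classes && ncol(X) < 2) {
    stop("product features need >= 2 predictors", call. = FALSE)
  }
  vars <- colnames(X)
  defs <- list()
  add <- function(type, v1, v2 = NA_character_, knot = NA_real_) {
    defs[[length(defs) + 1]] <<- tibble::tibble(
      type = type, var1 = v1, var2 = v2, knot = knot)
  }
  if ("l" %in% classes) for (v in vars) add("l", v)
  if ("q" %in% classes) for (v in vars) add("q", v)
  if ("p" %in% classes) {
    for (i in seq_len(ncol(X) - 1)) for (j in seq(i + 1, ncol(X))) {
      add("p", vars[i], vars[j])
    }
  }
  if (any(c("h", "t") %in% classes)) {
    probs <- seq(0, 1, length.out = n_knots + 2)[-c(1, n_knots + 2)]
    for (v in vars) {
      knots <- unique(stats::quantile(X[, v], probs, names = FALSE))
      for (kn in knots) {
        if ("h" %in% classes) { add("hf", v, knot = kn); add("hr", v, knot = kn) }
        if ("t" %in% classes) add("t", v, knot = kn)
      }
    }
  }
  defs <- dplyr::bind_rows(defs)
  defs$name <- paste0(defs$type, "_", defs$var1,
                      ifelse(is.na(defs$var2), "", paste0(".", defs$var2)),
                      ifelse(is.na(defs$knot), "",
                             paste0("@", signif(defs$knot, 4))))
  fs <- structure(list(classes = sort(classes), predictor_names = vars,
                       defs = defs, n_knots = n_knots,
                       f_min = NULL, f_max = NULL),
                  class = "feature_set")
  raw <- featurize_raw(fs, X)
  fs$f_min <- apply(raw, 2, min)
  fs$f_max <- apply(raw, 2, max)
  keep <- fs$f_max > fs$f_min
  fs$defs <- fs$defs[keep, , drop = FALSE]
  fs$f_min <- fs$f_min[keep]
  fs$f_max <- fs$f_max[keep]
  fs
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> classes {", paste(x$classes, collapse = ","), "}, ",
      nrow(x$defs), " features over ",
      length(x$predictor_names), " predictor(s)\n", sep = "")
  invisible(x)
}

featurize_raw <- function(fs, X) {
  X <- as.matrix(X)
  out <- matrix(NA_real_, nrow(X), nrow(fs$defs),
                dimnames = list(NULL, fs$defs$name))
  for (j in seq_len(nrow(fs$defs))) {
    d <- fs$defs[j, ]
    v <- X[, d$var1]
    out[, j] <- switch(d$type,
      l = v,
      q = v^2,
      p = v * X[, d$var2],
      hf = pmax(0, v - d$knot),
      hr = pmax(0, d$knot - v),
      t = as.numeric(v > d$knot))
  }
  out
}

#' Evaluate a feature set (scaled to the background \[0, 1\] range)
#'
#' @param fs a `feature_set`.
#' @param X matrix/data frame with the predictor columns.
#' @return Numeric matrix, rows matching `X`.
#' @export
featurize <- function(fs, X) {
  X <- as.matrix(X)
  raw <- featurize_raw(fs, X[, fs$predictor_names, drop = FALSE])
  sweep(sweep(raw, 2, fs$f_min), 2, fs$f_max - fs$f_min, `/`)
}

# per-class regularization constants, interpolated over the presence
# sample size (approximation of the canonical per-class defaults)
tau_class <- function(type, n) {
  tab <- switch(type,
    l = , q = cbind(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
    p = cbind(c(0, 10, 17, 30, 100), c(2.2, 1.6, 0.5, 0.25, 0.05)),
    hf = , hr = cbind(c(0, 1), c(0.5, 0.5)),
    t = cbind(c(0, 100), c(2, 1)))
  stats::approx(tab[, 1], tab[, 2], xout = n, rule = 2)$y
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' Fit the L1-regularized maximum-entropy suitability model
#'
#' Finds coefficients maximizing the mean presence score minus the log
#' partition function over the calibration background, minus a per-feature
#' L1 penalty `lambda_j = rm * tau(class_j, n) * sd_j / sqrt(n)` with `n`
#' the presence count, `tau` a tabulated per-class constant and `sd_j` the
#' feature's standard deviation at the presences. The problem is convex
#' and solved by accelerated proximal gradient descent with backtracking;
#' the fit is deterministic.
#'
#' @param presence cells x predictors table of presence environments
#'   (>= 10 rows).
#' @param background cells x predictors table of calibration-background
#'   environments (should contain the presence cells).
#' @param features a [build_features()] `feature_set`.
#' @param rm regularization multiplier (> 0).
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return A `maxent_model` with coefficients, normalizer, entropy and
#'   calibration ranges.
#' @export
fit_maxent <- function(presence, background, features, rm = 1,
                       tol = 1e-7, max_iter = 5000) {
  stopifnot(inherits(features, "feature_set"))
  if (rm <= 0) stop("`rm` must be > 0", call. = FALSE)
  Xp <- as.matrix(presence)[, features$predictor_names, drop = FALSE]
  Xb <- as.matrix(background)[, features$predictor_names, drop = FALSE]
  np <- nrow(Xp)
  if (np < 10) stop("need >= 10 presences", call. = FALSE)
  Hp <- featurize(features, Xp)
  Hb <- featurize(features, Xb)
  J <- ncol(Hp)
  s <- apply(Hp, 2, stats::sd)
  s_bg <- apply(Hb, 2, stats::sd)
  s[s == 0] <- s_bg[s == 0]
  s[s == 0] <- mean(s[s > 0])
  tau <- vapply(seq_len(J), function(j) tau_class(features$defs$type[j], np),
                numeric(1))
  lambda <- pmax(rm * tau * s / sqrt(np), 1e-8)

  mean_hp <- colMeans(Hp)
  fsmooth <- function(beta) {
    -sum(mean_hp * beta) + logsumexp(drop(Hb %*% beta))
  }
  grad <- function(beta) {
    eta <- drop(Hb %*% beta)
    w <- exp(eta - logsumexp(eta))
    -mean_hp + drop(crossprod(Hb, w))
  }
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

  # stationarity residual of the L1 subgradient condition at beta
  kkt_violation <- function(beta, g) {
    v <- abs(g + lambda * sign(beta))
    v[beta == 0] <- pmax(abs(g[beta == 0]) - lambda[beta == 0], 0)
    max(v)
  }

  beta <- numeric(J)
  yv <- beta
  tk <- 1
  L <- 1
  converged <- FALSE
  it <- 0
  obj_old <- fsmooth(beta) + sum(lambda * abs(beta))
  while (it < max_iter) {
    it <- it + 1
    g <- grad(yv)
    fy <- fsmooth(yv)
    repeat {
      cand <- soft(yv - g / L, lambda / L)
      dlt <- cand - yv
      if (fsmooth(cand) <= fy + sum(g * dlt) + L / 2 * sum(dlt^2) + 1e-12) break
      L <- L * 2
    }
    beta_new <- cand
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    yv <- beta_new + (tk - 1) / tk_new * (beta_new - beta)
    beta <- beta_new
    tk <- tk_new
    L <- max(L / 2, 1e-4)
    if (it %% 10 == 0 || it == max_iter) {
      gb <- grad(beta)
      obj_new <- fsmooth(beta) + sum(lambda * abs(beta))
      if (kkt_violation(beta, gb) <= 1e-6 &&
          abs(obj_new - obj_old) <= tol * (1 + abs(obj_old))) {
        converged <- TRUE
        obj_old <- obj_new
        break
      }
      obj_old <- obj_new
    }
  }
  if (!converged) {
    stop("maximum-entropy fit did not converge after ", max_iter,
         " iterations (last objective ", signif(obj_old, 8), ", rm = ", rm,
         ", ", J, " features)", call. = FALSE)
  }
  obj_old <- fsmooth(beta) + sum(lambda * abs(beta))
  eta_b <- drop(Hb %*% beta)
  logZ <- logsumexp(eta_b)
  w <- exp(eta_b - logZ)
  entropy <- -sum(w[w > 0] * log(w[w > 0]))
  structure(
    list(beta = stats::setNames(beta, colnames(Hp)), features = features,
         rm = rm, lambda = lambda, log_partition = logZ, entropy = entropy,
         calibration_range = apply(Xb, 2, range),
         n_presence = np, n_background = nrow(Xb),
         objective = obj_old, n_iter = it, converged = converged),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat("<maxent_model> rm = ", x$rm, ", classes {",
      paste(x$features$classes, collapse = ","), "}, ",
      sum(x$beta != 0), "/", length(x$beta), " nonzero coefficients\n",
      sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.maxent_model <- function(x, ...) {
  tibble::tibble(feature = names(x$beta), type = x$features$defs$type,
                 estimate = unname(x$beta), lambda = x$lambda)
}

#' @exportS3Method generics::glance
glance.maxent_model <- function(x, ...) {
  tibble::tibble(rm = x$rm, n_presence = x$n_presence,
                 n_background = x$n_background,
                 n_parameters = sum(x$beta != 0),
                 entropy = x$entropy, objective = x$objective,
                 iterations = x$n_iter, converged = x$converged)
}

#' Predict suitability from a fitted maximum-entropy model
#'
#' `raw` output is the exponential-model probability re-normalized over
#' the (unmasked) prediction cells, summing to one; `cloglog` is the
#' bounded transform `1 - exp(-exp(H) * p_cal)` of the calibration-
#' normalized probability `p_cal`, with `H` the calibration entropy. Cells
#' whose raw predictor values fall outside the calibration range are
#' masked (`extrapolation = "mask"`, the conservative no-extrapolation
#' default) or truncated to the range boundary (`"clamp"`).
#'
#' @param object a `maxent_model`.
#' @param newdata an [env_stack()] of predictor layers, or a data frame
#'   with the predictor columns.
#' @param type `"cloglog"` (default) or `"raw"`.
#' @param extrapolation `"mask"` or `"clamp"`.
#' @param ... unused.
#' @return For a stack, a `suitability_map` (an `env_stack` carrying a
#'   `suitability` layer, `NA` = masked, plus provenance); for a data
#'   frame, a numeric vector.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("cloglog", "raw"),
                                 extrapolation = c("mask", "clamp"), ...) {
  type <- match.arg(type)
  extrapolation <- match.arg(extrapolation)
  is_stack <- inherits(newdata, "env_stack")
  X <- if (is_stack) newdata$values else as.matrix(newdata)
  X <- X[, object$features$predictor_names, drop = FALSE]
  rng <- object$calibration_range
  out_of_range <- rep(FALSE, nrow(X))
  for (j in seq_len(ncol(X))) {
    out_of_range <- out_of_range |
      X[, j] < rng[1, j] | X[, j] > rng[2, j]
  }
  masked <- is.na(rowSums(X))
  if (extrapolation == "mask") {
    masked <- masked | out_of_range
  } else {
    for (j in seq_len(ncol(X))) {
      X[, j] <- pmin(pmax(X[, j], rng[1, j]), rng[2, j])
    }
  }
  suit <- rep(NA_real_, nrow(X))
  if (all(masked)) {
    warning("all prediction cells are masked", call. = FALSE)
  } else {
    H <- featurize(object$features, X[!masked, , drop = FALSE])
    eta <- drop(H %*% object$beta)
    if (type == "raw") {
      suit[!masked] <- exp(eta - logsumexp(eta))
    } else {
      p_cal <- exp(eta - object$log_partition)
      suit[!masked] <- 1 - exp(-exp(object$entropy) * p_cal)
    }
  }
  if (!is_stack) return(suit)
  map <- env_stack(matrix(suit, ncol = 1), nrow = newdata$nrow,
                   ncol = newdata$ncol, xmin = newdata$xmin,
                   ymin = newdata$ymin, cellsize = newdata$cellsize,
                   crs = newdata$crs, layers = "suitability")
  class(map) <- c("suitability_map", class(map))
  attr(map, "provenance") <- list(
    rm = object$rm, classes = object$features$classes, type = type,
    extrapolation = extrapolation, n_masked = sum(masked))
  map
}

#' @exportS3Method ggplot2::autoplot
autoplot.suitability_map <- function(object, ...) {
  plot_stack_layer(object, "suitability") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "suitability")
}
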