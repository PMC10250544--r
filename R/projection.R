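#' Transfer a model specification to a scenario stack
#'
#' Refits the maximum-entropy model on bootstrap resamples of the
#' presences and predicts each replicate on the scenario stack with the
#' no-extrapolation mask, returning the cell-wise mean suitability (and
#' keeping the per-cell standard deviation in an `sd` layer). The scenario
#' must carry the model's predictor layers (PC layers transformed by the
#' same environmental-space model as the calibration data). With
#' `replicates = 1` no resampling is done and the result equals a plain
#' prediction.
#'
#' @param presence_env presences x predictors table.
#' @param bg_env calibration-background cells x predictors table.
#' @param classes feature-class string for the model.
#' @param rm regularization multiplier.
#' @param scenario an [env_stack()] holding the predictor layers.
#' @param replicates bootstrap replicates.
#' @param seed integer seed.
#' @param summary `"mean"` (default) or `"median"` cell-wise summary.
#' @param n_knots hinge/threshold knots.
#' @return A `suitability_map` with layers `suitability` and `sd`.
#' @export
transfer <- function(presence_env, bg_env, classes, rm, scenario,
                     replicates = 30, seed = 1,
                     summary = c("mean", "median"), n_knots = 10) {
  summary <- match.arg(summary)
  stopifnot(inherits(scenario, "env_stack"))
  presence_env <- as.data.frame(presence_env)
  preds <- names(presence_env)
  miss <- setdiff(preds, layer_names(scenario))
  if (length(miss) > 0) {
    stop("scenario lacks predictor layer(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  fs <- build_features(bg_env[, preds, drop = FALSE], classes,
                       n_knots = n_knots)
  set.seed(seed)
  vals <- matrix(NA_real_, n_cells(scenario), replicates)
  n_masked <- NA_integer_
  for (r in seq_len(replicates)) {
    pres <- if (replicates == 1) presence_env else
      presence_env[sample.int(nrow(presence_env), replace = TRUE), ,
                   drop = FALSE]
    m <- fit_maxent(pres, bg_env[, preds, drop = FALSE], fs, rm = rm)
    map <- suppressWarnings(
      predict(m, stack_subset(scenario, preds), type = "cloglog",
              extrapolation = "mask"))
    vals[, r] <- map$values[, 1]
    n_masked <- attr(map, "provenance")$n_masked
  }
  agg <- if (summary == "mean") rowMeans(vals) else
    apply(vals, 1, stats::median)
  sdv <- apply(vals, 1, stats::sd)
  if (n_masked > 0.95 * n_cells(scenario)) {
    warning("scenario is almost entirely outside the calibration range (",
            n_masked, "/", n_cells(scenario), " cells masked)",
            call. = FALSE)
  }
  out <- env_stack(cbind(suitability = agg, sd = sdv),
                   nrow = scenario$nrow, ncol = scenario$ncol,
                   xmin = scenario$xmin, ymin = scenario$ymin,
                   cellsize = scenario$cellsize, crs = scenario$crs)
  class(out) <- c("suitability_map", class(out))
  attr(out, "provenance") <- list(rm = rm, classes = classes,
                                  replicates = replicates, seed = seed,
                                  summary = summary, n_masked = n_masked)
  out
}

#' Cross-model agreement ("common area") map
#'
#' Cells where both suitability maps are at or above the threshold and
#' unmasked.
#'
#' @param a,b `suitability_map`s on the same grid.
#' @param threshold suitability threshold.
#' @return List with `map` (an `env_stack` with a binary `agreement`
#'   layer) and `common_cell_count`.
#' @export
agreement_map <- function(a, b, threshold = 0.5) {
  stopifnot(inherits(a, "env_stack"), inherits(b, "env_stack"))
  if (!same_grid(a, b)) stop("grid mismatch", call. = FALSE)
  va <- a$values[, "suitability"]
  vb <- b$values[, "suitability"]
  agree <- as.numeric(!is.na(va) & !is.na(vb) & va >= threshold &
                        vb >= threshold)
  map <- env_stack(matrix(agree, ncol = 1), nrow = a$nrow, ncol = a$ncol,
                   xmin = a$xmin, ymin = a$ymin, cellsize = a$cellsize,
                   crs = a$crs, layers = "agreement")
  list(map = map, common_cell_count = sum(agree))
}

#' Four-way spread-stage classification of occurrences
#'
#' Compares the suitability an occurrence receives from a locally
#' calibrated model with the suitability from a continental model:
#' `stabilizing` when both are at or above the threshold (populations in
#' equilibrium with the environment), `adaptation` when only the local
#' model predicts it, `colonization` when only the continental model
#' does, and `sink` when neither does. Values exactly at the threshold
#' count as high. Occurrences on masked cells are `unscored`.
#'
#' @param occ occurrence tibble.
#' @param local_map,continental_map `suitability_map`s.
#' @param threshold suitability threshold (0.5 by default).
#' @return A `spread_classification` tibble: `id`, `x`, `y`,
#'   `local_suit`, `continental_suit`, `category`.
#' @export
classify_spread <- function(occ, local_map, continental_map,
                            threshold = 0.5) {
  ls <- extract_env(local_map, occ)[["suitability"]]
  cs <- extract_env(continental_map, occ)[["suitability"]]
  category <- dplyr::case_when(
    is.na(ls) | is.na(cs) ~ "unscored",
    ls >= threshold & cs >= threshold ~ "stabilizing",
    ls >= threshold & cs < threshold ~ "adaptation",
    ls < threshold & cs >= threshold ~ "colonization",
    TRUE ~ "sink")
  if (any(category == "unscored")) {
    warning(sum(category == "unscored"),
            " occurrence(s) fall on masked cells and are unscored",
            call. = FALSE)
  }
  out <- tibble::tibble(
    id = occ$id, x = occ$x, y = occ$y,
    local_suit = ls, continental_suit = cs,
    category = factor(category,
                      levels = c("sink", "stabilizing", "adaptation",
                                 "colonization", "unscored")))
  attr(out, "threshold") <- threshold
  class(out) <- c("spread_classification", class(out))
  out
}

#' Category fractions of a spread classification
#'
#' @param x a `spread_classification`.
#' @param ... unused.
#' @return A tibble with `category`, `n`, `fraction` (fractions over
#'   scored occurrences).
#' @exportS3Method generics::tidy
tidy.spread_classification <- function(x, ...) {
  scored <- x$category != "unscored"
  tab <- table(x$category)
  tibble::tibble(category = names(tab), n = as.integer(tab),
                 fraction = ifelse(names(tab) == "unscored", NA,
                                   as.integer(tab) / max(sum(scored), 1)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.spread_classification <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$category)),
                  ggplot2::aes(.data$x, .data$y,
                               color = .data$category)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::scale_color_manual(values = c(
      sink = "#d73027", stabilizing = "#1a9850", adaptation = "#fdae61",
      colonization = "#4575b4", unscored = "grey60")) +
    ggplot2::labs(x = NULL, y = NULL, color = "spread stage")
}
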