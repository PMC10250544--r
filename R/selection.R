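#' Default regularization-multiplier ladder
#'
#' `0.1` to `1` in steps of `0.1`, `2` to `6` in steps of `1`, then `8`
#' and `10` — 17 values.
#'
#' @return Numeric vector of length 17.
#' @export
rm_default <- function() c(seq(0.1, 1, by = 0.1), 2:6, 8, 10)

#' All non-empty feature-class combinations
#'
#' Every non-empty subset of the five feature classes (linear, quadratic,
#' product, hinge, threshold): 31 combinations, ordered by subset size
#' then alphabetically.
#'
#' @param classes the available classes.
#' @return Character vector of class strings (e.g. `"lqp"`).
#' @export
feature_class_subsets <- function(classes = c("l", "q", "p", "h", "t")) {
  classes <- sort(classes)
  subsets <- unlist(lapply(seq_along(classes), function(k) {
    apply(utils::combn(classes, k), 2, paste, collapse = "")
  }))
  subsets[order(nchar(subsets), subsets)]
}

#' Candidate-model grid
#'
#' Cartesian product of regularization multipliers, feature-class
#' combinations and predictor sets, in stable order. With the defaults
#' (17 x 31 x 3) this enumerates 1581 candidates.
#'
#' @param rm_values regularization multipliers.
#' @param class_subsets feature-class strings.
#' @param predictor_sets labels of predictor sets (e.g. `"PC1-4"`).
#' @return A tibble with `candidate_id`, `rm`, `classes`, `predictor_set`.
#' @export
candidate_grid <- function(rm_values = rm_default(),
                           class_subsets = feature_class_subsets(),
                           predictor_sets = "PC1-2") {
  if (length(rm_values) == 0 || length(class_subsets) == 0 ||
      length(predictor_sets) == 0) {
    stop("all grid inputs must be non-empty", call. = FALSE)
  }
  g <- tidyr::expand_grid(predictor_set = predictor_sets,
                          classes = class_subsets, rm = rm_values)
  g <- g[, c("rm", "classes", "predictor_set")]
  dplyr::mutate(g, candidate_id = dplyr::row_number(), .before = 1)
}

#' One fixed train/test split of occurrences
#'
#' A single random split reused across every candidate model, so all
#' candidates are evaluated on the same 75/25 partition.
#'
#' @param occ occurrence tibble (or any data frame; n >= 8).
#' @param train_frac training fraction.
#' @param seed integer seed.
#' @return List with `train` and `test` row subsets (a partition).
#' @export
split_occurrences <- function(occ, train_frac = 0.75, seed = 1) {
  n <- nrow(occ)
  if (n < 8) stop("need >= 8 occurrences to split", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(n, round(train_frac * n))
  list(train = occ[idx, , drop = FALSE],
       test = occ[-idx, , drop = FALSE])
}

#' Omission rate at the E-percent training threshold
#'
#' The suitability threshold is the `E`-quantile of the training-presence
#' suitabilities (the lowest `E` share of training presences is allowed to
#' be omitted); the omission rate is the share of test presences strictly
#' below that threshold.
#'
#' @param suit_train,suit_test suitability values at training and test
#'   presences.
#' @param E allowed omission fraction.
#' @return Omission rate in \[0, 1\].
#' @export
omission_rate <- function(suit_train, suit_test, E = 0.05) {
  if (length(suit_train) == 0 || length(suit_test) == 0) {
    stop("empty train/test suitabilities", call. = FALSE)
  }
  # order-statistic (type 1) quantile: the ceiling(E*n)-th smallest
  # training value, so at most an E share of training presences sits
  # strictly below the threshold
  thr <- stats::quantile(suit_train, E, names = FALSE, type = 1)
  mean(suit_test < thr)
}

#' Partial ROC AUC-ratio significance test
#'
#' Compares the model's partial area under the curve of sensitivity
#' against proportion-of-area-predicted, restricted to sensitivities at
#' least `1 - E`, with the area under the random-prediction diagonal over
#' the same interval. Ratios above 1 indicate better-than-random
#' prediction. Bootstraps over `boot_frac` resamples of the test points;
#' the p-value is the share of bootstrap ratios at or below 1.
#'
#' @param suit_bg suitability over the background/prediction cells.
#' @param suit_test suitability at test presences (>= 10).
#' @param E allowed omission fraction.
#' @param n_boot bootstrap iterations.
#' @param boot_frac fraction of test points per bootstrap resample.
#' @param seed integer seed.
#' @return A tibble row: `mean_auc_ratio`, `proc_p`, `flag`.
#' @export
partial_roc <- function(suit_bg, suit_test, E = 0.05, n_boot = 500,
                        boot_frac = 0.5, seed = 1) {
  if (length(suit_test) < 10) stop("need >= 10 test points", call. = FALSE)
  if (stats::sd(suit_bg) == 0) {
    return(tibble::tibble(mean_auc_ratio = NA_real_, proc_p = NA_real_,
                          flag = "constant suitability map"))
  }
  thresholds <- sort(unique(stats::quantile(
    suit_bg, probs = seq(0, 1, length.out = 201), names = FALSE)))
  area <- vapply(thresholds, function(th) mean(suit_bg >= th), numeric(1))
  ratio_of <- function(test) {
    sens <- vapply(thresholds, function(th) mean(test >= th), numeric(1))
    keep <- sens >= 1 - E
    if (sum(keep) < 2) return(NA_real_)
    x <- area[keep]; y <- sens[keep]
    ord <- order(x)
    x <- x[ord]; y <- y[ord]
    pauc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    pnull <- sum(diff(x) * (utils::head(x, -1) + utils::tail(x, -1)) / 2)
    if (pnull <= 0) return(NA_real_)
    pauc / pnull
  }
  set.seed(seed)
  m <- max(2, round(boot_frac * length(suit_test)))
  ratios <- vapply(seq_len(n_boot), function(b) {
    ratio_of(sample(suit_test, m, replace = TRUE))
  }, numeric(1))
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) == 0) {
    return(tibble::tibble(mean_auc_ratio = NA_real_, proc_p = NA_real_,
                          flag = "partial AUC undefined"))
  }
  tibble::tibble(mean_auc_ratio = mean(ratios),
                 proc_p = mean(ratios <= 1), flag = NA_character_)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)` with `k` the number of nonzero
#' coefficients and `n` the number of occurrences; undefined (NA) when
#' `n <= k + 1`.
#'
#' @param log_lik total log-likelihood of the occurrences.
#' @param k parameter count.
#' @param n occurrence count.
#' @return AICc value (NA when undefined).
#' @export
aicc <- function(log_lik, k, n) {
  if (n <= k + 1) return(NA_real_)
  2 * k - 2 * log_lik + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc of a fitted maximum-entropy model
#'
#' Log-likelihood of all occurrences under the raw exponential-model
#' probabilities normalized over the calibration background, with `k` the
#' count of nonzero coefficients.
#'
#' @param model a `maxent_model` fitted on all occurrences.
#' @param occ_env occurrences x predictors table.
#' @return A tibble row: `aicc`, `n_parameters`, `log_lik`, `flag`.
#' @export
aicc_maxent <- function(model, occ_env) {
  H <- featurize(model$features,
                 as.matrix(occ_env)[, model$features$predictor_names,
                                    drop = FALSE])
  eta <- drop(H %*% model$beta)
  log_lik <- sum(eta - model$log_partition)
  k <- sum(model$beta != 0)
  n <- nrow(H)
  tibble::tibble(aicc = aicc(log_lik, k, n), n_parameters = k,
                 log_lik = log_lik,
                 flag = ifelse(n <= k + 1, "n <= k + 1", NA_character_))
}

#' Evaluate a candidate grid on one occurrence set
#'
#' For every candidate: builds the feature set on the calibration
#' background, fits the model on the training presences, evaluates
#' partial ROC and omission rate on the fixed test split, refits on all
#' presences for AICc, and assembles the selection table.
#'
#' @param occ_env occurrences x predictors table (all occurrences).
#' @param bg_env calibration-background cells x predictors table.
#' @param candidates a [candidate_grid()] tibble; its `predictor_set`
#'   column is matched against names of `predictor_sets`.
#' @param predictor_sets named list mapping predictor-set label to the
#'   character vector of predictor columns to use.
#' @param train_frac,seed split passed to [split_occurrences()].
#' @param E,n_boot partial-ROC/omission settings.
#' @param n_knots hinge/threshold knots per predictor.
#' @return A `selection_table` tibble (one row per candidate).
#' @export
evaluate_candidates <- function(occ_env, bg_env, candidates,
                                predictor_sets, train_frac = 0.75,
                                seed = 1, E = 0.05, n_boot = 500,
                                n_knots = 10) {
  split <- split_occurrences(occ_env, train_frac, seed)
  rows <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    preds <- predictor_sets[[cand$predictor_set]]
    fs <- build_features(bg_env[, preds, drop = FALSE], cand$classes,
                         n_knots = n_knots)
    res <- tryCatch({
      m_train <- fit_maxent(split$train[, preds, drop = FALSE],
                            bg_env[, preds, drop = FALSE], fs, rm = cand$rm)
      s_train <- predict(m_train, split$train[, preds, drop = FALSE],
                         type = "cloglog", extrapolation = "clamp")
      s_test <- predict(m_train, split$test[, preds, drop = FALSE],
                        type = "cloglog", extrapolation = "clamp")
      s_bg <- predict(m_train, bg_env[, preds, drop = FALSE],
                      type = "cloglog", extrapolation = "clamp")
      pr <- partial_roc(s_bg, s_test, E = E, n_boot = n_boot,
                        seed = seed + i)
      m_all <- fit_maxent(occ_env[, preds, drop = FALSE],
                          bg_env[, preds, drop = FALSE], fs, rm = cand$rm)
      ac <- aicc_maxent(m_all, occ_env[, preds, drop = FALSE])
      tibble::tibble(
        mean_auc_ratio = pr$mean_auc_ratio, proc_p = pr$proc_p,
        omission_rate = omission_rate(s_train, s_test, E),
        aicc = ac$aicc, n_parameters = ac$n_parameters,
        flag = dplyr::coalesce(pr$flag, ac$flag))
    }, error = function(e) {
      tibble::tibble(mean_auc_ratio = NA_real_, proc_p = NA_real_,
                     omission_rate = NA_real_, aicc = NA_real_,
                     n_parameters = NA_integer_, flag = conditionMessage(e))
    })
    dplyr::bind_cols(cand, res)
  })
  class(rows) <- c("selection_table", class(rows))
  rows
}

#' Filter a selection table to the best candidate models
#'
#' A candidate is selected when its partial ROC is significant
#' (`proc_p < proc_alpha`), its omission rate is at most `or_max`, and its
#' AICc is within `delta_max` of the minimum. The delta-AICc baseline is
#' the minimum among candidates already passing the significance and
#' omission filters (`delta_baseline = "passing"`, the default) or among
#' all candidates (`"all"`).
#'
#' @param table a `selection_table` from [evaluate_candidates()].
#' @param proc_alpha significance level for the partial ROC p-value.
#' @param or_max maximum omission rate.
#' @param delta_max maximum delta-AICc.
#' @param delta_baseline `"passing"` or `"all"`.
#' @return The table with `delta_aicc` and logical `selected` columns.
#' @export
select_models <- function(table, proc_alpha = 0.05, or_max = 0.05,
                          delta_max = 2,
                          delta_baseline = c("passing", "all")) {
  delta_baseline <- match.arg(delta_baseline)
  if (nrow(table) == 0) stop("empty selection table", call. = FALSE)
  pass_stat <- !is.na(table$proc_p) & table$proc_p < proc_alpha &
    !is.na(table$omission_rate) & table$omission_rate <= or_max
  base_pool <- if (delta_baseline == "passing" && any(pass_stat)) {
    table$aicc[pass_stat]
  } else {
    table$aicc
  }
  base <- suppressWarnings(min(base_pool, na.rm = TRUE))
  out <- dplyr::mutate(
    table, delta_aicc = .data$aicc - base,
    selected = pass_stat & !is.na(.data$aicc) & .data$delta_aicc <= delta_max &
      .data$delta_aicc >= 0)
  if (!any(out$selected)) {
    best <- which.min(out$aicc)
    warning("no candidate passes all filters; best by AICc is candidate ",
            out$candidate_id[best], " (rm = ", out$rm[best], ", classes = ",
            out$classes[best], ")", call. = FALSE)
  }
  class(out) <- unique(c("selection_table", class(out)))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.selection_table <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$aicc))
  ggplot2::ggplot(df, ggplot2::aes(.data$rm, .data$aicc,
                                   color = .data$classes)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~predictor_set) +
    ggplot2::labs(x = "regularization multiplier", y = "AICc")
}
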