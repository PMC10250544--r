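#' Calibration-buffer mask
#'
#' Marks the cells within `radius` of any occurrence — the buffered
#' calibration region used to restrict the SDM background (500 km in the
#' workflow defaults). Distances are Euclidean map units for projected
#' stacks and great-circle km for geographic ones.
#'
#' @param stack an [env_stack()].
#' @param occ occurrence tibble.
#' @param radius buffer radius (map units or km).
#' @return Logical vector over cells.
#' @export
buffer_mask <- function(stack, occ, radius) {
  xy <- xy_from_cell(stack, seq_len(n_cells(stack)))
  if (stack$crs == "geographic") {
    dmin <- rep(Inf, n_cells(stack))
    for (i in seq_len(nrow(occ))) {
      d <- geosphere::distHaversine(cbind(xy$x, xy$y),
                                    c(occ$x[i], occ$y[i]),
                                    r = 6371000) / 1000
      dmin <- pmin(dmin, d)
    }
  } else {
    d2 <- outer(xy$x, occ$x, `-`)^2 + outer(xy$y, occ$y, `-`)^2
    dmin <- sqrt(apply(d2, 1, min))
  }
  dmin <= radius
}

stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 7919 + 104729 * stage) %% 2147483647)
}

#' Default pipeline configuration
#'
#' All stage parameters of the end-to-end workflow with their standard
#' values: a 100 x 100 environmental-space grid, 100 permutation
#' replicates, 10,000 posterior draws, niche-region sizes 0.95/0.99,
#' omission threshold E = 0.05, the 17-value regularization ladder with
#' all 31 feature-class subsets, suitability threshold 0.5, a 500-unit
#' calibration buffer, 30 bootstrap transfer replicates and a 75/25
#' train/test split.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @return A nested config list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    synthetic = list(
      landscape = list(n_rows = 100, n_cols = 100, cell_size = 1,
                       n_layers = 4, autocorr_range = 8),
      barrier = list(x = 50, gap = 6),
      species = list(
        west = list(niche_mean = c(0.5, 0.5, 0, 0), niche_sd = 0.6, n = 561),
        east = list(niche_mean = c(0.5, 0.5, 0, 0), niche_sd = 0.6, n = 201)),
      thin_dmin = 1),
    espace = list(R = 100, pad = 0.05),
    overlap2d = list(reps = 100),
    overlap3d = list(draws = 10000, nprob = 1000, alpha = c(0.95, 0.99)),
    sdm = list(rm_values = rm_default(),
               class_subsets = feature_class_subsets(),
               predictor_sets = list(`PC1-2` = c("PC1", "PC2"),
                                     `PC1-3` = c("PC1", "PC2", "PC3")),
               E = 0.05, n_boot = 500, train_frac = 0.75,
               buffer = 500, n_knots = 10),
    projection = list(replicates = 30,
                      paleo_shift = c(0.5, -0.3, 0.2, 0),
                      paleo_noise_sd = 0.2),
    spread = list(threshold = 0.5))
}

#' Desk-scale synthetic demonstration configuration
#'
#' A reduced variant of [default_config()] sized for minutes-scale runs:
#' a smaller candidate grid and fewer posterior draws, while keeping the
#' two-range virtual-species design (561 west / 201 east records) intact.
#' `niche_shift` displaces the western niche to emulate divergence; 0
#' keeps one shared niche.
#'
#' @param seed master seed.
#' @param niche_shift additive shift of the western niche mean on the
#'   first two environmental axes.
#' @return A nested config list.
#' @export
synth_demo_config <- function(seed = 1, niche_shift = 0) {
  cfg <- default_config(seed)
  cfg$synthetic$landscape <- list(n_rows = 70, n_cols = 70, cell_size = 1,
                                  n_layers = 4, autocorr_range = 6)
  cfg$synthetic$barrier <- list(x = 35, gap = 4)
  cfg$synthetic$species$west$niche_mean <-
    c(0.5 + niche_shift, 0.5 + niche_shift, 0, 0)
  cfg$overlap2d$reps <- 99
  cfg$overlap3d <- list(draws = 2000, nprob = 500, alpha = c(0.95, 0.99))
  cfg$sdm$rm_values <- c(1, 2)
  cfg$sdm$class_subsets <- c("lq", "lqp")
  cfg$sdm$predictor_sets <- list(`PC1-3` = c("PC1", "PC2", "PC3"))
  cfg$sdm$buffer <- 25
  cfg$sdm$n_boot <- 200
  cfg$projection$replicates <- 5
  cfg
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config` returns the config list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config a config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

pipeline_log <- function(dir, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(line)
  cat(line, "\n", file = file.path(dir, "pipeline.log"), append = TRUE)
}

#' Run the full niche-comparison and distribution-modelling pipeline
#'
#' Executes, on a synthetic two-range virtual-species scenario described
#' by the config: landscape and occurrence generation; occurrence
#' cleaning and the Welch climate comparison; environmental-space PCA and
#' occupancy grids; the 2-D overlap table (D, equivalency/similarity
#' tests, dynamics indices); the 3-D overlap table (convex-polyhedron and
#' Bayesian ellipsoid overlaps); candidate-model calibration and
#' selection per range and for the continental set; transfer of the
#' selected models to a perturbed past scenario with an agreement map;
#' and the four-way spread classification of the western occurrences.
#' All tables are written to `out_dir` as tab-separated text together
#' with the resolved config, seeds and a stage log; rasters are written
#' as ESRI ASCII grids. A failing stage halts with a stage-named error,
#' retaining the outputs already written.
#'
#' @param config a config list (see [default_config()]).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the main result objects.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_config(config, file.path(out_dir, "config_used.yaml"))
  master <- config$seed
  res <- list()
  stage <- function(name, expr) {
    pipeline_log(out_dir, "stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  res$stack <- stage("synthetic", {
    ls_cfg <- config$synthetic$landscape
    spec <- landscape_spec(ls_cfg$n_rows, ls_cfg$n_cols, ls_cfg$cell_size,
                           ls_cfg$n_layers, ls_cfg$autocorr_range,
                           seed = stage_seed(master, 1))
    make_landscape(spec)
  })
  stack <- res$stack
  bar <- config$synthetic$barrier
  xy <- xy_from_cell(stack, seq_len(n_cells(stack)))
  mask_w <- xy$x < bar$x - bar$gap / 2
  mask_e <- xy$x > bar$x + bar$gap / 2

  occ <- stage("occurrences", {
    spw <- config$synthetic$species$west
    spe <- config$synthetic$species$east
    sp_w <- virtual_species(spw$niche_mean,
                            diag(spw$niche_sd^2, length(spw$niche_mean)),
                            label = "west")
    sp_e <- virtual_species(spe$niche_mean,
                            diag(spe$niche_sd^2, length(spe$niche_mean)),
                            label = "east")
    list(west = sample_occurrences(sp_w, stack, spw$n, mask_w,
                                   seed = stage_seed(master, 2),
                                   range_label = "west"),
         east = sample_occurrences(sp_e, stack, spe$n, mask_e,
                                   seed = stage_seed(master, 3),
                                   range_label = "east"))
  })

  occ <- stage("prep", {
    out <- purrr::map(occ, function(o) {
      o <- dedupe_per_cell(o, stack)
      thin_min_distance(o, config$synthetic$thin_dmin,
                        seed = stage_seed(master, 4))
    })
    pipeline_log(out_dir, "records after cleaning: west ",
                 nrow(out$west), ", east ", nrow(out$east))
    write_occurrences(dplyr::bind_rows(out$west, out$east),
                      file.path(out_dir, "occurrences.tsv"))
    out
  })
  res$occurrences <- occ

  res$welch <- stage("welch", {
    w <- welch_compare(occ$west, occ$east, stack)
    readr::write_tsv(w, file.path(out_dir, "welch_climate_comparison.tsv"))
    w
  })

  es <- stage("espace", {
    model <- fit_pca(stack, mask_w | mask_e)
    list(model = model,
         bg_w = project_espace(model,
                               stack$values[mask_w, , drop = FALSE]),
         bg_e = project_espace(model,
                               stack$values[mask_e, , drop = FALSE]),
         occ_w = espace_scores(model, occ$west, stack),
         occ_e = espace_scores(model, occ$east, stack))
  })
  res$espace <- es

  res$overlap2d <- stage("overlap2d", {
    t2 <- overlap2d_table(es$occ_w[, 1:2], es$occ_e[, 1:2],
                          es$bg_w[, 1:2], es$bg_e[, 1:2],
                          R = config$espace$R, reps = config$overlap2d$reps,
                          seed = stage_seed(master, 5),
                          labels = c("west", "east"))
    readr::write_tsv(t2, file.path(out_dir, "overlap2d_table.tsv"))
    t2
  })

  res$overlap3d <- stage("overlap3d", {
    t3 <- overlap3d_table(es$occ_w[, 1:3], es$occ_e[, 1:3],
                          alphas = config$overlap3d$alpha,
                          n_draws = config$overlap3d$draws,
                          nprob = config$overlap3d$nprob,
                          seed = stage_seed(master, 6),
                          labels = c("west", "east"))
    readr::write_tsv(t3, file.path(out_dir, "overlap3d_table.tsv"))
    t3
  })

  pc_stack <- project_espace(es$model, stack)
  sdm_cfg <- config$sdm
  datasets <- stage("calibration", {
    sets <- list(
      west = list(occ = occ$west, mask = mask_w),
      east = list(occ = occ$east, mask = mask_e),
      continental = list(occ = dplyr::bind_rows(occ$west, occ$east),
                         mask = mask_w | mask_e))
    purrr::imap(sets, function(d, nm) {
      buf <- buffer_mask(stack, d$occ, sdm_cfg$buffer) & d$mask
      occ_pc <- extract_env(pc_stack, d$occ)
      occ_pc <- occ_pc[, layer_names(pc_stack), drop = FALSE]
      bg_pc <- tibble::as_tibble(pc_stack$values[buf, , drop = FALSE])
      cands <- candidate_grid(sdm_cfg$rm_values, sdm_cfg$class_subsets,
                              names(sdm_cfg$predictor_sets))
      tab <- evaluate_candidates(occ_pc, bg_pc, cands,
                                 sdm_cfg$predictor_sets,
                                 train_frac = sdm_cfg$train_frac,
                                 seed = stage_seed(master, 7),
                                 E = sdm_cfg$E, n_boot = sdm_cfg$n_boot,
                                 n_knots = sdm_cfg$n_knots)
      tab <- select_models(tab)
      readr::write_tsv(tab, file.path(out_dir,
                                      paste0("selection_", nm, ".tsv")))
      best <- dplyr::arrange(
        dplyr::filter(tab, .data$selected | dplyr::row_number() ==
                        which.min(.data$aicc)), .data$aicc)[1, ]
      pipeline_log(out_dir, nm, ": ", sum(tab$selected),
                   " model(s) selected; best rm = ", best$rm,
                   ", classes = ", best$classes)
      list(occ = d$occ, occ_pc = occ_pc, bg_pc = bg_pc, mask = buf,
           table = tab, best = best)
    })
  })
  res$selection <- purrr::map(datasets, "table")

  res$transfer <- stage("transfer", {
    paleo <- make_paleo_stack(stack, config$projection$paleo_shift,
                              config$projection$paleo_noise_sd,
                              seed = stage_seed(master, 8))
    paleo_pc <- project_espace(es$model, paleo)
    maps <- purrr::imap(datasets[c("west", "east")], function(d, nm) {
      preds <- sdm_cfg$predictor_sets[[d$best$predictor_set]]
      transfer(d$occ_pc[, preds, drop = FALSE],
               d$bg_pc[, preds, drop = FALSE],
               d$best$classes, d$best$rm,
               stack_subset(paleo_pc, preds),
               replicates = config$projection$replicates,
               seed = stage_seed(master, 9))
    })
    agree <- agreement_map(maps$west, maps$east,
                           threshold = config$spread$threshold)
    write_esri_ascii(agree$map, file.path(out_dir, "rasters"))
    pipeline_log(out_dir, "paleo agreement cells: ",
                 agree$common_cell_count)
    list(maps = maps, agreement = agree)
  })

  res$spread <- stage("spread", {
    maps <- purrr::imap(datasets[c("west", "continental")],
                        function(d, nm) {
      preds <- sdm_cfg$predictor_sets[[d$best$predictor_set]]
      transfer(d$occ_pc[, preds, drop = FALSE],
               d$bg_pc[, preds, drop = FALSE],
               d$best$classes, d$best$rm,
               stack_subset(pc_stack, preds),
               replicates = config$projection$replicates,
               seed = stage_seed(master, 10))
    })
    cls <- classify_spread(occ$west, maps$west, maps$continental,
                           threshold = config$spread$threshold)
    readr::write_tsv(tibble::as_tibble(cls),
                     file.path(out_dir, "spread_classification.tsv"))
    frac <- tidy.spread_classification(cls)
    readr::write_tsv(frac, file.path(out_dir, "spread_fractions.tsv"))
    cls
  })

  pipeline_log(out_dir, "pipeline complete")
  invisible(res)
}
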