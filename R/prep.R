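#' Occurrence tables
#'
#' Occurrence sets are plain tibbles with columns `id`, `x`, `y`,
#' `range_label`, `variety_label` and a `crs` attribute (`"projected"` map
#' units or `"geographic"` lon/lat degrees). All cleaning verbs take and
#' return this shape so they chain with the pipe.
#'
#' @param x,y coordinate vectors.
#' @param range_label,variety_label labels (recycled).
#' @param id record identifiers; defaults to `1:n`.
#' @param crs `"projected"` or `"geographic"`.
#' @return A tibble of class `occurrence_set`.
#' @export
occurrence_set <- function(x, y, range_label = "A", variety_label = "type",
                           id = NULL, crs = c("projected", "geographic")) {
  crs <- match.arg(crs)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(!nzchar(range_label)) || any(!nzchar(variety_label))) {
    stop("labels must be non-empty", call. = FALSE)
  }
  n <- length(x)
  out <- tibble::tibble(
    id = if (is.null(id)) seq_len(n) else id,
    x = as.numeric(x), y = as.numeric(y),
    range_label = rep_len(as.character(range_label), n),
    variety_label = rep_len(as.character(variety_label), n))
  attr(out, "crs") <- crs
  class(out) <- c("occurrence_set", class(out))
  out
}

occ_crs <- function(occ) {
  crs <- attr(occ, "crs")
  if (is.null(crs)) "projected" else crs
}

restore_occ <- function(new, template) {
  attr(new, "crs") <- occ_crs(template)
  if (!inherits(new, "occurrence_set")) {
    class(new) <- c("occurrence_set", class(new))
  }
  new
}

#' Read/write occurrence tables as delimited text
#'
#' @param path file path.
#' @param delim field delimiter.
#' @param crs coordinate-system tag attached on read.
#' @return `read_occurrences` returns an occurrence tibble;
#'   `write_occurrences` returns `path` invisibly.
#' @export
read_occurrences <- function(path, delim = "\t",
                             crs = c("projected", "geographic")) {
  crs <- match.arg(crs)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  occurrence_set(df$x, df$y, range_label = df$range_label,
                 variety_label = df$variety_label, id = df$id, crs = crs)
}

#' @rdname read_occurrences
#' @param occ an occurrence tibble.
#' @export
write_occurrences <- function(occ, path, delim = "\t") {
  readr::write_delim(tibble::as_tibble(occ), path, delim = delim)
  invisible(path)
}

# Pairwise distance matrix between records, in km for geographic
# coordinates (haversine, R = 6371 km) and in map units otherwise.
occ_dist_matrix <- function(occ) {
  pts <- cbind(occ$x, occ$y)
  if (occ_crs(occ) == "geographic") {
    hav <- function(p1, p2) geosphere::distHaversine(p1, p2, r = 6371000)
    geosphere::distm(pts, fun = hav) / 1000
  } else {
    as.matrix(stats::dist(pts))
  }
}

#' Per-pixel deduplication of occurrences
#'
#' Keeps at most one record per raster cell of `stack` (the first in input
#' order). Records falling off the grid are dropped and counted in the
#' `n_dropped_off_grid` attribute.
#'
#' @param occ an occurrence tibble.
#' @param stack an [env_stack()] defining the pixel grid.
#' @return The deduplicated occurrence tibble.
#' @export
dedupe_per_cell <- function(occ, stack) {
  if (nrow(occ) == 0) return(occ)
  cell <- cell_from_xy(stack, occ$x, occ$y)
  off <- sum(is.na(cell))
  if (off > 0) {
    message(off, " record(s) fall outside the grid and were dropped")
  }
  keep <- !is.na(cell) & !duplicated(cell, incomparables = NA)
  out <- restore_occ(occ[keep, , drop = FALSE], occ)
  attr(out, "n_dropped_off_grid") <- off
  out
}

#' Minimum-distance spatial thinning
#'
#' Repeatedly removes, from the closest conflicting pair, the record with
#' the most remaining conflicts (ties broken at random), until all pairwise
#' distances are at least `dmin`. The randomized pass is restarted `trials`
#' times and a pass retaining the maximum number of records is returned.
#' Distances are great-circle km for geographic coordinates and map units
#' otherwise. Deterministic given `seed`.
#'
#' @param occ an occurrence tibble.
#' @param dmin minimum allowed pairwise distance (km or map units).
#' @param trials number of randomized restarts.
#' @param seed integer seed.
#' @return The thinned occurrence tibble (a subset of the input rows).
#' @export
thin_min_distance <- function(occ, dmin, trials = 10, seed = 1) {
  if (dmin <= 0) stop("`dmin` must be > 0", call. = FALSE)
  n <- nrow(occ)
  if (n <= 1) return(occ)
  D <- occ_dist_matrix(occ)
  diag(D) <- Inf
  if (min(D) >= dmin) return(occ)
  set.seed(seed)
  best <- NULL
  for (trial in seq_len(trials)) {
    conflict <- D < dmin
    alive <- rep(TRUE, n)
    repeat {
      counts <- rowSums(conflict[alive, alive, drop = FALSE])
      if (all(counts == 0)) break
      sub <- D[alive, alive, drop = FALSE]
      sub[!conflict[alive, alive, drop = FALSE]] <- Inf
      pair <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      ci <- counts[pair[1]]; cj <- counts[pair[2]]
      drop_local <- if (ci > cj) pair[1]
        else if (cj > ci) pair[2]
        else pair[sample.int(2, 1)] # tie broken at random
      drop_global <- which(alive)[drop_local]
      alive[drop_global] <- FALSE
    }
    if (is.null(best) || sum(alive) > sum(best)) best <- alive
  }
  restore_occ(occ[best, , drop = FALSE], occ)
}

# rings: data.frame(x, y) or list thereof -> single boundary matrix with
# NA-separated loops, as mgcv::in.out expects.
polygon_boundary <- function(polygon) {
  rings <- if (is.data.frame(polygon)) list(polygon) else polygon
  parts <- lapply(rings, function(r) as.matrix(r[, c("x", "y")]))
  do.call(rbind, lapply(seq_along(parts), function(i) {
    if (i == 1) parts[[i]] else rbind(c(NA, NA), parts[[i]])
  }))
}

polygon_area <- function(polygon) {
  rings <- if (is.data.frame(polygon)) list(polygon) else polygon
  sum(vapply(rings, function(r) {
    x <- r$x; y <- r$y
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1)))
}

#' Random points inside polygons with a minimum spacing
#'
#' Rejection-samples up to `n` points uniformly inside the polygon(s),
#' accepting a point only if it lies at least `dmin` from every point
#' already accepted. Warns if fewer than `n` points are achievable within
#' the retry budget.
#'
#' @param polygon a data frame with `x`, `y` vertex columns, or a list of
#'   such rings.
#' @param n number of points requested.
#' @param dmin minimum pairwise distance (km if `crs = "geographic"`,
#'   map units otherwise).
#' @param seed integer seed.
#' @param crs coordinate system of the polygon vertices.
#' @param max_tries rejection-sampling budget.
#' @return An occurrence tibble of accepted points.
#' @export
sample_polygon_points <- function(polygon, n, dmin = 0, seed = 1,
                                  crs = c("projected", "geographic"),
                                  max_tries = 200 * n) {
  crs <- match.arg(crs)
  if (polygon_area(polygon) <= 0) {
    stop("degenerate polygon: zero area", call. = FALSE)
  }
  bnd <- polygon_boundary(polygon)
  xr <- range(bnd[, 1], na.rm = TRUE); yr <- range(bnd[, 2], na.rm = TRUE)
  set.seed(seed)
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < n && tries < max_tries) {
    tries <- tries + 1
    p <- c(stats::runif(1, xr[1], xr[2]), stats::runif(1, yr[1], yr[2]))
    if (!mgcv::in.out(bnd, matrix(p, 1))) next
    if (nrow(pts) > 0 && dmin > 0) {
      d <- if (crs == "geographic") {
        geosphere::distHaversine(pts, p, r = 6371000) / 1000
      } else {
        sqrt(rowSums(sweep(pts, 2, p)^2))
      }
      if (min(d) < dmin) next
    }
    pts <- rbind(pts, p)
  }
  if (nrow(pts) < n) {
    warning("only ", nrow(pts), " of ", n,
            " points placed within the retry budget", call. = FALSE)
  }
  occurrence_set(pts[, 1], pts[, 2], range_label = "polygon",
                 variety_label = "sampled", crs = crs)
}

#' Welch comparison of range climates
#'
#' Extracts the environmental values of each layer at two occurrence sets
#' and compares their means with a two-sided Welch (unequal-variance)
#' t-test, layer by layer.
#'
#' @param occ_a,occ_b occurrence tibbles (each with at least 2 on-grid
#'   records).
#' @param stack an [env_stack()].
#' @param adjust multiplicity adjustment of p-values: `"none"` (default) or
#'   `"bonferroni"`.
#' @return A tibble with one row per layer: `layer`, `mean_a`, `mean_b`,
#'   `t`, `df`, `p` (and `p_adj` when adjusted), plus `flag` marking layers
#'   where the test is undefined (zero variance in both groups).
#' @export
welch_compare <- function(occ_a, occ_b, stack,
                          adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  va <- extract_env(stack, occ_a)[, layer_names(stack), drop = FALSE]
  vb <- extract_env(stack, occ_b)[, layer_names(stack), drop = FALSE]
  va <- va[stats::complete.cases(va), , drop = FALSE]
  vb <- vb[stats::complete.cases(vb), , drop = FALSE]
  if (nrow(va) < 2 || nrow(vb) < 2) {
    stop("each occurrence set needs >= 2 records on the stack", call. = FALSE)
  }
  res <- purrr::map_dfr(layer_names(stack), function(ly) {
    a <- va[[ly]]; b <- vb[[ly]]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      return(tibble::tibble(layer = ly, mean_a = mean(a), mean_b = mean(b),
                            t = NA_real_, df = NA_real_, p = NA_real_,
                            flag = "zero variance in both groups"))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    tibble::tibble(layer = ly, mean_a = mean(a), mean_b = mean(b),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, flag = NA_character_)
  })
  if (adjust == "bonferroni") {
    res$p_adj <- stats::p.adjust(res$p, method = "bonferroni")
  }
  res
}
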