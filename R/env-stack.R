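#' Multi-layer environmental raster stack
#'
#' `env_stack` is the package's gridded-environment container (the G-space):
#' a set of named layers sharing one geotransform, stored as a cells-by-layers
#' matrix. Cells are ordered row-major starting at the top-left corner, the
#' usual raster convention. Coordinates are either projected planar map units
#' (`crs = "projected"`, the default for synthetic landscapes) or geographic
#' degrees (`crs = "geographic"`), which switches distance computations
#' downstream to great-circle formulas.
#'
#' @param values numeric matrix with one row per cell (row-major from the
#'   top-left) and one column per layer, or a vector for a single layer.
#' @param nrow,ncol grid dimensions in cells.
#' @param xmin,ymin coordinates of the lower-left corner of the grid.
#' @param cellsize side length of a (square) cell in map units.
#' @param crs `"projected"` or `"geographic"`.
#' @param layers character vector of layer names; defaults to the column
#'   names of `values` or `env1, env2, ...`.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(values, nrow, ncol, xmin = 0, ymin = 0, cellsize = 1,
                      crs = c("projected", "geographic"), layers = NULL) {
  crs <- match.arg(crs)
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  if (nrow(values) != nrow * ncol) {
    stop("`values` must have nrow * ncol = ", nrow * ncol, " rows, got ",
         nrow(values), call. = FALSE)
  }
  if (is.null(layers)) {
    layers <- colnames(values)
    if (is.null(layers)) layers <- paste0("env", seq_len(ncol(values)))
  }
  colnames(values) <- layers
  structure(
    list(values = values, nrow = as.integer(nrow), ncol = as.integer(ncol),
         xmin = xmin, ymin = ymin, cellsize = cellsize, crs = crs),
    class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat("<env_stack> ", x$nrow, " x ", x$ncol, " cells, ",
      n_layers(x), " layer(s), cellsize ", x$cellsize,
      " (", x$crs, ")\n", sep = "")
  cat("  layers:", paste(layer_names(x), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname env_stack
#' @param stack an `env_stack`.
#' @export
n_cells <- function(stack) stack$nrow * stack$ncol

#' @rdname env_stack
#' @export
n_layers <- function(stack) ncol(stack$values)

#' @rdname env_stack
#' @export
layer_names <- function(stack) colnames(stack$values)

stack_xmax <- function(stack) stack$xmin + stack$ncol * stack$cellsize
stack_ymax <- function(stack) stack$ymin + stack$nrow * stack$cellsize

same_grid <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Cell index from coordinates
#'
#' Maps x/y coordinates onto row-major cell indices of a stack's grid.
#' Points outside the grid extent return `NA`.
#'
#' @param stack an `env_stack`.
#' @param x,y coordinate vectors of equal length.
#' @return Integer vector of cell indices (NA outside the grid).
#' @export
cell_from_xy <- function(stack, x, y) {
  col <- floor((x - stack$xmin) / stack$cellsize) + 1
  row <- floor((stack_ymax(stack) - y) / stack$cellsize) + 1
  # points exactly on the top/right edge belong to the last row/col
  col[x == stack_xmax(stack)] <- stack$ncol
  row[y == stack$ymin] <- stack$nrow
  bad <- col < 1 | col > stack$ncol | row < 1 | row > stack$nrow |
    is.na(x) | is.na(y)
  idx <- (row - 1L) * stack$ncol + col
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Cell-center coordinates from cell indices
#'
#' @param stack an `env_stack`.
#' @param cell integer cell indices (row-major from the top-left).
#' @return A tibble with columns `x`, `y`.
#' @export
xy_from_cell <- function(stack, cell) {
  row <- (cell - 1L) %/% stack$ncol + 1L
  col <- (cell - 1L) %% stack$ncol + 1L
  tibble::tibble(
    x = stack$xmin + (col - 0.5) * stack$cellsize,
    y = stack_ymax(stack) - (row - 0.5) * stack$cellsize)
}

#' Extract layer values at point locations
#'
#' @param stack an `env_stack`.
#' @param x,y coordinates (or a data frame with `x`, `y` columns as `x`).
#' @return A tibble with one row per point: `cell` plus one column per layer
#'   (NA for points off the grid).
#' @export
extract_env <- function(stack, x, y = NULL) {
  if (is.null(y)) {
    y <- x$y
    x <- x$x
  }
  cell <- cell_from_xy(stack, x, y)
  vals <- matrix(NA_real_, length(cell), n_layers(stack),
                 dimnames = list(NULL, layer_names(stack)))
  ok <- !is.na(cell)
  vals[ok, ] <- stack$values[cell[ok], , drop = FALSE]
  dplyr::bind_cols(tibble::tibble(cell = cell), tibble::as_tibble(vals))
}

#' @exportS3Method tibble::as_tibble
as_tibble.env_stack <- function(x, ...) {
  cell <- seq_len(n_cells(x))
  dplyr::bind_cols(tibble::tibble(cell = cell), xy_from_cell(x, cell),
                   tibble::as_tibble(x$values))
}

#' Keep a subset of layers
#'
#' @param stack an `env_stack`.
#' @param layers character vector of layer names (or integer indices).
#' @return An `env_stack` with only the requested layers.
#' @export
stack_subset <- function(stack, layers) {
  if (is.character(layers) && !all(layers %in% layer_names(stack))) {
    stop("unknown layer(s): ",
         paste(setdiff(layers, layer_names(stack)), collapse = ", "),
         call. = FALSE)
  }
  stack$values <- stack$values[, layers, drop = FALSE]
  stack
}

#' Read and write ESRI ASCII grids
#'
#' One plain-text `.asc` file per layer; the standard header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' rows of cell values from the top row down.
#'
#' @param stack an `env_stack`.
#' @param dir directory in which to write one `<layer>.asc` file per layer.
#' @param nodata value written for `NA` cells.
#' @return `write_esri_ascii` returns the written paths invisibly;
#'   `read_esri_ascii` returns an `env_stack`.
#' @export
write_esri_ascii <- function(stack, dir, nodata = -9999) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(n_layers(stack))
  for (j in seq_len(n_layers(stack))) {
    path <- file.path(dir, paste0(layer_names(stack)[j], ".asc"))
    v <- stack$values[, j]
    v[is.na(v)] <- nodata
    m <- matrix(v, nrow = stack$nrow, ncol = stack$ncol, byrow = TRUE)
    hdr <- c(paste("ncols", stack$ncol), paste("nrows", stack$nrow),
             paste("xllcorner", format(stack$xmin, digits = 15)),
             paste("yllcorner", format(stack$ymin, digits = 15)),
             paste("cellsize", format(stack$cellsize, digits = 15)),
             paste("NODATA_value", nodata))
    writeLines(c(hdr, apply(m, 1, paste, collapse = " ")), path)
    paths[j] <- path
  }
  invisible(paths)
}

#' @rdname write_esri_ascii
#' @param files character vector of `.asc` paths sharing one geotransform.
#' @param layers layer names; defaults to file base names.
#' @param crs coordinate system tag for the resulting stack.
#' @export
read_esri_ascii <- function(files, layers = NULL,
                            crs = c("projected", "geographic")) {
  crs <- match.arg(crs)
  if (is.null(layers)) layers <- sub("\\.asc$", "", basename(files))
  cols <- vector("list", length(files))
  hdr0 <- NULL
  for (j in seq_along(files)) {
    lines <- readLines(files[j])
    hdr_n <- 6L
    hdr <- strsplit(trimws(lines[seq_len(hdr_n)]), "\\s+")
    keys <- tolower(vapply(hdr, `[`, "", 1))
    vals <- as.numeric(vapply(hdr, `[`, "", 2))
    names(vals) <- keys
    body <- scan(text = lines[-seq_len(hdr_n)], quiet = TRUE)
    m <- matrix(body, nrow = vals[["nrows"]], ncol = vals[["ncols"]],
                byrow = TRUE)
    m[m == vals[["nodata_value"]]] <- NA
    if (is.null(hdr0)) hdr0 <- vals
    else if (any(abs(vals[1:5] - hdr0[1:5]) > 1e-9)) {
      stop("grid headers differ between files", call. = FALSE)
    }
    cols[[j]] <- as.vector(t(m))
  }
  env_stack(do.call(cbind, cols), nrow = hdr0[["nrows"]],
            ncol = hdr0[["ncols"]], xmin = hdr0[["xllcorner"]],
            ymin = hdr0[["yllcorner"]], cellsize = hdr0[["cellsize"]],
            crs = crs, layers = layers)
}

#' Raster heat map of one layer of a stack
#'
#' @param stack an `env_stack`.
#' @param layer layer name (defaults to the first).
#' @return A ggplot object.
#' @export
plot_stack_layer <- function(stack, layer = layer_names(stack)[1]) {
  df <- as_tibble.env_stack(stack)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data[[layer]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = layer, x = NULL, y = NULL)
}
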