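#' Grid specification for a north-up lon/lat raster
#'
#' A `grid_spec` describes a regular grid of square cells in WGS84
#' longitude/latitude: the number of rows and columns, the lower-left
#' corner, the cell size in degrees, and the nodata sentinel. Row 1 of any
#' layer on this grid is the northernmost row, matching ESRI ASCII order.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param x_min,y_min Coordinates of the lower-left corner of the grid, in
#'   degrees. `y_min + n_rows * cell_size` must stay within \[-90, 90\].
#' @param cell_size Cell edge length in degrees (square cells).
#' @param nodata Sentinel written for invalid cells (default -9999).
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(90, 120, x_min = 92, y_min = 18.5, cell_size = 0.25)
#' @export
grid_spec <- function(n_rows, n_cols, x_min, y_min, cell_size, nodata = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  y_max <- y_min + n_rows * cell_size
  if (y_max > 90 + 1e-9 || y_min < -90 - 1e-9) {
    stop("grid extent exceeds latitude range [-90, 90]: y in [",
         y_min, ", ", y_max, "]", call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         cell_size = as.numeric(cell_size), nodata = as.numeric(nodata),
         crs_label = "WGS84 lon/lat"),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d rows x %d cols @ %g deg, origin (%g, %g), nodata %g\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_min, x$y_min, x$nodata))
  invisible(x)
}

grids_identical <- function(a, b) {
  # exact comparison by design: silent resampling is a bug source
  identical(a$n_rows, b$n_rows) && identical(a$n_cols, b$n_cols) &&
    identical(a$x_min, b$x_min) && identical(a$y_min, b$y_min) &&
    identical(a$cell_size, b$cell_size)
}

grid_mismatch_fields <- function(a, b) {
  f <- c("n_rows", "n_cols", "x_min", "y_min", "cell_size")
  f[!vapply(f, function(k) identical(a[[k]], b[[k]]), logical(1))]
}

#' Cell-center coordinates of a grid
#'
#' Centers follow the half-open convention: cell (r, c) covers
#' `[x_min + (c-1) s, x_min + c s)` in lon and the matching latitude band,
#' with row 1 at the top (north).
#'
#' @param grid A [grid_spec()].
#' @return A tibble with columns `row`, `col`, `lon`, `lat` in row-major
#'   order (row 1 first).
#' @export
grid_centers <- function(grid) {
  s <- grid$cell_size
  y_top <- grid$y_min + grid$n_rows * s
  rows <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  tibble::tibble(
    row = rows, col = cols,
    lon = grid$x_min + (cols - 0.5) * s,
    lat = y_top - (rows - 0.5) * s
  )
}

#' Locate points on a grid
#'
#' Maps lon/lat points to 1-based (row, col) indices under the half-open
#' cell convention; points outside the extent get NA.
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Numeric vectors of coordinates.
#' @return A tibble with columns `row`, `col` (NA outside the grid).
#' @export
locate_cells <- function(grid, lon, lat) {
  s <- grid$cell_size
  y_top <- grid$y_min + grid$n_rows * s
  col <- floor((lon - grid$x_min) / s) + 1
  row <- floor((y_top - lat) / s) + 1
  # top edge belongs to row 1 (half-open from the top)
  row[lat == y_top] <- 1L
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Construct an environmental layer
#'
#' @param name Variable code (e.g. "bio2", "Ele", "UVB4").
#' @param grid A [grid_spec()].
#' @param values Numeric matrix `n_rows x n_cols`, row 1 = northernmost.
#' @param mask Logical matrix of per-cell validity; defaults to
#'   `is.finite(values)`.
#' @return An object of class `env_layer`.
#' @export
env_layer <- function(name, grid, values, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols))) {
    stop("values must be a ", grid$n_rows, " x ", grid$n_cols, " matrix",
         call. = FALSE)
  }
  if (is.null(mask)) mask <- is.finite(values)
  stopifnot(is.logical(mask), all(dim(mask) == dim(values)))
  if (any(!is.finite(values[mask]))) {
    stop("layer '", name, "' has non-finite values on valid cells", call. = FALSE)
  }
  structure(list(name = name, grid = grid, values = values, mask = mask),
            class = "env_layer")
}

#' @export
print.env_layer <- function(x, ...) {
  cat(sprintf("<env_layer> '%s' (%d x %d, %d valid cells)\n",
              x$name, x$grid$n_rows, x$grid$n_cols, sum(x$mask)))
  invisible(x)
}

#' Read a single-band raster
#'
#' Parses an ESRI ASCII grid (.asc, standard 6-line header with
#' `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`). Values equal to
#' the nodata sentinel are masked. Row 1 of the result is the top (north)
#' row, as in the file.
#'
#' @param path Path to the raster file.
#' @param format Only `"esri_ascii"` is supported.
#' @param name Layer name; defaults to the file name without extension.
#' @return An [env_layer()].
#' @export
read_raster <- function(path, format = c("esri_ascii", "geotiff"), name = NULL) {
  format <- match.arg(format)
  if (format == "geotiff") {
    stop("GeoTIFF input is not supported by this build; convert to ESRI ASCII (.asc)",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(toks[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "dx", "dy", "nodata_value")) {
      val <- suppressWarnings(as.numeric(toks[2]))
      if (is.na(val)) {
        stop("malformed ESRI ASCII header field '", toks[1], "' in ", path,
             call. = FALSE)
      }
      hdr[[key]] <- val
      n_hdr <- n_hdr + 1L
    } else break
  }
  for (req in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[req]])) {
      stop("ESRI ASCII header missing required field '", req, "' in ", path,
           call. = FALSE)
    }
  }
  if (!is.null(hdr$dx) || !is.null(hdr$dy)) {
    stop("non-square cells (dx/dy header) are not supported", call. = FALSE)
  }
  if (is.null(hdr$xllcorner)) {
    if (is.null(hdr$xllcenter)) stop("ESRI ASCII header missing xllcorner", call. = FALSE)
    hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
    hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
  }
  if (is.null(hdr$yllcorner)) stop("ESRI ASCII header missing yllcorner", call. = FALSE)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = paste(lines[-seq_len(n_hdr)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("ESRI ASCII body has ", length(vals), " values; expected ",
         nr * nc, call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- m != nodata & is.finite(m)
  m[!mask] <- NA_real_
  g <- grid_spec(nr, nc, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  env_layer(name, g, m, mask)
}

#' Write a single-band raster
#'
#' Writes an [env_layer()] as an ESRI ASCII grid. Masked cells serialize as
#' the grid's nodata sentinel; the header cellsize is written with 12
#' significant digits so a round trip is lossless at double precision.
#'
#' @param layer An [env_layer()].
#' @param path Output path.
#' @param format Only `"esri_ascii"` is supported.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, format = c("esri_ascii", "geotiff")) {
  format <- match.arg(format)
  if (format == "geotiff") {
    stop("GeoTIFF output is not supported by this build; use ESRI ASCII (.asc)",
         call. = FALSE)
  }
  g <- layer$grid
  m <- layer$values
  m[!layer$mask] <- g$nodata
  hdr <- c(
    paste("ncols", g$n_cols),
    paste("nrows", g$n_rows),
    paste("xllcorner", format(g$x_min, digits = 12)),
    paste("yllcorner", format(g$y_min, digits = 12)),
    paste("cellsize", format(g$cell_size, digits = 12)),
    paste("NODATA_value", format(g$nodata, digits = 12))
  )
  body <- apply(m, 1, function(r) paste(format(r, digits = 12, trim = TRUE),
                                        collapse = " "))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Assemble aligned layers into an environmental stack
#'
#' Verifies that every layer shares one bitwise-identical grid (no epsilon:
#' header fields must match exactly) and computes the joint validity mask as
#' the intersection of layer masks. Layer order and names are preserved.
#'
#' @param layers A list of [env_layer()] objects.
#' @return An object of class `env_stack` with fields `layers` (named
#'   list), `grid`, and `mask` (joint validity matrix).
#' @export
assemble_stack <- function(layers) {
  if (length(layers) == 0) stop("no layers supplied", call. = FALSE)
  stopifnot(all(vapply(layers, inherits, logical(1), "env_layer")))
  g <- layers[[1]]$grid
  for (i in seq_along(layers)[-1]) {
    if (!grids_identical(g, layers[[i]]$grid)) {
      stop("grid mismatch between layer '", layers[[1]]$name, "' and '",
           layers[[i]]$name, "' in field(s): ",
           paste(grid_mismatch_fields(g, layers[[i]]$grid), collapse = ", "),
           call. = FALSE)
    }
  }
  mask <- Reduce(`&`, lapply(layers, `[[`, "mask"))
  if (!any(mask)) stop("stack has no jointly valid cell", call. = FALSE)
  names(layers) <- vapply(layers, `[[`, character(1), "name")
  structure(list(layers = layers, grid = g, mask = mask), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers (%s) on %d x %d grid, %d jointly valid cells\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols, sum(x$mask)))
  invisible(x)
}

#' Stack values as a cell-by-variable tibble
#'
#' @param x An `env_stack`.
#' @param valid_only Keep only jointly valid cells (default TRUE).
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `lon`, `lat` and one column per layer.
#' @method as_tibble env_stack
#' @export
as_tibble.env_stack <- function(x, ..., valid_only = TRUE) {
  out <- grid_centers(x$grid)
  for (nm in names(x$layers)) {
    # matrices are column-major; centers are row-major
    out[[nm]] <- as.vector(t(x$layers[[nm]]$values))
  }
  if (valid_only) out <- out[as.vector(t(x$mask)), ]
  out
}

stack_matrix <- function(stack, cells = NULL) {
  # n_cells x n_vars matrix over jointly valid cells (or given linear
  # row-major cell ids), columns named by layer
  vals <- vapply(stack$layers, function(l) as.vector(t(l$values)),
                 numeric(stack$grid$n_rows * stack$grid$n_cols))
  if (is.null(cells)) cells <- which(as.vector(t(stack$mask)))
  vals[cells, , drop = FALSE]
}

valid_cell_ids <- function(stack) which(as.vector(t(stack$mask)))

#' Area of one grid cell, by row
#'
#' Spherical-zone area of a cell in the given row:
#' `A = R^2 * dlam * (sin(phi_top) - sin(phi_bot))` with R = 6371 km and
#' `dlam` the cell size in radians. Positive everywhere, decreasing toward
#' the poles, equal for mirror rows at +/-phi.
#'
#' @param grid A [grid_spec()].
#' @param row Row index (1-based, row 1 = north), vectorized.
#' @return Cell area(s) in km^2.
#' @export
cell_area_km2 <- function(grid, row) {
  if (any(row < 1 | row > grid$n_rows)) {
    stop("row index out of range [1, ", grid$n_rows, "]", call. = FALSE)
  }
  R <- 6371.0
  s <- grid$cell_size
  y_top <- grid$y_min + grid$n_rows * s
  phi_top <- (y_top - (row - 1) * s) * pi / 180
  phi_bot <- (y_top - row * s) * pi / 180
  R^2 * (s * pi / 180) * (sin(phi_top) - sin(phi_bot))
}

#' Per-cell area layer for a grid
#'
#' @param grid A [grid_spec()].
#' @return Matrix of cell areas (km^2), constant within each row.
#' @export
cell_area_matrix <- function(grid) {
  matrix(rep(cell_area_km2(grid, seq_len(grid$n_rows)), grid$n_cols),
         nrow = grid$n_rows, ncol = grid$n_cols)
}
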