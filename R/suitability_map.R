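#' Habitat suitability surface
#'
#' Container for a continuous habitat-suitability index (HSI) on a grid.
#' Values live in \[0, 1\] for the cloglog/logistic transforms; on the raw
#' scale they are the normalized Gibbs probabilities and sum to 1 over the
#' training background.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix (NA outside `mask`).
#' @param mask Logical validity matrix.
#' @param transform One of "raw", "cloglog", "logistic".
#' @param label Optional free-text tag (e.g. a scenario name).
#' @return An object of class `suitability_map`.
#' @export
suitability_map <- function(grid, values, mask, transform = "cloglog",
                            label = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values), is.logical(mask))
  transform <- match.arg(transform, c("raw", "cloglog", "logistic"))
  if (transform != "raw") {
    v <- values[mask]
    if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE)) {
      stop("suitability values outside [0, 1] on valid cells", call. = FALSE)
    }
  }
  structure(list(grid = grid, values = values, mask = mask,
                 transform = transform, label = label),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  rng <- range(x$values[x$mask], na.rm = TRUE)
  cat(sprintf("<suitability_map> %s scale, %d x %d grid, range [%.3f, %.3f]%s\n",
              x$transform, x$grid$n_rows, x$grid$n_cols, rng[1], rng[2],
              if (is.null(x$label)) "" else paste0(", '", x$label, "'")))
  invisible(x)
}

#' @method as_tibble suitability_map
#' @export
as_tibble.suitability_map <- function(x, ...) {
  out <- grid_centers(x$grid)
  out$suitability <- as.vector(t(x$values))
  out[as.vector(t(x$mask)), ]
}

#' Plot a suitability surface
#'
#' @param object A `suitability_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot suitability_map
#' @export
autoplot.suitability_map <- function(object, ...) {
  df <- as_tibble.suitability_map(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$suitability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = if (object$transform == "raw")
      NULL else c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  fill = paste0("HSI (", object$transform, ")"),
                  title = object$label)
}

map_values_valid <- function(map) map$values[map$mask]
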