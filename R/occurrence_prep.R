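#' Read species occurrence records
#'
#' Reads a CSV with columns `species`, `lon`, `lat` (header required). Rows
#' with unparseable or out-of-range coordinates (|lon| > 180, |lat| > 90)
#' are dropped with a message reporting the count.
#'
#' @param path CSV path.
#' @return A tibble with columns `species`, `lon`, `lat`.
#' @export
read_occurrences <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_guess()))
  missing <- setdiff(c("species", "lon", "lat"), names(df))
  if (length(missing)) {
    stop("occurrence CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- dplyr::mutate(df,
                      lon = suppressWarnings(as.numeric(.data$lon)),
                      lat = suppressWarnings(as.numeric(.data$lat)))
  n0 <- nrow(df)
  keep <- is.finite(df$lon) & is.finite(df$lat) &
    df$lon >= -180 & df$lon <= 180 & df$lat >= -90 & df$lat <= 90
  if (any(!keep)) {
    message("read_occurrences: dropped ", sum(!keep), " of ", n0,
            " rows with invalid coordinates")
  }
  tibble::as_tibble(df[keep, c("species", "lon", "lat")])
}

#' Thin occurrences to one record per grid cell
#'
#' Spatial rarefaction on the modelling grid: at most one record per cell
#' and species, keeping the first record (input order) in each occupied
#' cell. Records outside the grid extent are dropped with a message. The
#' operation is idempotent.
#'
#' @param occ Tibble with columns `species`, `lon`, `lat`.
#' @param grid A [grid_spec()] (the working raster's grid).
#' @param mask Optional validity matrix; records on invalid cells dropped.
#' @return The thinned tibble (original row order preserved).
#' @export
thin_to_grid <- function(occ, grid, mask = NULL) {
  stopifnot(all(c("species", "lon", "lat") %in% names(occ)))
  cells <- locate_cells(grid, occ$lon, occ$lat)
  inside <- !is.na(cells$row)
  if (!is.null(mask)) {
    on_valid <- inside
    on_valid[inside] <- mask[cbind(cells$row[inside], cells$col[inside])]
    inside <- on_valid
  }
  if (any(!inside)) {
    message("thin_to_grid: dropped ", sum(!inside),
            " record(s) outside the grid or on nodata cells")
  }
  occ <- occ[inside, ]
  cells <- cells[inside, ]
  key <- paste(occ$species, cells$row, cells$col)
  keep <- !duplicated(key)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("thin_to_grid: removed ", n_dropped,
            " duplicate record(s) sharing a cell; kept ", sum(keep))
  }
  occ[keep, ]
}

#' Map occurrences to grid cell indices
#'
#' @param occ Occurrence tibble.
#' @param grid A [grid_spec()].
#' @return `occ` with `row`, `col` and linear row-major `cell` columns.
#' @export
occurrence_cells <- function(occ, grid) {
  cells <- locate_cells(grid, occ$lon, occ$lat)
  dplyr::bind_cols(occ, cells) |>
    dplyr::mutate(cell = (.data$row - 1L) * grid$n_cols + .data$col)
}
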