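#' Priority conservation areas from species class maps
#'
#' A cell is a priority cell when at least `min_species` species are
#' moderately or highly suitable there (class >= 2). Raising `min_species`
#' never grows the mask.
#'
#' @param classmaps List of `class_map`s on one shared grid.
#' @param min_species Minimum co-occurring species (default 2, reading
#'   "more than two species" inclusively so pairwise coexistence counts).
#' @return Logical priority matrix on the shared grid.
#' @export
priority_areas <- function(classmaps, min_species = 2) {
  stopifnot(length(classmaps) >= 1)
  g <- classmaps[[1]]$grid
  for (cm in classmaps[-1]) {
    if (!grids_identical(g, cm$grid)) {
      stop("class maps are on different grids", call. = FALSE)
    }
  }
  counts <- Reduce(`+`, lapply(classmaps, function(cm) {
    m <- cm$classes >= 2L
    m[!cm$mask | is.na(m)] <- FALSE
    m
  }))
  counts >= min_species
}

#' Protected-area gap analysis
#'
#' Overlays the priority mask with the protected-area mask and reports
#' priority area, protected overlap (both 10^4 km^2, latitude-correct cell
#' areas) and the unprotected percentage
#' `100 * (1 - overlap / priority)`.
#'
#' @param priority Logical priority matrix.
#' @param pa A `pa_mask` (or logical matrix) on the same grid.
#' @param grid The shared [grid_spec()].
#' @return A one-row tibble: `priority_area`, `protected_overlap`
#'   (10^4 km^2), `percent_unprotected`.
#' @export
gap_analysis <- function(priority, pa, grid) {
  member <- if (inherits(pa, "pa_mask")) pa$member else pa
  stopifnot(all(dim(priority) == c(grid$n_rows, grid$n_cols)),
            all(dim(member) == dim(priority)))
  if (!any(priority)) stop("priority mask is empty", call. = FALSE)
  areas <- cell_area_matrix(grid)
  prio <- sum(areas[priority]) / 1e4
  ovl <- sum(areas[priority & member]) / 1e4
  tibble::tibble(priority_area = prio, protected_overlap = ovl,
                 percent_unprotected = 100 * (1 - ovl / prio))
}

#' Area-weighted centroid of the suitable range
#'
#' Mean of cell-center coordinates over cells with HSI at or above the
#' threshold, weighted by latitude-correct cell area.
#'
#' @param map A `suitability_map`.
#' @param mask_threshold HSI threshold for range membership (default 0.2,
#'   the total-suitable cutoff).
#' @return A one-row tibble: `lon`, `lat`.
#' @export
suitable_centroid <- function(map, mask_threshold = 0.2) {
  sel <- map$mask & map$values >= mask_threshold
  sel[is.na(sel)] <- FALSE
  if (!any(sel)) stop("no cell reaches the threshold", call. = FALSE)
  keep <- as.vector(t(sel))
  w <- as.vector(t(cell_area_matrix(map$grid)))[keep]
  cent <- grid_centers(map$grid)
  tibble::tibble(lon = sum(cent$lon[keep] * w) / sum(w),
                 lat = sum(cent$lat[keep] * w) / sum(w))
}

#' Great-circle shift between two centroids
#'
#' Haversine distance on the R = 6371 km sphere plus the initial bearing
#' (degrees clockwise from north).
#'
#' @param from,to Length-2 numeric `c(lon, lat)` (or one-row tibbles with
#'   `lon`, `lat`).
#' @return A one-row tibble: `distance_km`, `bearing_deg`.
#' @export
centroid_shift <- function(from, to) {
  as_pt <- function(p) {
    if (is.data.frame(p)) c(p$lon[1], p$lat[1]) else as.numeric(p)
  }
  a <- as_pt(from); b <- as_pt(to)
  d <- geosphere::distHaversine(a, b, r = 6371000) / 1000
  brg <- if (d == 0) NA_real_ else (geosphere::bearing(a, b) + 360) %% 360
  tibble::tibble(distance_km = d, bearing_deg = brg)
}

#' Centroid track across periods
#'
#' Chains the suitable-range centroid from the current map through each
#' future period of one scenario, reporting per-step haversine distance
#' and bearing (one fewer step than periods).
#'
#' @param current_map Current `suitability_map`.
#' @param future_maps Ordered named list of the scenario's period maps.
#' @param scenario Scenario label.
#' @param mask_threshold Threshold for [suitable_centroid()].
#' @return A tibble with `scenario`, `period`, `lon`, `lat`,
#'   `distance_km`, `bearing_deg` (NA on the first row).
#' @export
centroid_track <- function(current_map, future_maps, scenario = "scenario",
                           mask_threshold = 0.2) {
  cents <- dplyr::bind_rows(
    dplyr::mutate(suitable_centroid(current_map, mask_threshold),
                  period = "current"),
    purrr::map_dfr(names(future_maps), function(nm) {
      dplyr::mutate(suitable_centroid(future_maps[[nm]], mask_threshold),
                    period = nm)
    }))
  steps <- purrr::map_dfr(seq_len(nrow(cents)), function(i) {
    if (i == 1) return(tibble::tibble(distance_km = NA_real_,
                                      bearing_deg = NA_real_))
    centroid_shift(cents[i - 1, c("lon", "lat")], cents[i, c("lon", "lat")])
  })
  dplyr::bind_cols(tibble::tibble(scenario = scenario), cents[, c("period",
                                                                  "lon", "lat")],
                   steps)
}
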