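#' Bundled reference tables for the three-Magnoliaceae case study
#'
#' The package ships the printed summary tables of a published
#' three-species Magnoliaceae habitat study (area totals by scenario and
#' period, centroid coordinates with step distances, headline gap-analysis
#' figures, and variable contributions) as plain CSVs. They serve as
#' external worked-example inputs: the package's arithmetic and geodesic
#' operations recompute their derived columns from the printed primary
#' columns.
#'
#' @param name One of "area_tables", "centroids", "headline",
#'   "contributions".
#' @return A tibble.
#' @export
reference_table <- function(name = c("area_tables", "centroids", "headline",
                                     "contributions")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("magnolia_", name, ".csv"),
                      package = "nichecast", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Replicate the case study's worked examples
#'
#' Recomputes, from the bundled printed inputs alone, every derived
#' quantity the package's operations cover:
#' area change and rate-of-change chained within each scenario from the
#' printed totals ([area_change()]); the gap-analysis unprotected
#' percentage from the printed priority and overlap areas; the
#' largest species' share of a nominal 960 x 10^4 km^2 land area; and the
#' per-step centroid distances by haversine on the printed coordinates
#' ([centroid_shift()]).
#'
#' @return A tibble with columns `check`, `species`, `scenario`, `period`,
#'   `computed`, `printed`, `abs_diff`, `rel_diff`.
#' @export
replicate_worked_examples <- function() {
  areas <- reference_table("area_tables")
  cur <- dplyr::filter(areas, .data$scenario == "current")
  fut <- dplyr::filter(areas, .data$scenario != "current") |>
    dplyr::group_by(.data$species, .data$scenario) |>
    dplyr::arrange(.data$period, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      prev <- c(cur$total_suitable[cur$species == key$species],
                utils::head(df$total_suitable, -1))
      ch <- area_change(prev, df$total_suitable)
      df$change_computed <- round(ch$change, 2)
      df$rate_computed <- round(ch$rate_percent, 2)
      df
    }) |>
    dplyr::ungroup()

  rows <- list(
    dplyr::transmute(fut, check = "area_change", species = .data$species,
                     scenario = .data$scenario, period = .data$period,
                     computed = .data$change_computed,
                     printed = .data$change_printed),
    dplyr::transmute(fut, check = "rate_of_change", species = .data$species,
                     scenario = .data$scenario, period = .data$period,
                     computed = .data$rate_computed,
                     printed = .data$rate_printed))

  head_tbl <- reference_table("headline")
  hv <- stats::setNames(head_tbl$value, head_tbl$quantity)
  gap <- gap_from_totals(hv[["priority_area_1e4km2"]],
                         hv[["protected_overlap_1e4km2"]])
  rows[[3]] <- tibble::tibble(
    check = "gap_percent_unprotected", species = "all", scenario = NA_character_,
    period = NA_character_, computed = round(gap, 2),
    printed = hv[["percent_unprotected_printed"]])
  rows[[4]] <- tibble::tibble(
    check = "land_fraction_percent", species = "M_insignis",
    scenario = NA_character_, period = NA_character_,
    computed = round(100 * hv[["m_insignis_total_1e4km2"]] /
                       hv[["china_land_area_1e4km2"]], 2),
    printed = hv[["m_insignis_land_fraction_printed"]])

  cents <- reference_table("centroids")
  cur_c <- dplyr::filter(cents, .data$scenario == "current")
  steps <- dplyr::filter(cents, .data$scenario != "current") |>
    dplyr::group_by(.data$species, .data$scenario) |>
    dplyr::arrange(.data$period, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      c0 <- cur_c[cur_c$species == key$species, c("lon", "lat")]
      lon0 <- c(c0$lon, utils::head(df$lon, -1))
      lat0 <- c(c0$lat, utils::head(df$lat, -1))
      df$dist_computed <- vapply(seq_len(nrow(df)), function(i) {
        centroid_shift(c(lon0[i], lat0[i]), c(df$lon[i], df$lat[i]))$distance_km
      }, numeric(1))
      df
    }) |>
    dplyr::ungroup()
  rows[[5]] <- dplyr::transmute(
    steps, check = "centroid_step_km", species = .data$species,
    scenario = .data$scenario, period = .data$period,
    computed = round(.data$dist_computed, 2), printed = .data$dist_printed)

  out <- dplyr::bind_rows(rows)
  out$abs_diff <- abs(out$computed - out$printed)
  out$rel_diff <- out$abs_diff / abs(out$printed)
  out
}

# unprotected percentage from area totals (the GapReport identity)
gap_from_totals <- function(priority, overlap) {
  100 * (1 - overlap / priority)
}
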