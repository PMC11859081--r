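#' Four-level habitat suitability classification
#'
#' Discretizes an HSI surface into the standard four classes: not suitable
#' \[0, 0.2), minimally suitable \[0.2, 0.4), moderately suitable
#' \[0.4, 0.6), highly suitable \[0.6, 1\] (lower-closed intervals, final
#' class closed at 1).
#'
#' @param map A `suitability_map` with values in \[0, 1\].
#' @param cuts Class thresholds, strictly increasing in (0, 1)
#'   (default `c(0.2, 0.4, 0.6)`).
#' @return An object of class `class_map` with integer codes 0-3 per valid
#'   cell and levels not/minimal/moderate/high.
#' @export
classify_suitability <- function(map, cuts = c(0.2, 0.4, 0.6)) {
  if (inherits(map, "class_map")) {
    stop("input is already a class map", call. = FALSE)
  }
  stopifnot(inherits(map, "suitability_map"))
  stopifnot(length(cuts) == 3, all(diff(cuts) > 0), all(cuts > 0 & cuts < 1))
  v <- map$values
  if (any(v[map$mask] < 0 | v[map$mask] > 1, na.rm = TRUE)) {
    stop("suitability values outside [0, 1]", call. = FALSE)
  }
  cls <- matrix(NA_integer_, nrow(v), ncol(v))
  cls[map$mask] <- findInterval(v[map$mask], cuts)
  structure(list(grid = map$grid, classes = cls, mask = map$mask,
                 cuts = cuts, label = map$label,
                 levels = c("not", "minimal", "moderate", "high")),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tabs <- table(factor(x$classes[x$mask], levels = 0:3, labels = x$levels))
  cat("<class_map>", paste(names(tabs), tabs, sep = "=", collapse = ", "),
      if (!is.null(x$label)) paste0(" ('", x$label, "')"), "\n")
  invisible(x)
}

#' @method as_tibble class_map
#' @export
as_tibble.class_map <- function(x, ...) {
  out <- grid_centers(x$grid)
  out$class <- factor(as.vector(t(x$classes)), levels = 0:3, labels = x$levels)
  out[as.vector(t(x$mask)), ]
}

#' Plot a habitat-class map
#'
#' @param object A `class_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot class_map
#' @export
autoplot.class_map <- function(object, ...) {
  df <- as_tibble.class_map(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(not = "grey90", minimal = "#fee08b",
                                          moderate = "#a6d96a", high = "#1a9850"),
                               drop = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "Suitability",
                  title = object$label)
}

#' Per-class areas of a classified map
#'
#' Sums latitude-correct cell areas per suitability class and reports them
#' in units of 10^4 km^2; total suitable = minimal + moderate + high.
#' Internal arithmetic is double precision; rounding to 2 decimals happens
#' only in reporting functions.
#'
#' @param cmap A `class_map`.
#' @param label Optional period/scenario label for the row.
#' @return A one-row tibble: `label`, `not`, `minimal`, `moderate`, `high`,
#'   `total_suitable` (10^4 km^2).
#' @export
class_areas <- function(cmap, label = cmap$label) {
  areas <- cell_area_matrix(cmap$grid)
  one <- function(code) sum(areas[cmap$mask & cmap$classes == code]) / 1e4
  out <- tibble::tibble(label = label %||% NA_character_,
                        not = one(0), minimal = one(1), moderate = one(2),
                        high = one(3))
  out$total_suitable <- out$minimal + out$moderate + out$high
  out
}

#' Change and rate of change between two period totals
#'
#' `change = current - previous`; `rate = 100 * change / previous`. The
#' rate is flagged undefined when the previous total is zero.
#'
#' @param previous_total,current_total Area totals (same unit).
#' @return A one-row tibble: `change`, `rate_percent`, `rate_defined`.
#' @export
area_change <- function(previous_total, current_total) {
  change <- current_total - previous_total
  defined <- previous_total > 0
  tibble::tibble(change = change,
                 rate_percent = ifelse(defined, 100 * change / previous_total,
                                       NA_real_),
                 rate_defined = defined)
}

#' Project a fitted model onto a scenario stack
#'
#' Delegates to [predict.maxent_model()] with clamping; the stack's
#' scenario label (attribute set by [make_future_stack()]) propagates to
#' the output map.
#'
#' @param model A `maxent_model`.
#' @param future An `env_stack` (typically from [make_future_stack()]).
#' @param transform Output transform (default cloglog).
#' @return A `suitability_map` tagged with the scenario label.
#' @export
project_future <- function(model, future, transform = "cloglog") {
  predict(model, future, transform = transform, clamp = TRUE)
}

#' Area dynamics across periods within scenarios
#'
#' Builds the period-by-scenario area table: per-class and total suitable
#' areas plus change and rate-of-change chained sequentially within each
#' scenario (current, then each future period in order).
#'
#' @param current_map Current-period `suitability_map`.
#' @param future_maps Named list (scenario-period label ->
#'   `suitability_map`), e.g. `"SSP126-2050"`.
#' @param cuts Classification thresholds.
#' @return A tibble with `scenario`, `period`, class areas (10^4 km^2),
#'   `change`, `rate_percent` (2-decimal reporting columns `change` and
#'   `rate_percent` are unrounded; round at print time).
#' @export
area_dynamics <- function(current_map, future_maps, cuts = c(0.2, 0.4, 0.6)) {
  cur <- class_areas(classify_suitability(current_map, cuts), label = "current")
  labels <- names(future_maps)
  parts <- strsplit(labels, "-", fixed = TRUE)
  scen <- vapply(parts, `[`, character(1), 1)
  period <- vapply(parts, function(p) paste(p[-1], collapse = "-"), character(1))
  rows <- purrr::map_dfr(seq_along(future_maps), function(i) {
    dplyr::mutate(
      class_areas(classify_suitability(future_maps[[i]], cuts),
                  label = labels[i]),
      scenario = scen[i], period = period[i])
  })
  out <- dplyr::bind_rows(
    dplyr::mutate(cur, scenario = "current", period = "current"),
    rows)
  out$.ord <- seq_len(nrow(out))
  out <- dplyr::group_by(out, .data$scenario) |>
    dplyr::group_modify(function(df, key) {
      if (key$scenario == "current") {
        df$change <- NA_real_; df$rate_percent <- NA_real_
        return(df)
      }
      prev <- c(cur$total_suitable,
                utils::head(df$total_suitable, -1))
      ch <- area_change(prev, df$total_suitable)
      df$change <- ch$change
      df$rate_percent <- ch$rate_percent
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord)
  dplyr::select(out, "scenario", "period", "not", "minimal", "moderate",
                "high", "total_suitable", "change", "rate_percent")
}
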