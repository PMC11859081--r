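#' Default pipeline configuration
#'
#' One place for every knob of the end-to-end analysis. Defaults define the
#' package's synthetic study: a 120 x 90-cell world at 0.25 deg (lon
#' 92-122E, lat 18.5-41N), three species with presence sample sizes 41, 12
#' and 79 records and slightly different linear-quadratic truths, three
#' emission scenarios by three future periods, a protected-area mask
#' covering ~3 percent of the window, the four-level suitability cuts
#' (0.2, 0.4, 0.6), range threshold 0.4, priority co-occurrence minimum 2,
#' and centroid threshold 0.2.
#'
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param tune Run the full AICc grid search per species (default FALSE:
#'   fit at FC = LQ, RM = 1, the desk-scale setting; set TRUE for the
#'   ENMeval-style search).
#' @param n_presence Named or unnamed vector of per-species sample sizes.
#' @param out_dir Output directory for artifact files (NULL = don't write).
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 0, tune = FALSE,
                               n_presence = c(41, 12, 79), out_dir = NULL) {
  species <- paste0("species_", letters[seq_along(n_presence)])
  truths <- list(
    true_model(-4.5, linear = c(bio2 = -2.8, bio9 = -2.2),
               quadratic = c(Ele = -2.5)),
    true_model(-5.0, linear = c(bio9 = -2.6, bio4 = -1.8),
               quadratic = c(Ele = -2.2)),
    true_model(-4.0, linear = c(bio2 = -2.0, bio4 = -2.4),
               quadratic = c(bio9 = -2.0)))
  cfg <- list(
    mode = "synthetic",
    synthetic = list(n_rows = 90, n_cols = 120, cell_size = 0.25,
                     origin = c(92, 18.5), var_specs = default_var_specs(),
                     target_corr = default_target_corr(8),
                     noise = 0.05),
    species = species,
    n_presence = stats::setNames(n_presence[seq_along(species)], species),
    truths = stats::setNames(truths[seq_along(species)], species),
    rm_grid = seq(0.5, 4, by = 0.5),
    fc_grid = FC_LEVELS,
    tune = tune, fixed_fc = "LQ", fixed_rm = 1,
    cuts = c(0.2, 0.4, 0.6), range_threshold = 0.4,
    min_species = 2, centroid_threshold = 0.2,
    pearson_threshold = 0.80,
    pa = list(coverage = 0.03, n_patches = 12),
    scenarios = default_scenarios(),
    seed = seed, out_dir = out_dir)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Default future-scenario deltas
#'
#' Shifted/scaled layer stand-ins for three emission pathways by three
#' periods: warming grows with forcing (0.8, 1.6, 2.8 units of bio9 by
#' 2090 for SSP126/245/585) and through time (50, 75, 100 percent of the
#' end-of-century shift by 2050/2070/2090); diurnal range and temperature
#' seasonality rise with warming, precipitation-like layers shrink
#' slightly.
#'
#' @return Named list of [scenario_delta()]s keyed "SSPxxx-year".
#' @export
default_scenarios <- function() {
  forcing <- c(SSP126 = 0.8, SSP245 = 1.6, SSP585 = 2.8)
  frac <- c(`2050` = 0.5, `2070` = 0.75, `2090` = 1.0)
  out <- list()
  for (s in names(forcing)) for (p in names(frac)) {
    w <- forcing[[s]] * frac[[p]]
    out[[paste0(s, "-", p)]] <- scenario_delta(
      label = paste0(s, "-", p),
      shift = c(bio9 = w, bio2 = 0.3 * w),
      scale = c(bio4 = 1 + 0.04 * w, bio12 = 1 - 0.02 * w,
                bio17 = 1 - 0.03 * w))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes the stages in study order: synthetic world (or user rasters)
#' -> occurrence thinning -> variable screening -> model selection ->
#' current prediction -> scenario projections -> classification and area
#' dynamics -> niche metrics -> protected-area gap analysis -> centroid
#' tracks. Every stochastic step is seeded from `config$seed`; rerunning
#' the same config reproduces every output byte for byte.
#'
#' @param config A [default_run_config()]-style list.
#' @return Invisibly, a `nichecast_run` list: `manifest` (config echo,
#'   chosen settings, timings, file index) plus all result objects
#'   (`stack`, per-species `models`, `current_maps`, `area_tables`,
#'   `niche`, `gap`, `centroids`, `tuning`, `screening`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, expr) {
    st <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    out
  }
  seed <- config$seed

  stack <- tick("world", {
    sy <- config$synthetic
    generate_env_stack(sy$n_rows, sy$n_cols, sy$cell_size, sy$origin,
                       sy$var_specs, sy$target_corr, seed = seed)
  })

  occs <- tick("occurrences", {
    out <- list()
    for (i in seq_along(config$species)) {
      sp <- config$species[i]
      truth <- true_suitability(config$truths[[sp]], stack)
      occ <- sample_occurrences(truth, config$n_presence[[sp]],
                                seed = seed + 1000 + i,
                                noise = config$synthetic$noise, species = sp)
      out[[sp]] <- thin_to_grid(occ, stack$grid, stack$mask)
      message(sprintf("[occurrences] %s: %d records after thinning", sp,
                      nrow(out[[sp]])))
    }
    out
  })

  screening <- tick("screening", {
    lapply(stats::setNames(config$species, config$species), function(sp) {
      sc <- screen_variables(occs[[sp]], stack,
                             threshold = config$pearson_threshold,
                             seed = seed + 2000)
      message(sprintf("[screening] %s: retained %d/%d variables (%s)", sp,
                      length(sc$retained), length(stack$layers),
                      paste(sc$retained, collapse = ", ")))
      sc
    })
  })

  tuning <- list()
  models <- tick("model_selection", {
    out <- list()
    for (sp in config$species) {
      sub <- select_layers(stack, screening[[sp]]$retained)
      if (isTRUE(config$tune)) {
        tr <- tune_sdm(occs[[sp]], sub, rm_grid = config$rm_grid,
                       fc_grid = config$fc_grid, seed = seed + 3000)
        tuning[[sp]] <<- tr
        ch <- chosen_setting(tr)
        message(sprintf("[tuning] %s: chose FC=%s RM=%g (k=%d, AICc=%.2f)",
                        sp, ch$fc, ch$rm, ch$k, ch$aicc))
        out[[sp]] <- attr(tr, "chosen_model")
      } else {
        out[[sp]] <- fit_sdm(occs[[sp]], sub, fc = config$fixed_fc,
                             rm = config$fixed_rm, seed = seed + 3000)
      }
    }
    out
  })

  stacks_by_species <- lapply(stats::setNames(config$species, config$species),
                              function(sp) select_layers(stack,
                                                         screening[[sp]]$retained))

  current_maps <- tick("current_prediction", {
    lapply(stats::setNames(config$species, config$species), function(sp) {
      predict(models[[sp]], stacks_by_species[[sp]], transform = "cloglog")
    })
  })

  future_maps <- tick("projection", {
    lapply(stats::setNames(config$species, config$species), function(sp) {
      vars <- names(stacks_by_species[[sp]]$layers)
      lapply(config$scenarios, function(d) {
        # screening may have pruned layers a scenario names; restrict the
        # delta to the species' retained variables
        d_sp <- scenario_delta(d$label,
                               shift = d$shift[names(d$shift) %in% vars],
                               scale = d$scale[names(d$scale) %in% vars])
        project_future(models[[sp]],
                       make_future_stack(stacks_by_species[[sp]], d_sp))
      })
    })
  })

  area_tables <- tick("areas", {
    lapply(stats::setNames(config$species, config$species), function(sp) {
      area_dynamics(current_maps[[sp]], future_maps[[sp]], cuts = config$cuts)
    })
  })

  niche <- tick("niche_metrics",
                niche_metrics(current_maps, threshold = config$range_threshold))

  gap <- tick("gap_analysis", {
    cms <- lapply(current_maps, classify_suitability, cuts = config$cuts)
    prio <- priority_areas(cms, min_species = config$min_species)
    pa <- generate_pa_mask(stack$grid, config$pa$coverage, config$pa$n_patches,
                           seed = seed + 4000)
    rep <- gap_analysis(prio, pa, stack$grid)
    message(sprintf("[gap] priority %.2f, protected %.2f (x10^4 km^2), %.2f%% unprotected",
                    rep$priority_area, rep$protected_overlap,
                    rep$percent_unprotected))
    list(report = rep, priority = prio, pa = pa)
  })

  centroids <- tick("centroids", {
    scen_names <- unique(sub("-[^-]+$", "", names(config$scenarios)))
    purrr::map_dfr(config$species, function(sp) {
      purrr::map_dfr(scen_names, function(sc) {
        fm <- future_maps[[sp]][grep(paste0("^", sc, "-"),
                                     names(future_maps[[sp]]))]
        dplyr::mutate(centroid_track(current_maps[[sp]], fm, scenario = sc,
                                     mask_threshold = config$centroid_threshold),
                      species = sp, .before = 1)
      })
    })
  })

  files <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, name) {
      p <- file.path(config$out_dir, name)
      readr::write_csv(df, p)
      files <<- c(files, p)
    }
    for (sp in config$species) {
      wcsv(area_tables[[sp]], paste0("areas_", sp, ".csv"))
      write_raster(env_layer(paste0("hsi_", sp), stack$grid,
                             current_maps[[sp]]$values,
                             current_maps[[sp]]$mask),
                   file.path(config$out_dir, paste0("hsi_", sp, ".asc")))
      files <- c(files, file.path(config$out_dir, paste0("hsi_", sp, ".asc")))
      if (!is.null(tuning[[sp]])) {
        wcsv(tidy(tuning[[sp]]), paste0("tuning_", sp, ".csv"))
      }
      wcsv(screening[[sp]]$contrib, paste0("contributions_", sp, ".csv"))
    }
    wcsv(niche_metrics_table(niche), "niche_metrics.csv")
    wcsv(centroids, "centroid_tracks.csv")
    jsonlite::write_json(gap$report, file.path(config$out_dir,
                                               "gap_report.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(config$out_dir, "gap_report.json"))
  }

  manifest <- list(
    seed = seed,
    species = config$species,
    n_presence = as.list(config$n_presence),
    chosen = lapply(models, function(m) list(fc = m$fc, rm = m$rm,
                                             k = sum(abs(m$lambda) > 1e-12))),
    timings = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = files)
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(structure(
    list(manifest = manifest, config = config, stack = stack, occurrences = occs,
         screening = screening, tuning = tuning, models = models,
         current_maps = current_maps, future_maps = future_maps,
         area_tables = area_tables, niche = niche, gap = gap,
         centroids = centroids),
    class = "nichecast_run"))
}

#' @export
print.nichecast_run <- function(x, ...) {
  cat("<nichecast_run>", length(x$config$species), "species, seed",
      x$config$seed, sprintf("(%.1f s)\n", x$manifest$total_seconds))
  for (sp in x$config$species) {
    ch <- x$manifest$chosen[[sp]]
    cat(sprintf("  %s: FC=%s RM=%g k=%d, current total suitable %.2f x10^4 km^2\n",
                sp, ch$fc, ch$rm, ch$k,
                x$area_tables[[sp]]$total_suitable[
                  x$area_tables[[sp]]$period == "current"][1]))
  }
  invisible(x)
}
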