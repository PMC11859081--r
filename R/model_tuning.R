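#' AICc of a maxent model (landscape-normalized likelihood)
#'
#' Warren-Seifert formulation: raw predictions are renormalized to sum to 1
#' over the full valid grid, the log-likelihood is the sum of log
#' normalized raw values at the presence cells, `k` counts nonzero
#' coefficients (|lambda| > 1e-12), and
#' `AICc = 2k - 2 lnL + 2k(k + 1)/(n - k - 1)` with `n` the presence
#' count. Rows with `n - k - 1 <= 0` are flagged invalid (`aicc = NA`).
#'
#' @param model A `maxent_model`.
#' @param occ Presence tibble (`lon`, `lat`).
#' @param stack The `env_stack` defining the landscape.
#' @return A one-row tibble: `lnL`, `k`, `n`, `aicc`, `valid`.
#' @export
aicc <- function(model, occ, stack) {
  n <- nrow(occ)
  if (n < 2) stop("need at least 2 presences", call. = FALSE)
  pred <- predict(model, stack, transform = "raw")
  p_mat <- pred$values / sum(pred$values[pred$mask])
  pc <- occurrence_cells(occ, stack$grid)
  if (any(is.na(pc$row))) {
    stop("presence record(s) outside the grid extent", call. = FALSE)
  }
  lp <- log(p_mat[cbind(pc$row, pc$col)])
  if (any(is.na(lp))) {
    stop("presence record(s) on nodata cells", call. = FALSE)
  }
  lnL <- sum(lp)
  k <- sum(abs(model$lambda) > 1e-12)
  valid <- (n - k - 1) > 0
  aicc_val <- if (valid) 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1) else
    NA_real_
  tibble::tibble(lnL = lnL, k = k, n = n, aicc = aicc_val, valid = valid)
}

#' Tune maxent hyperparameters by AICc
#'
#' ENMeval-style grid search: fits every (feature combination,
#' regularization multiplier) candidate on the full presence set, computes
#' the landscape-normalized AICc, and selects the candidate with
#' `delta_aicc = 0` (ties broken by smaller k, then smaller rm, then FC
#' order). Replicate test AUC (10 random 75/25 presence splits) is computed
#' for the chosen model only.
#'
#' @param occ Thinned presence tibble.
#' @param stack Screened `env_stack`.
#' @param rm_grid Regularization multipliers (default 0.5 to 4 step 0.5).
#' @param fc_grid Feature combinations (default all six).
#' @param seed Seed governing background sampling, coordinate order, and
#'   replicate splits.
#' @param n_rep Replicates for the winner's test AUC (default 10; 0 skips).
#' @param ... Passed to [fit_sdm()].
#' @return An object of class `tuning_result`: a tibble of candidate rows
#'   (`fc`, `rm`, `k`, `lnL`, `aicc`, `delta_aicc`, `valid`,
#'   `mean_test_auc`) with attributes `chosen` (row index) and
#'   `chosen_model` (the refitted winner).
#' @export
tune_sdm <- function(occ, stack, rm_grid = seq(0.5, 4, by = 0.5),
                     fc_grid = FC_LEVELS, seed = 0, n_rep = 10, ...) {
  grid <- tidyr::expand_grid(fc = factor(fc_grid, levels = fc_grid),
                             rm = rm_grid) |>
    dplyr::arrange(.data$fc, .data$rm) |>
    dplyr::mutate(fc = as.character(.data$fc))
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))

  dots <- list(...)
  bg_max <- dots$bg_max %||% 10000
  tol <- dots$tol %||% 1e-5
  max_cycles <- dots$max_cycles %||% 2000
  nh <- dots$n_hinge_knots %||% 10
  nt <- dots$n_threshold_knots %||% 10

  pres <- occurrence_cells(occ, stack$grid)
  if (any(is.na(pres$row))) {
    stop("presence record(s) outside the grid extent", call. = FALSE)
  }
  on_valid <- stack$mask[cbind(pres$row, pres$col)]
  if (any(!on_valid)) {
    message("tune_sdm: dropped ", sum(!on_valid),
            " presence record(s) off the valid grid")
    pres <- pres[on_valid, ]
  }
  n <- nrow(pres)
  cells <- valid_cell_ids(stack)
  bg_cells <- if (length(cells) > bg_max) {
    withr::with_seed(seed, sort(sample(cells, bg_max)))
  } else cells
  Xb <- stack_matrix(stack, bg_cells)
  Xp <- stack_matrix(stack, pres$cell)
  Xg <- stack_matrix(stack, cells)
  pres_idx <- match(pres$cell, cells)

  # walk each FC's RM path from most to least regularized, warm-starting
  # successive fits from the previous solution (the regularization-path
  # convention); features and the landscape feature matrix are built once
  # per FC. Results are deterministic under the seed.
  for (fc in fc_grid) {
    fb <- build_features(Xb, fc, nh, nt)
    Fp <- eval_features(fb$specs, fb$anchors, Xp, clamp = TRUE)
    Fg <- eval_features(fb$specs, fb$anchors, Xg, clamp = TRUE)
    warm <- NULL
    for (rm in sort(rm_grid, decreasing = TRUE)) {
      i <- which(grid$fc == fc & grid$rm == rm)
      fit <- fit_maxent(Fp, fb$features, fc = fc, rm = rm, specs = fb$specs,
                        anchors = fb$anchors, tol = tol,
                        max_cycles = max_cycles, seed = seed,
                        var_means = colMeans(Xb), lambda_init = warm)
      warm <- fit$lambda
      fits[[i]] <- fit
      raw <- exp(as.vector(Fg %*% fit$lambda) - fit$log_Z)
      p <- raw / sum(raw)
      lnL <- sum(log(p[pres_idx]))
      k <- sum(abs(fit$lambda) > 1e-12)
      valid <- (n - k - 1) > 0
      rows[[i]] <- dplyr::bind_cols(
        grid[i, ],
        tibble::tibble(lnL = lnL, k = k, n = n,
                       aicc = if (valid) 2 * k - 2 * lnL +
                         2 * k * (k + 1) / (n - k - 1) else NA_real_,
                       valid = valid))
    }
  }
  tab <- dplyr::bind_rows(rows)
  if (!any(tab$valid)) stop("all tuning candidates invalid (k >= n - 1)",
                            call. = FALSE)
  min_aicc <- min(tab$aicc[tab$valid])
  tab$delta_aicc <- ifelse(tab$valid, tab$aicc - min_aicc, NA_real_)
  cand <- which(tab$valid & tab$delta_aicc == 0)
  if (length(cand) > 1) {
    o <- order(tab$k[cand], tab$rm[cand],
               match(tab$fc[cand], fc_grid))
    cand <- cand[o]
  }
  chosen <- cand[1]
  tab$mean_test_auc <- NA_real_
  if (n_rep > 0) {
    reps <- replicate_auc(occ, stack, fc = tab$fc[chosen], rm = tab$rm[chosen],
                          n_rep = n_rep, seed_base = seed, ...)
    tab$mean_test_auc[chosen] <- mean(reps$auc_test)
    attr(tab, "replicates") <- reps
  }
  attr(tab, "chosen") <- chosen
  attr(tab, "chosen_model") <- fits[[chosen]]
  class(tab) <- c("tuning_result", class(tab))
  tab
}

#' Chosen row of a tuning result
#'
#' @param result A `tuning_result`.
#' @return One-row tibble for the delta-AICc = 0 candidate.
#' @export
chosen_setting <- function(result) {
  result[attr(result, "chosen"), , drop = FALSE]
}

#' @method tidy tuning_result
#' @export
tidy.tuning_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$chosen <- seq_len(nrow(out)) == attr(x, "chosen")
  out
}

#' @method glance tuning_result
#' @export
glance.tuning_result <- function(x, ...) {
  ch <- chosen_setting(x)
  tibble::tibble(n_candidates = nrow(x), n_valid = sum(x$valid),
                 fc = ch$fc, rm = ch$rm, k = ch$k, aicc = ch$aicc,
                 mean_test_auc = ch$mean_test_auc)
}

#' Plot a tuning surface
#'
#' @param object A `tuning_result`.
#' @param ... Unused.
#' @return A ggplot of delta AICc against RM, one line per FC.
#' @method autoplot tuning_result
#' @export
autoplot.tuning_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$rm, .data$delta_aicc,
                                   color = .data$fc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = df[df$chosen, ], size = 3, shape = 1) +
    ggplot2::labs(x = "Regularization multiplier",
                  y = expression(Delta * "AICc"), color = "FC")
}
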