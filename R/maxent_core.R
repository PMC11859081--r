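#' @useDynLib nichecast, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom tibble as_tibble
#' @importFrom ggplot2 autoplot
#' @importFrom generics tidy glance
NULL

FC_LEVELS <- c("L", "H", "LQ", "LQH", "LQPH", "LQPHT")

fc_classes <- function(fc) {
  fc <- match.arg(fc, FC_LEVELS)
  strsplit(fc, "")[[1]]
}

#' Build a maxent feature expansion
#'
#' Expands raw variable values into the feature classes named by `fc`
#' (subsets of Linear, Quadratic, Product, Hinge, Threshold). Base
#' variables are min-max scaled to \[0, 1\] using background min/max
#' anchors; L is the scaled value, Q its square, P pairwise products of
#' scaled variables, forward/reverse hinges `max(0, (v - k)/(max - k))` and
#' `max(0, (k - v)/(k - min))`, and thresholds `1[v > k]`, with knots at
#' equally spaced quantiles of the background values. Every feature lies in
#' \[0, 1\].
#'
#' @param X Numeric matrix of background variable values (cells x
#'   variables, named columns).
#' @param fc Feature combination: one of `"L"`, `"H"`, `"LQ"`, `"LQH"`,
#'   `"LQPH"`, `"LQPHT"`.
#' @param n_hinge_knots,n_threshold_knots Knots per variable and hinge
#'   direction (default 10).
#' @return A list with `specs` (tibble: kind, var1, var2, knot), `anchors`
#'   (tibble: variable, min, max), and `features` (matrix over `X`'s rows).
#' @export
build_features <- function(X, fc, n_hinge_knots = 10, n_threshold_knots = 10) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  classes <- fc_classes(fc)
  rng <- apply(X, 2, range)
  const <- rng[1, ] == rng[2, ]
  if (any(const)) {
    warning("constant variable(s) excluded from feature expansion: ",
            paste(colnames(X)[const], collapse = ", "), call. = FALSE)
    X <- X[, !const, drop = FALSE]
    rng <- rng[, !const, drop = FALSE]
  }
  vars <- colnames(X)
  anchors <- tibble::tibble(variable = vars, min = rng[1, ], max = rng[2, ])
  specs <- list()
  add <- function(kind, v1, v2 = NA_character_, knot = NA_real_) {
    specs[[length(specs) + 1]] <<- tibble::tibble(
      kind = kind, var1 = v1, var2 = v2, knot = knot)
  }
  if ("L" %in% classes) for (v in vars) add("linear", v)
  if ("Q" %in% classes) for (v in vars) add("quadratic", v)
  if ("P" %in% classes && length(vars) >= 2) {
    cmb <- utils::combn(vars, 2)
    for (i in seq_len(ncol(cmb))) add("product", cmb[1, i], cmb[2, i])
  }
  knot_seq <- function(v, n) {
    ks <- stats::quantile(X[, v], probs = seq_len(n) / (n + 1), names = FALSE,
                          type = 7)
    lo <- anchors$min[anchors$variable == v]
    hi <- anchors$max[anchors$variable == v]
    unique(ks[ks > lo & ks < hi])
  }
  if ("H" %in% classes) {
    for (v in vars) for (k in knot_seq(v, n_hinge_knots)) {
      add("hinge_fwd", v, knot = k)
      add("hinge_rev", v, knot = k)
    }
  }
  if ("T" %in% classes) {
    for (v in vars) for (k in knot_seq(v, n_threshold_knots)) {
      add("threshold", v, knot = k)
    }
  }
  specs <- dplyr::bind_rows(specs)
  list(specs = specs, anchors = anchors,
       features = eval_features(specs, anchors, X, clamp = FALSE))
}

#' Evaluate feature specs on new data
#'
#' @param specs,anchors From [build_features()].
#' @param X Cells-x-variables matrix with all anchor variables.
#' @param clamp Clamp variables to the training \[min, max\] first
#'   (default TRUE; the projection contract).
#' @return Feature matrix (rows of `X` x features).
#' @export
eval_features <- function(specs, anchors, X, clamp = TRUE) {
  missing <- setdiff(anchors$variable, colnames(X))
  if (length(missing)) {
    stop("data lacks model variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lo <- stats::setNames(anchors$min, anchors$variable)
  hi <- stats::setNames(anchors$max, anchors$variable)
  V <- X[, anchors$variable, drop = FALSE]
  if (clamp) {
    for (v in anchors$variable) {
      V[, v] <- pmin(pmax(V[, v], lo[[v]]), hi[[v]])
    }
  }
  U <- sweep(sweep(V, 2, lo[colnames(V)]), 2, hi[colnames(V)] - lo[colnames(V)],
             "/")
  n <- nrow(V)
  Fm <- matrix(0, n, nrow(specs))
  for (j in seq_len(nrow(specs))) {
    kind <- specs$kind[j]; v1 <- specs$var1[j]
    Fm[, j] <- switch(
      kind,
      linear = U[, v1],
      quadratic = U[, v1]^2,
      product = U[, v1] * U[, specs$var2[j]],
      hinge_fwd = pmax(0, (V[, v1] - specs$knot[j]) /
                         (hi[[v1]] - specs$knot[j])),
      hinge_rev = pmax(0, (specs$knot[j] - V[, v1]) /
                         (specs$knot[j] - lo[[v1]])),
      threshold = as.numeric(V[, v1] > specs$knot[j]),
      stop("unknown feature kind: ", kind)
    )
  }
  Fm
}

# per-feature regularization: beta_j = rm * beta_class(m) * s_j / sqrt(m),
# with s_j the presence sd of the feature floored at 0.05 (features span
# [0, 1]) and beta_class interpolated from the published default tables.
beta_class_value <- function(kind, m) {
  tab <- switch(kind,
                linear = , quadratic = list(x = c(10, 30, 100), y = c(1.0, 0.2, 0.05)),
                product = list(x = c(10, 30, 100), y = c(0.5, 0.3, 0.1)),
                hinge_fwd = , hinge_rev = list(x = c(10, 10, 10), y = c(0.5, 0.5, 0.5)),
                threshold = list(x = c(10, 30, 100), y = c(2.0, 1.5, 1.0)))
  if (kind %in% c("hinge_fwd", "hinge_rev")) return(0.5)
  stats::approx(tab$x, tab$y, xout = m, rule = 2)$y
}

feature_betas <- function(specs, Fp, rm) {
  m <- nrow(Fp)
  sj <- apply(Fp, 2, stats::sd)
  sj <- pmax(sj, 0.05)
  bc <- vapply(specs$kind, beta_class_value, numeric(1), m = m)
  rm * bc * sj / sqrt(m)
}

#' Fit an L1-regularized maximum-entropy model
#'
#' Maximizes the penalized presence log-gain
#' `F(lambda) = mean_presence(lambda . f) - ln Z(lambda) - sum_j beta_j |lambda_j|`
#' with `Z` summed over the background, by cyclic coordinate descent with
#' Newton/soft-threshold one-dimensional updates (compiled core). The
#' per-feature penalty is `beta_j = rm * beta_class(m) * s_j / sqrt(m)`
#' with `m` the presence count, `s_j` the presence sd of feature j (floored
#' at 0.05), and `beta_class` interpolated per feature class from the
#' published default tables. The regularized training gain
#' `G = ln(n_background) + F(lambda)` is recorded per cycle and is
#' non-decreasing by construction.
#'
#' @param presence_features,background_features Feature matrices from
#'   [build_features()]/[eval_features()].
#' @param fc,rm Feature-combination label and regularization multiplier
#'   (metadata; `rm` scales the penalty).
#' @param specs,anchors Feature specs and scaling anchors (stored on the
#'   model for prediction).
#' @param tol Convergence tolerance on penalized-gain improvement per full
#'   cycle (default 1e-5).
#' @param max_cycles Cycle budget (default 2000); non-convergence sets a
#'   warning flag on the model, it is not an error.
#' @param seed Seed for the (shuffled) coordinate visit order.
#' @param var_means Named background means of the raw variables (stored for
#'   response curves).
#' @param lambda_init Optional warm-start coefficient vector (used by the
#'   tuning path across the RM grid). Gain-credit bookkeeping then reflects
#'   the warm-started path, so percent contributions are only meaningful
#'   for cold fits.
#' @return An object of class `maxent_model`.
#' @export
fit_maxent <- function(presence_features, background_features, fc = "LQ",
                       rm = 1, specs = NULL, anchors = NULL, tol = 1e-5,
                       max_cycles = 2000, seed = 0, var_means = NULL,
                       lambda_init = NULL) {
  Fp <- as.matrix(presence_features)
  Fb <- as.matrix(background_features)
  if (any(!is.finite(Fp)) || any(!is.finite(Fb))) {
    stop("non-finite feature values", call. = FALSE)
  }
  if (nrow(Fp) < 2) stop("need at least 2 presence points", call. = FALSE)
  if (nrow(Fb) < 10) stop("need at least 10 background points", call. = FALSE)
  stopifnot(ncol(Fp) == ncol(Fb))
  beta <- feature_betas(specs %||% tibble::tibble(kind = rep("linear", ncol(Fp))),
                        Fp, rm)
  res <- withr::with_seed(seed,
    maxent_cd_cpp(Fp, Fb, beta, tol, as.integer(max_cycles), 2.0,
                  lambda_init))
  if (!res$converged) {
    warning("maxent fit did not converge in ", max_cycles, " cycles",
            call. = FALSE)
  }
  structure(list(
    specs = specs, anchors = anchors, lambda = as.numeric(res$lambda),
    fc = fc, rm = rm, log_Z = res$logZ, H_entropy = res$H,
    gain = res$gain, gain_trace = as.numeric(res$gain_trace),
    credit = as.numeric(res$credit), beta = beta,
    bg_weights = as.numeric(res$w),
    n_presence = nrow(Fp), n_background = nrow(Fb),
    converged = res$converged, cycles = res$cycles, seed = seed,
    var_means = var_means), class = "maxent_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("<maxent_model> FC=%s RM=%g: %d features (%d nonzero), ",
                     "gain %.4f, H %.3f, n_presence %d, n_background %d\n"),
              x$fc, x$rm, length(x$lambda), sum(abs(x$lambda) > 1e-12),
              x$gain, x$H_entropy, x$n_presence, x$n_background))
  invisible(x)
}

#' Fit a maxent model from occurrences and a stack
#'
#' High-level fitting surface: extracts presence cell values, draws the
#' background (all jointly valid cells if at most `bg_max`, otherwise a
#' seeded uniform sample of `bg_max`), builds the feature expansion, and
#' calls [fit_maxent()].
#'
#' @param occ Thinned occurrence tibble (`species`, `lon`, `lat`).
#' @param stack Screened `env_stack`.
#' @param fc,rm Feature combination and regularization multiplier.
#' @param bg_max Background cap (default 10000).
#' @param n_hinge_knots,n_threshold_knots Knots per variable (default 10).
#' @param tol,max_cycles,seed Passed to [fit_maxent()].
#' @param lambda_init Optional warm-start coefficients (see [fit_maxent()]).
#' @return A `maxent_model`.
#' @export
fit_sdm <- function(occ, stack, fc = "LQ", rm = 1, bg_max = 10000,
                    n_hinge_knots = 10, n_threshold_knots = 10,
                    tol = 1e-5, max_cycles = 2000, seed = 0,
                    lambda_init = NULL) {
  pres <- occurrence_cells(occ, stack$grid)
  on_valid <- !is.na(pres$row) &
    stack$mask[cbind(pres$row, pres$col)]
  if (any(!on_valid)) {
    message("fit_sdm: dropped ", sum(!on_valid),
            " presence record(s) off the valid grid")
  }
  pres <- pres[on_valid, ]
  cells <- valid_cell_ids(stack)
  bg_cells <- if (length(cells) > bg_max) {
    withr::with_seed(seed, sort(sample(cells, bg_max)))
  } else cells
  Xb <- stack_matrix(stack, bg_cells)
  Xp <- stack_matrix(stack, pres$cell)
  fb <- build_features(Xb, fc, n_hinge_knots, n_threshold_knots)
  Fp <- eval_features(fb$specs, fb$anchors, Xp, clamp = TRUE)
  fit_maxent(Fp, fb$features, fc = fc, rm = rm, specs = fb$specs,
             anchors = fb$anchors, tol = tol, max_cycles = max_cycles,
             seed = seed, var_means = colMeans(Xb), lambda_init = lambda_init)
}

#' Predict habitat suitability over a stack
#'
#' Variables are clamped to the training \[min, max\] before feature
#' evaluation; the raw Gibbs density is `r(x) = exp(lambda . f(x)) / Z`
#' with the training normalizer, and the default cloglog habitat
#' suitability index is `1 - exp(-exp(H) * r(x))` with `H` the training
#' entropy. Values are clipped to \[0, 1\].
#'
#' @param object A `maxent_model`.
#' @param stack An `env_stack` carrying all model variables.
#' @param transform `"cloglog"` (default), `"logistic"`, or `"raw"`.
#' @param clamp Clamp to training ranges (default TRUE).
#' @param ... Unused.
#' @return A `suitability_map`.
#' @export
predict.maxent_model <- function(object, stack, transform = c("cloglog",
                                 "logistic", "raw"), clamp = TRUE, ...) {
  transform <- match.arg(transform)
  cells <- valid_cell_ids(stack)
  X <- stack_matrix(stack, cells)
  Fm <- eval_features(object$specs, object$anchors, X, clamp = clamp)
  raw <- exp(as.vector(Fm %*% object$lambda) - object$log_Z)
  vals <- switch(transform,
    raw = raw,
    cloglog = pmin(pmax(1 - exp(-exp(object$H_entropy) * raw), 0), 1),
    logistic = {
      er <- exp(object$H_entropy) * raw
      pmin(pmax(er / (1 + er), 0), 1)
    })
  m <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  mt <- t(m)
  mt[cells] <- vals
  m <- t(mt)
  suitability_map(stack$grid, m, stack$mask, transform = transform,
                  label = attr(stack, "scenario"))
}

#' Percent contribution per variable
#'
#' Credits each coordinate-descent update's penalized-gain change to the
#' updated feature's variable(s) (split equally for products), floors
#' negatives at zero, and normalizes to sum 100.
#'
#' @param model A `maxent_model` fitted by this package (the training trace
#'   is recorded during fitting).
#' @return A tibble with `variable` and `contribution` (percent), in
#'   anchor-variable order.
#' @export
percent_contribution <- function(model) {
  if (is.null(model$credit) || is.null(model$specs)) {
    stop("model carries no training trace", call. = FALSE)
  }
  vars <- model$anchors$variable
  acc <- stats::setNames(numeric(length(vars)), vars)
  for (j in seq_along(model$credit)) {
    g <- max(model$credit[j], 0)
    v1 <- model$specs$var1[j]; v2 <- model$specs$var2[j]
    if (!is.na(v2)) {
      acc[v1] <- acc[v1] + g / 2
      acc[v2] <- acc[v2] + g / 2
    } else {
      acc[v1] <- acc[v1] + g
    }
  }
  tot <- sum(acc)
  pct <- if (tot > 0) 100 * acc / tot else acc * 0
  tibble::tibble(variable = vars, contribution = as.numeric(pct))
}

#' Jackknife variable importance
#'
#' Refits the model with each variable alone and with each variable left
#' out (2V + 1 fits) and reports regularized training gains.
#'
#' @param occ,stack,fc,rm,seed As in [fit_sdm()].
#' @param ... Further arguments to [fit_sdm()].
#' @return A tibble with `variable`, `gain_with_only`, `gain_without`, and
#'   `gain_all`; failed refits yield NA in the affected cell.
#' @export
jackknife_importance <- function(occ, stack, fc = "LQ", rm = 1, seed = 0, ...) {
  vars <- names(stack$layers)
  if (length(vars) < 2) stop("need at least 2 variables", call. = FALSE)
  safe_gain <- function(v) {
    tryCatch(fit_sdm(occ, select_layers(stack, v), fc = fc, rm = rm,
                     seed = seed, ...)$gain,
             error = function(e) NA_real_)
  }
  gain_all <- fit_sdm(occ, stack, fc = fc, rm = rm, seed = seed, ...)$gain
  tibble::tibble(
    variable = vars,
    gain_with_only = vapply(vars, function(v) safe_gain(v), numeric(1)),
    gain_without = vapply(vars, function(v) safe_gain(setdiff(vars, v)),
                          numeric(1)),
    gain_all = gain_all)
}

#' Response curve of one variable
#'
#' Sweeps the variable across its background \[min, max\] while holding all
#' other variables at their background means, and returns the cloglog
#' response.
#'
#' @param model A `maxent_model` (fitted via [fit_sdm()], which stores the
#'   background means).
#' @param variable Variable name.
#' @param n_points Grid resolution (default 100).
#' @return A tibble with `value` and `response`.
#' @export
response_curve <- function(model, variable, n_points = 100) {
  if (!variable %in% model$anchors$variable) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  if (is.null(model$var_means)) {
    stop("model lacks stored background means", call. = FALSE)
  }
  a <- model$anchors[model$anchors$variable == variable, ]
  xs <- seq(a$min, a$max, length.out = n_points)
  X <- matrix(rep(model$var_means[model$anchors$variable], each = n_points),
              nrow = n_points,
              dimnames = list(NULL, model$anchors$variable))
  X[, variable] <- xs
  Fm <- eval_features(model$specs, model$anchors, X, clamp = TRUE)
  raw <- exp(as.vector(Fm %*% model$lambda) - model$log_Z)
  tibble::tibble(value = xs,
                 response = pmin(pmax(1 - exp(-exp(model$H_entropy) * raw), 0), 1))
}

#' Presence-background AUC
#'
#' Rank-based Mann-Whitney estimator of the area under the ROC curve, with
#' ties counted one half.
#'
#' @param scores_presence,scores_background Numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores_presence, scores_background) {
  np <- length(scores_presence); nb <- length(scores_background)
  if (np == 0 || nb == 0) stop("empty score set", call. = FALSE)
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Replicate test AUC by presence subsampling
#'
#' Emulates replicate runs: `n_rep` random 75/25 presence splits (seeds
#' `seed_base + 0:(n_rep-1)`), refitting on the training side and scoring
#' the held-out presences against the background.
#'
#' @param occ,stack,fc,rm As in [fit_sdm()].
#' @param n_rep Number of replicates (default 10).
#' @param train_frac Training fraction (default 0.75).
#' @param seed_base First replicate seed (default 0).
#' @param ... Passed to [fit_sdm()].
#' @return A tibble with `replicate`, `seed`, `auc_test`.
#' @export
replicate_auc <- function(occ, stack, fc = "LQ", rm = 1, n_rep = 10,
                          train_frac = 0.75, seed_base = 0, ...) {
  n <- nrow(occ)
  purrr::map_dfr(seq_len(n_rep), function(i) {
    sd <- seed_base + i - 1
    idx <- withr::with_seed(sd, sample(n, max(2, round(train_frac * n))))
    fit <- fit_sdm(occ[idx, ], stack, fc = fc, rm = rm, seed = sd, ...)
    test <- occ[-idx, ]
    pred <- predict(fit, stack, transform = "cloglog")
    pc <- occurrence_cells(test, stack$grid)
    ok <- !is.na(pc$row) & stack$mask[cbind(pc$row, pc$col)]
    sp <- pred$values[cbind(pc$row[ok], pc$col[ok])]
    sb <- pred$values[pred$mask]
    tibble::tibble(replicate = i, seed = sd, auc_test = auc_score(sp, sb))
  })
}

#' @method tidy maxent_model
#' @export
tidy.maxent_model <- function(x, ...) {
  dplyr::bind_cols(x$specs,
                   tibble::tibble(estimate = x$lambda, penalty = x$beta))
}

#' @method glance maxent_model
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(fc = x$fc, rm = x$rm, n_features = length(x$lambda),
                 k = sum(abs(x$lambda) > 1e-12), gain = x$gain,
                 entropy = x$H_entropy, n_presence = x$n_presence,
                 n_background = x$n_background, converged = x$converged,
                 cycles = x$cycles)
}

#' Plot response curves for the top variables of a model
#'
#' @param model A `maxent_model`.
#' @param variables Variables to plot (default: all model variables).
#' @param n_points Curve resolution.
#' @return A ggplot.
#' @export
plot_response_curves <- function(model, variables = NULL, n_points = 100) {
  variables <- variables %||% model$anchors$variable
  df <- purrr::map_dfr(variables, function(v) {
    dplyr::mutate(response_curve(model, v, n_points), variable = v)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$response)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Variable value", y = "Suitability (cloglog)")
}
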