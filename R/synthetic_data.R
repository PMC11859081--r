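#' Synthetic environmental worlds
#'
#' Generators for correlated, spatially smooth environmental raster stacks,
#' a known species-environment response, presence samples, future-scenario
#' stacks, and protected-area masks. Everything is deterministic under a
#' single integer seed, so every downstream stage of the pipeline can be
#' exercised and verified without external data.
#'
#' @name synthetic_data
NULL

# separable gaussian blur with edge renormalization
smooth_field <- function(w, sd_cells) {
  if (sd_cells <= 0) return(w)
  sm <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-0.5 * (d / sd_cells)^2)
    k / rowSums(k)
  }
  sm(nrow(w)) %*% w %*% t(sm(ncol(w)))
}

#' Generate a correlated synthetic environmental stack
#'
#' Each variable is a smooth random field: white noise is low-pass filtered
#' (separable Gaussian kernel, `smoothness` = kernel sd in cells), the
#' fields are mixed through a Cholesky factor of `target_corr` so their
#' cell-wise correlations approximate the target, and each is rescaled to
#' the requested mean and sd.
#'
#' @param n_rows,n_cols,cell_size,origin Grid geometry; `origin` is
#'   `c(x_min, y_min)`. Defaults give the package's study window:
#'   120 x 90 cells at 0.25 deg, lon 92-122E, lat 18.5-41N.
#' @param var_specs Tibble/data frame with columns `name`, `mean`, `sd`,
#'   and optionally `smoothness` (cells, default 6).
#' @param target_corr Correlation matrix across variables (symmetric PSD,
#'   unit diagonal), or NULL for independent fields.
#' @param seed Integer seed; the stack is a pure function of it.
#' @return An [assemble_stack()] result (`env_stack`).
#' @export
generate_env_stack <- function(n_rows = 90, n_cols = 120, cell_size = 0.25,
                               origin = c(92, 18.5),
                               var_specs = default_var_specs(),
                               target_corr = default_target_corr(nrow(var_specs)),
                               seed = 0) {
  var_specs <- tibble::as_tibble(var_specs)
  stopifnot(all(c("name", "mean", "sd") %in% names(var_specs)))
  v <- nrow(var_specs)
  if (!"smoothness" %in% names(var_specs)) var_specs$smoothness <- 6
  if (is.null(target_corr)) target_corr <- diag(v)
  target_corr <- as.matrix(target_corr)
  if (!isTRUE(all.equal(target_corr, t(target_corr))) ||
      !isTRUE(all.equal(diag(target_corr), rep(1, v), check.attributes = FALSE))) {
    stop("target_corr must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("target_corr is not positive semi-definite", call. = FALSE)
  U <- chol(target_corr + diag(1e-10, v))
  g <- grid_spec(n_rows, n_cols, origin[1], origin[2], cell_size)
  withr::with_seed(seed, {
    fields <- lapply(seq_len(v), function(i) {
      f <- smooth_field(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                        var_specs$smoothness[i])
      (f - mean(f)) / stats::sd(as.vector(f))
    })
  })
  Z <- vapply(fields, as.vector, numeric(n_rows * n_cols))
  X <- Z %*% U
  layers <- lapply(seq_len(v), function(i) {
    x <- X[, i]
    x <- (x - mean(x)) / stats::sd(x) * var_specs$sd[i] + var_specs$mean[i]
    env_layer(var_specs$name[i], g, matrix(x, n_rows, n_cols))
  })
  assemble_stack(layers)
}

#' Default synthetic variable roster
#'
#' Eight variables emulating the mix a bioclim-style analysis screens:
#' temperature-like (bio2, bio4, bio9), precipitation-like (bio12, bio17),
#' elevation, a soil index and a UV-B layer, with realistic means/sds.
#'
#' @return A tibble of `name`, `mean`, `sd`, `smoothness`.
#' @export
default_var_specs <- function() {
  tibble::tibble(
    name = c("bio2", "bio4", "bio9", "bio12", "bio17", "Ele", "T_BS", "UVB4"),
    mean = c(8, 600, 12, 1200, 200, 800, 60, 2800),
    sd = c(2, 180, 6, 400, 90, 600, 15, 350),
    smoothness = c(8, 10, 8, 6, 6, 4, 5, 10)
  )
}

#' Default cross-variable correlation target
#'
#' Moderate positive blocks among the temperature-like variables and among
#' the moisture-like variables, with one near-collinear pair (bio12/bio17,
#' r = 0.85) so collinearity pruning has something to do.
#'
#' @param v Number of variables (only 8 supported for the default roster).
#' @return A `v x v` correlation matrix.
#' @export
default_target_corr <- function(v = 8) {
  if (v != 8) return(diag(v))
  C <- diag(8)
  nm <- c("bio2", "bio4", "bio9", "bio12", "bio17", "Ele", "T_BS", "UVB4")
  dimnames(C) <- list(nm, nm)
  set_r <- function(a, b, r) {
    C[a, b] <<- r; C[b, a] <<- r
  }
  set_r("bio2", "bio4", 0.55)
  set_r("bio2", "bio9", 0.45)
  set_r("bio4", "bio9", 0.50)
  set_r("bio12", "bio17", 0.85)
  set_r("bio9", "Ele", -0.40)
  set_r("UVB4", "Ele", 0.35)
  C
}

#' A known species-environment response
#'
#' Defines the synthetic truth: a linear-quadratic predictor on
#' standardized layers passed through the cloglog link,
#' `suitability = 1 - exp(-exp(eta))`.
#'
#' @param intercept Intercept of the linear predictor.
#' @param linear Named numeric vector of linear coefficients.
#' @param quadratic Named numeric vector of quadratic coefficients.
#' @return An object of class `true_model`.
#' @export
true_model <- function(intercept = 0, linear = numeric(), quadratic = numeric()) {
  if (length(linear) + length(quadratic) == 0 ||
      all(c(linear, quadratic) == 0)) {
    stop("true_model needs at least one nonzero coefficient", call. = FALSE)
  }
  structure(list(intercept = intercept, linear = linear, quadratic = quadratic,
                 link = "cloglog",
                 active_vars = union(names(linear), names(quadratic))),
            class = "true_model")
}

#' Default synthetic truth
#'
#' Three active variables out of the default eight, mirroring the common
#' finding that a few temperature/elevation variables dominate: negative
#' linear responses to bio2 and bio9 and a concave (negative-quadratic)
#' response to Ele peaking at the mean elevation. The coefficient scale
#' gives a strongly structured low-prevalence niche (roughly 10 percent of
#' the landscape above HSI 0.2), the regime of a rare montane species.
#'
#' @return A [true_model()].
#' @export
default_true_model <- function() {
  true_model(intercept = -4.5,
             linear = c(bio2 = -2.8, bio9 = -2.2),
             quadratic = c(Ele = -2.5))
}

#' Evaluate the true suitability surface
#'
#' Standardizes each active layer over valid cells (so the truth is
#' invariant to the layers' means/sds), evaluates the linear-quadratic
#' predictor, and applies the cloglog link.
#'
#' @param model A [true_model()].
#' @param stack An `env_stack` containing all active variables.
#' @return A `suitability_map` (cloglog scale).
#' @export
true_suitability <- function(model, stack) {
  stopifnot(inherits(model, "true_model"), inherits(stack, "env_stack"))
  missing <- setdiff(model$active_vars, names(stack$layers))
  if (length(missing)) {
    stop("stack lacks variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  eta <- matrix(model$intercept, stack$grid$n_rows, stack$grid$n_cols)
  zs <- function(v) {
    m <- stack$layers[[v]]$values
    mu <- mean(m[stack$mask]); sd <- stats::sd(m[stack$mask])
    (m - mu) / sd
  }
  for (v in names(model$linear)) eta <- eta + model$linear[[v]] * zs(v)
  for (v in names(model$quadratic)) eta <- eta + model$quadratic[[v]] * zs(v)^2
  vals <- 1 - exp(-exp(eta))
  vals <- pmin(pmax(vals, 0), 1)
  vals[!stack$mask] <- NA_real_
  suitability_map(stack$grid, vals, stack$mask, transform = "cloglog")
}

#' Sample presence records from a suitability surface
#'
#' Cells are drawn with probability proportional to suitability, with a
#' `noise` fraction of the sampling mass spread uniformly over valid cells
#' (contamination), then one point is jittered uniformly inside each drawn
#' cell. Deterministic given `seed`.
#'
#' @param truth A `suitability_map` (the ground truth).
#' @param n Number of records.
#' @param seed Integer seed.
#' @param noise Contamination fraction in \[0, 1\] (default 0.05).
#' @param species Species label for the output tibble.
#' @param replace Sample cells with replacement (default FALSE, matching the
#'   one-record-per-cell world the pipeline assumes).
#' @return A tibble with columns `species`, `lon`, `lat`.
#' @export
sample_occurrences <- function(truth, n, seed = 0, noise = 0.05,
                               species = "species", replace = FALSE) {
  stopifnot(inherits(truth, "suitability_map"), n >= 1)
  ok <- which(as.vector(t(truth$mask)))
  if (!replace && n > length(ok)) {
    stop("n = ", n, " exceeds the ", length(ok),
         " valid cells (replacement disabled)", call. = FALSE)
  }
  w <- as.vector(t(truth$values))[ok]
  w[w < 0] <- 0
  if (sum(w) <= 0) w <- rep(1, length(w))
  p <- (1 - noise) * w / sum(w) + noise / length(w)
  g <- truth$grid
  cent <- grid_centers(g)[ok, ]
  withr::with_seed(seed, {
    pick <- sample(length(ok), n, replace = replace, prob = p)
    jx <- stats::runif(n, -0.5, 0.5) * g$cell_size
    jy <- stats::runif(n, -0.5, 0.5) * g$cell_size
  })
  tibble::tibble(species = species,
                 lon = cent$lon[pick] + jx,
                 lat = cent$lat[pick] + jy)
}

#' Scenario delta: additive shift and multiplicative scale per variable
#'
#' @param label Scenario label, e.g. "SSP245-2070".
#' @param shift Named numeric vector of additive shifts (layer units).
#' @param scale Named numeric vector of multiplicative scales (> 0).
#' @return An object of class `scenario_delta`.
#' @export
scenario_delta <- function(label, shift = numeric(), scale = numeric()) {
  if (length(scale) && any(scale <= 0)) {
    stop("scenario scales must be > 0", call. = FALSE)
  }
  structure(list(label = label, shift = shift, scale = scale),
            class = "scenario_delta")
}

#' Apply a scenario delta to a stack
#'
#' Named layers become `v * scale + shift`; untouched layers are copied.
#'
#' @param stack An `env_stack`.
#' @param delta A [scenario_delta()].
#' @return A new `env_stack` carrying the scenario label as attribute
#'   `"scenario"`.
#' @export
make_future_stack <- function(stack, delta) {
  stopifnot(inherits(stack, "env_stack"), inherits(delta, "scenario_delta"))
  unknown <- setdiff(union(names(delta$shift), names(delta$scale)),
                     names(stack$layers))
  if (length(unknown)) {
    stop("delta names unknown layer(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  layers <- lapply(stack$layers, function(l) {
    v <- l$values
    if (l$name %in% names(delta$scale)) v <- v * delta$scale[[l$name]]
    if (l$name %in% names(delta$shift)) v <- v + delta$shift[[l$name]]
    env_layer(l$name, l$grid, v, l$mask)
  })
  out <- assemble_stack(layers)
  attr(out, "scenario") <- delta$label
  out
}

#' Generate a synthetic protected-area mask
#'
#' Adds random rectangular patches until coverage reaches the target
#' (stopping within the +/-20 percent construction band). Deterministic
#' given `seed`.
#'
#' @param grid A [grid_spec()].
#' @param coverage_target Fraction of cells to cover, in \[0, 1\].
#' @param n_patches Nominal number of patches sizing each rectangle.
#' @param seed Integer seed.
#' @return An object of class `pa_mask` with fields `grid` and `member`
#'   (logical matrix).
#' @export
generate_pa_mask <- function(grid, coverage_target = 0.03, n_patches = 12,
                             seed = 0) {
  if (coverage_target < 0 || coverage_target > 1) {
    stop("coverage_target must lie in [0, 1]", call. = FALSE)
  }
  member <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (coverage_target > 0) {
    n_cells <- grid$n_rows * grid$n_cols
    patch_cells <- max(1, round(coverage_target * n_cells / n_patches))
    side <- max(1, round(sqrt(patch_cells)))
    withr::with_seed(seed, {
      for (i in seq_len(10000)) {
        if (mean(member) >= coverage_target * 0.999) break
        h <- sample(max(1, side - 1):(side + 1), 1)
        w <- sample(max(1, side - 1):(side + 1), 1)
        r0 <- sample(grid$n_rows - h + 1, 1)
        c0 <- sample(grid$n_cols - w + 1, 1)
        member[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
      }
    })
  }
  structure(list(grid = grid, member = member), class = "pa_mask")
}

#' @export
print.pa_mask <- function(x, ...) {
  cat(sprintf("<pa_mask> %d / %d cells protected (%.2f%%)\n",
              sum(x$member), length(x$member), 100 * mean(x$member)))
  invisible(x)
}
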