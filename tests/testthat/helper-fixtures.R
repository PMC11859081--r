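# Small deterministic fixtures shared across test files. Everything is
# built in code at test time; no binary fixtures.

# a desk-scale world: 30 x 40 cells, 4 variables, mild correlation
small_world <- function(seed = 7) {
  specs <- tibble::tibble(
    name = c("temp", "prec", "elev", "soil"),
    mean = c(12, 900, 600, 50),
    sd = c(5, 250, 400, 10),
    smoothness = c(4, 4, 3, 3))
  C <- diag(4)
  C[1, 3] <- C[3, 1] <- -0.4
  C[2, 4] <- C[4, 2] <- 0.3
  generate_env_stack(n_rows = 30, n_cols = 40, cell_size = 0.25,
                     origin = c(100, 20), var_specs = specs,
                     target_corr = C, seed = seed)
}

small_truth_model <- function() {
  true_model(intercept = -2.5, linear = c(temp = -2.0),
             quadratic = c(elev = -1.8))
}

# a fitted small model + its inputs, memoized per test run
small_fit_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      stack <- small_world()
      truth <- true_suitability(small_truth_model(), stack)
      occ <- thin_to_grid(
        suppressMessages(sample_occurrences(truth, 120, seed = 11, noise = 0.05)),
        stack$grid, stack$mask)
      fit <- fit_sdm(occ, stack, fc = "LQ", rm = 1, seed = 0)
      cache <<- list(stack = stack, truth = truth, occ = occ, fit = fit)
    }
    cache
  }
})

# constant-valued layer helper
flat_layer <- function(name, grid, value) {
  env_layer(name, grid, matrix(value, grid$n_rows, grid$n_cols))
}

# tiny grid helper
tiny_grid <- function(n_rows = 3, n_cols = 4, cell_size = 0.25,
                      x_min = 100, y_min = 20) {
  grid_spec(n_rows, n_cols, x_min, y_min, cell_size)
}

# suitability map from a plain matrix
as_suit_map <- function(m, grid = NULL, transform = "cloglog") {
  if (is.null(grid)) grid <- tiny_grid(nrow(m), ncol(m))
  suitability_map(grid, m, mask = !is.na(m), transform = transform)
}

# independent penalized-objective evaluator (used by fit oracles):
# F(lambda) = mean_pres(lambda . f) - ln sum_bg exp(lambda . f) - sum beta |lambda|
penalized_objective <- function(lambda, Fp, Fb, beta) {
  mean(Fp %*% lambda) - log(sum(exp(Fb %*% lambda))) - sum(beta * abs(lambda))
}

# independent convex solve of the same objective via positive/negative
# split and L-BFGS-B (oracle; never touches the coordinate-descent path)
oracle_fit <- function(Fp, Fb, beta) {
  J <- ncol(Fb)
  obj <- function(ab) {
    l <- ab[1:J] - ab[(J + 1):(2 * J)]
    -(mean(Fp %*% l) - log(sum(exp(Fb %*% l))) - sum(beta * (ab[1:J] + ab[(J + 1):(2 * J)])))
  }
  fit <- stats::optim(rep(0, 2 * J), obj, method = "L-BFGS-B",
                      lower = rep(0, 2 * J),
                      control = list(maxit = 2000, factr = 1e4))
  lambda <- fit$par[1:J] - fit$par[(J + 1):(2 * J)]
  list(lambda = lambda, objective = -fit$value)
}
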