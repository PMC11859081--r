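test_that("a signal-free problem yields the uniform model", {
  Fp <- matrix(0.5, 20, 3)
  Fb <- matrix(0.5, 50, 3)
  specs <- tibble::tibble(kind = rep("linear", 3), var1 = c("a", "b", "c"),
                          var2 = NA_character_, knot = NA_real_)
  fit <- fit_maxent(Fp, Fb, specs = specs, rm = 1)
  expect_equal(fit$lambda, rep(0, 3))
  expect_equal(fit$bg_weights, rep(1 / 50, 50))
  expect_equal(fit$H_entropy, log(50))
  expect_equal(fit$gain, 0, tolerance = 1e-12)
})

test_that("coordinate descent matches a dense grid search on a 2-feature problem", {
  # literal dense grid oracle, step 0.01 over [-10, 10] per coordinate
  set.seed(10)
  v <- runif(20)
  Fb <- cbind(l = v, q = v^2)
  pres_idx <- order(v, decreasing = TRUE)[1:6]
  Fp <- Fb[pres_idx, ]
  specs <- tibble::tibble(kind = c("linear", "quadratic"), var1 = "v",
                          var2 = NA_character_, knot = NA_real_)
  beta <- nichecast:::feature_betas(specs, Fp, 1)

  grid <- seq(-10, 10, by = 0.01)
  best <- -Inf
  p1 <- colMeans(Fp)
  for (l1 in grid) {
    # profile the second coordinate on the coarse grid for tractability,
    # then refine around the incumbent
    obj <- p1[1] * l1 + p1[2] * grid -
      vapply(grid, function(l2) log(sum(exp(Fb %*% c(l1, l2)))), numeric(1)) -
      beta[1] * abs(l1) - beta[2] * abs(grid)
    m <- max(obj)
    if (m > best) best <- m
  }

  fit <- fit_maxent(Fp, Fb, specs = specs, rm = 1, tol = 1e-9,
                    max_cycles = 5000)
  cd_obj <- penalized_objective(fit$lambda, Fp, Fb, beta)
  expect_equal(cd_obj, best, tolerance = 1e-3)
})

test_that("coordinate descent matches an independent convex solve on 3-feature problems", {
  for (seed in 1:4) {
    set.seed(seed)
    Fb <- matrix(runif(90), 30, 3)
    Fp <- Fb[sample(30, 8, prob = Fb[, 1] + 0.1), ]
    specs <- tibble::tibble(kind = c("linear", "linear", "quadratic"),
                            var1 = c("a", "b", "a"), var2 = NA_character_,
                            knot = NA_real_)
    beta <- nichecast:::feature_betas(specs, Fp, 1)
    fit <- fit_maxent(Fp, Fb, specs = specs, rm = 1, tol = 1e-10,
                      max_cycles = 5000)
    orc <- oracle_fit(Fp, Fb, beta)
    expect_equal(penalized_objective(fit$lambda, Fp, Fb, beta),
                 orc$objective, tolerance = 1e-3)
  }
})

test_that("a separating binary variable concentrates the raw mass", {
  v <- rep(c(0, 1), each = 25)
  Fb <- cbind(v = v)
  Fp <- cbind(v = rep(1, 10))
  specs <- tibble::tibble(kind = "linear", var1 = "v", var2 = NA_character_,
                          knot = NA_real_)
  fit <- fit_maxent(Fp, Fb, specs = specs, rm = 0.1)
  mass_on_v1 <- sum(fit$bg_weights[v == 1])
  expect_gte(mass_on_v1, 0.95)
})

test_that("the penalized gain trace is non-decreasing", {
  b <- small_fit_bundle()
  expect_true(all(diff(b$fit$gain_trace) >= -1e-9))
})

test_that("raw predictions sum to one over the training background", {
  b <- small_fit_bundle()
  pred <- predict(b$fit, b$stack, transform = "raw")
  expect_equal(sum(pred$values[b$stack$mask]), 1, tolerance = 1e-9)
})

test_that("the all-zero model predicts the uniform cloglog value", {
  stack <- small_world()
  n <- sum(stack$mask)
  Xb <- nichecast:::stack_matrix(stack)
  fb <- build_features(Xb, "L")
  # all-zero coefficients by construction: presence features equal at 0.5
  fit <- fit_maxent(matrix(0.5, 5, ncol(fb$features)), fb$features * 0 + 0.5,
                    specs = fb$specs, anchors = fb$anchors, rm = 1)
  fit$lambda <- rep(0, length(fit$lambda))
  pred <- predict(fit, stack, transform = "cloglog")
  # H = ln N, raw = 1/N -> 1 - exp(-1)
  expect_equal(unique(round(pred$values[stack$mask], 9)), round(1 - exp(-1), 9))
})

test_that("L1 norm of coefficients is non-increasing in the regularization multiplier", {
  b <- small_fit_bundle()
  norms <- vapply(c(0.5, 1, 2, 4), function(rm) {
    sum(abs(fit_sdm(b$occ, b$stack, fc = "LQ", rm = rm, seed = 0)$lambda))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("percent contributions are normalized and credit the right variables", {
  b <- small_fit_bundle()
  contrib <- percent_contribution(b$fit)
  expect_equal(sum(contrib$contribution), 100, tolerance = 1e-9)
  expect_true(all(contrib$contribution >= 0))
  # the two active truth variables dominate the two inert ones
  active <- sum(contrib$contribution[contrib$variable %in% c("temp", "elev")])
  expect_gt(active, 50)

  # single-variable model -> 100 percent
  single <- fit_sdm(b$occ, select_layers(b$stack, "temp"), fc = "LQ", rm = 1,
                    seed = 0)
  cs <- percent_contribution(single)
  expect_equal(cs$contribution[cs$variable == "temp"], 100)
})

test_that("identical twin layers share contribution on average over seeds", {
  stack <- small_world()
  twin <- env_layer("twin", stack$grid, stack$layers[["temp"]]$values)
  st2 <- assemble_stack(list(stack$layers[["temp"]], twin))
  truth <- true_suitability(true_model(-2, linear = c(temp = -2)), stack)
  occ <- thin_to_grid(
    suppressMessages(sample_occurrences(truth, 100, seed = 3, noise = 0)),
    stack$grid, stack$mask)
  shares <- vapply(1:40, function(s) {
    fit <- fit_sdm(occ, st2, fc = "L", rm = 1, seed = s)
    pc <- percent_contribution(fit)
    pc$contribution[pc$variable == "temp"]
  }, numeric(1))
  expect_equal(mean(shares), 50, tolerance = 0.35)  # +/- ~17 absolute
})

test_that("jackknife importance behaves like nested models", {
  b <- small_fit_bundle()
  jk <- jackknife_importance(b$occ, b$stack, fc = "LQ", rm = 1, seed = 0)
  expect_setequal(jk$variable, names(b$stack$layers))
  # leaving any variable out cannot beat the full model (same penalty scheme)
  expect_true(all(jk$gain_without <= jk$gain_all + 0.05))
  # the dominant truth variable is more informative alone than an inert one
  only <- setNames(jk$gain_with_only, jk$variable)
  expect_gt(only[["temp"]], only[["soil"]])

  # V = 1: gain with only the variable equals the full-model gain
  one <- select_layers(b$stack, c("temp", "elev"))
  jk1 <- jackknife_importance(b$occ, one, fc = "LQ", rm = 1, seed = 0)
  expect_equal(nrow(jk1), 2)
})

test_that("an uninformative variable has near-zero gain alone", {
  stack <- small_world()
  withr::with_seed(99, {
    noise_vals <- matrix(rnorm(stack$grid$n_rows * stack$grid$n_cols),
                         stack$grid$n_rows)
  })
  st2 <- assemble_stack(c(stack$layers,
                          list(noise = env_layer("noise", stack$grid, noise_vals))))
  truth <- true_suitability(small_truth_model(), stack)
  occ <- thin_to_grid(
    suppressMessages(sample_occurrences(truth, 200, seed = 21, noise = 0)),
    stack$grid, stack$mask)
  only_noise <- fit_sdm(occ, select_layers(st2, c("noise", "soil")), fc = "L",
                        rm = 1, seed = 0)
  jk_gain <- fit_sdm(occ, select_layers(st2, "noise"), fc = "L", rm = 1,
                     seed = 0)$gain
  expect_lt(jk_gain, 0.05)
})

test_that("response curves reflect the fitted form", {
  b <- small_fit_bundle()
  # flat curve for an all-zero model
  zero <- b$fit
  zero$lambda <- rep(0, length(zero$lambda))
  zero$log_Z <- log(zero$n_background)
  zero$H_entropy <- log(zero$n_background)
  rc0 <- response_curve(zero, "temp")
  expect_equal(unique(round(rc0$response, 9)), round(1 - exp(-1), 9))

  # positive linear-only coefficient -> monotone nondecreasing curve
  mono <- zero
  j <- which(mono$specs$kind == "linear" & mono$specs$var1 == "temp")
  mono$lambda[j] <- 2
  rc1 <- response_curve(mono, "temp")
  expect_true(all(diff(rc1$response) >= -1e-12))

  # concave linear+quadratic pair peaks at the interior optimum a/(2b)
  lq <- zero
  jq <- which(lq$specs$kind == "quadratic" & lq$specs$var1 == "temp")
  lq$lambda[j] <- 6; lq$lambda[jq] <- -6   # peak at scaled u = 0.5
  rc2 <- response_curve(lq, "temp", n_points = 201)
  expect_equal(which.max(rc2$response), 101, tolerance = 2)
  expect_error(response_curve(b$fit, "nope"), "nope")
})

test_that("AUC follows the Mann-Whitney definition with half ties", {
  expect_equal(auc_score(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(auc_score(c(0.9, 0.1), c(0.5, 0.5)), 0.5)
  expect_equal(auc_score(c(0.3, 0.3), c(0.3, 0.3)), 0.5)
  expect_equal(auc_score(c(1, 0), c(0.5, 0)), (1 + 1 + 0 + 0.5) / 4)
  expect_error(auc_score(numeric(), 1), "empty")
})
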