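#' Pearson correlation matrix across stack variables
#'
#' Computes standard Pearson r over all jointly valid cells (or a seeded
#' background sample). Constant variables get r = 0 off-diagonal with a
#' warning.
#'
#' @param stack An `env_stack`.
#' @param sample "all_valid_cells" (default) or "background_sample".
#' @param n_sample Sample size when `sample = "background_sample"`.
#' @param seed Seed for the background sample.
#' @return A symmetric correlation matrix with unit diagonal, named by
#'   variable.
#' @export
pearson_matrix <- function(stack, sample = c("all_valid_cells", "background_sample"),
                           n_sample = 10000, seed = 0) {
  sample <- match.arg(sample)
  if (length(stack$layers) < 2) {
    stop("need at least 2 variables for a correlation matrix", call. = FALSE)
  }
  X <- stack_matrix(stack)
  if (nrow(X) < 3) stop("need at least 3 sample points", call. = FALSE)
  if (sample == "background_sample" && nrow(X) > n_sample) {
    withr::with_seed(seed, idx <- sample.int(nrow(X), n_sample))
    X <- X[idx, , drop = FALSE]
  }
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  C <- diag(ncol(X))
  dimnames(C) <- list(colnames(X), colnames(X))
  if (any(const)) {
    warning("constant variable(s): ", paste(colnames(X)[const], collapse = ", "),
            "; correlations set to 0", call. = FALSE)
  }
  live <- which(!const)
  if (length(live) >= 2) {
    C[live, live] <- stats::cor(X[, live, drop = FALSE])
  }
  diag(C) <- 1
  C
}

#' Drop variables with zero model contribution
#'
#' First screening stage: variables whose percent contribution in a
#' preliminary fit is (numerically) zero are removed; order is preserved.
#'
#' @param contrib Named numeric vector or two-column tibble
#'   (`variable`, `contribution`) of percent contributions.
#' @return Character vector of retained variable names.
#' @export
drop_zero_contribution <- function(contrib) {
  contrib <- as_contrib_vector(contrib)
  if (all(contrib < 1e-9)) {
    stop("all contributions are zero: degenerate preliminary model",
         call. = FALSE)
  }
  names(contrib)[contrib >= 1e-9]
}

as_contrib_vector <- function(contrib) {
  if (is.data.frame(contrib)) {
    stopifnot(all(c("variable", "contribution") %in% names(contrib)))
    stats::setNames(contrib$contribution, contrib$variable)
  } else {
    stopifnot(!is.null(names(contrib)))
    contrib
  }
}

#' Prune collinear variable pairs
#'
#' Second screening stage: pairs with |r| strictly above `threshold` are
#' visited in decreasing |r| order (alphabetical tie-break); in each pair
#' the lower-contribution member is dropped unless one member is already
#' gone. Never drops both members of a flagged pair.
#'
#' @param corr Correlation matrix (as from [pearson_matrix()]).
#' @param contrib Percent contributions (named vector or tibble).
#' @param threshold Absolute-correlation threshold (default 0.80, strict).
#' @return Character vector of retained names, in `corr` column order, with
#'   a `"dropped"` attribute tabulating the decisions.
#' @export
prune_collinear <- function(corr, contrib, threshold = 0.80) {
  contrib <- as_contrib_vector(contrib)
  vars <- colnames(corr)
  stopifnot(setequal(vars, names(contrib)))
  pairs <- which(upper.tri(corr) & abs(corr) > threshold, arr.ind = TRUE)
  dropped <- character()
  log <- list()
  if (nrow(pairs)) {
    r <- abs(corr[pairs])
    a <- vars[pairs[, 1]]; b <- vars[pairs[, 2]]
    ord <- order(-r, pmin(a, b), pmax(a, b))
    for (i in ord) {
      if (a[i] %in% dropped || b[i] %in% dropped) next
      ca <- contrib[[a[i]]]; cb <- contrib[[b[i]]]
      loser <- if (ca < cb) a[i] else if (cb < ca) b[i] else
        max(a[i], b[i])  # alphabetical tie-break: keep the earlier name
      dropped <- c(dropped, loser)
      log[[length(log) + 1]] <- tibble::tibble(
        var_a = a[i], var_b = b[i], r = corr[pairs[i, 1], pairs[i, 2]],
        dropped = loser)
    }
  }
  kept <- setdiff(vars, dropped)
  attr(kept, "dropped") <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(var_a = character(), var_b = character(),
                   r = numeric(), dropped = character())
  kept
}

#' Two-stage variable screening
#'
#' Runs the screening protocol: a preliminary maxent fit (FC = LQ, RM = 1)
#' yields percent contributions; zero-contribution variables are dropped;
#' then collinear pairs (|r| > threshold over all jointly valid cells) are
#' pruned keeping the higher-contribution member.
#'
#' @param occ Thinned occurrence tibble for one species.
#' @param stack An `env_stack` of candidate variables.
#' @param threshold Pearson threshold (default 0.80).
#' @param seed Seed for the preliminary fit's background sample.
#' @return A list with `retained` (names), `contrib` (tibble), `corr`
#'   (matrix), and `dropped_pairs` (tibble).
#' @export
screen_variables <- function(occ, stack, threshold = 0.80, seed = 0) {
  fit <- fit_sdm(occ, stack, fc = "LQ", rm = 1, seed = seed)
  contrib <- percent_contribution(fit)
  keep1 <- drop_zero_contribution(contrib)
  corr <- pearson_matrix(stack)[keep1, keep1, drop = FALSE]
  cv <- as_contrib_vector(contrib)[keep1]
  retained <- prune_collinear(corr, cv, threshold = threshold)
  list(retained = as.character(retained), contrib = contrib, corr = corr,
       dropped_pairs = attr(retained, "dropped"))
}

#' Subset a stack to named variables
#'
#' @param stack An `env_stack`.
#' @param vars Variable names to keep (order respected).
#' @return An `env_stack` with only those layers.
#' @export
select_layers <- function(stack, vars) {
  missing <- setdiff(vars, names(stack$layers))
  if (length(missing)) {
    stop("unknown layer(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  assemble_stack(stack$layers[vars])
}
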