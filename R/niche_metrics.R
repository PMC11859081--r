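#' Schoener's D niche overlap
#'
#' Normalizes each suitability surface to sum to 1 over the joint valid
#' mask (occurrence-probability surfaces P_ia, P_ja) and computes
#' `D = 1 - 0.5 * sum |P_ia - P_ja|`: 1 for identical surfaces, 0 for
#' disjoint supports.
#'
#' @param map_a,map_b `suitability_map`s on the same grid.
#' @return D in \[0, 1\].
#' @export
schoener_d <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "suitability_map"),
            inherits(map_b, "suitability_map"))
  if (!grids_identical(map_a$grid, map_b$grid)) {
    stop("maps are on different grids", call. = FALSE)
  }
  joint <- map_a$mask & map_b$mask
  if (!any(joint)) stop("joint valid mask is empty", call. = FALSE)
  pa <- map_a$values[joint]; pb <- map_b$values[joint]
  if (sum(pa) <= 0 || sum(pb) <= 0) {
    stop("cannot normalize an all-zero map", call. = FALSE)
  }
  pa <- pa / sum(pa); pb <- pb / sum(pb)
  1 - 0.5 * sum(abs(pa - pb))
}

#' Levins niche breadth (standardized B2)
#'
#' Shannon entropy of the normalized suitability surface divided by
#' `ln(R)`, with `R` the number of valid cells, so the statistic lies in
#' \[0, 1\]: 0 for a single-cell specialist, 1 for a uniform generalist.
#' Invariant to uniform rescaling of the map.
#'
#' @param map A `suitability_map`.
#' @return B2 in \[0, 1\].
#' @export
levins_b2 <- function(map) {
  stopifnot(inherits(map, "suitability_map"))
  v <- map$values[map$mask]
  R <- length(v)
  if (R < 2) stop("need at least 2 valid cells", call. = FALSE)
  if (sum(v) <= 0) stop("cannot normalize an all-zero map", call. = FALSE)
  p <- v / sum(v)
  p <- p[p > 0]
  (-sum(p * log(p))) / log(R)
}

#' Binary range overlap
#'
#' Binarizes both surfaces at `threshold` (HSI >= threshold) and reports
#' the shared fraction `|A and B| / min(|A|, |B|)` (symmetric,
#' min-denominator definition). Returns 0 with attribute
#' `empty_range = TRUE` if either range is empty.
#'
#' @param map_a,map_b `suitability_map`s on the same grid.
#' @param threshold HSI threshold for range membership (default 0.4).
#' @return Overlap in \[0, 1\].
#' @export
range_overlap <- function(map_a, map_b, threshold = 0.4) {
  if (!grids_identical(map_a$grid, map_b$grid)) {
    stop("maps are on different grids", call. = FALSE)
  }
  joint <- map_a$mask & map_b$mask
  ra <- joint & map_a$values >= threshold
  rb <- joint & map_b$values >= threshold
  na <- sum(ra, na.rm = TRUE); nb <- sum(rb, na.rm = TRUE)
  if (na == 0 || nb == 0) {
    return(structure(0, empty_range = TRUE))
  }
  sum(ra & rb, na.rm = TRUE) / min(na, nb)
}

#' Niche metrics across species
#'
#' Computes the pairwise Schoener's D matrix, per-species Levins B2, and
#' pairwise binary range overlap for a set of suitability surfaces.
#'
#' @param maps Named list of `suitability_map`s (one per species).
#' @param threshold Range threshold (default 0.4).
#' @return An object of class `niche_metrics`: a list with `species`, `D`
#'   and `range_overlap` matrices, `B2` vector, and `threshold`.
#' @export
niche_metrics <- function(maps, threshold = 0.4) {
  sp <- names(maps)
  stopifnot(!is.null(sp), length(sp) >= 1)
  k <- length(sp)
  D <- diag(k); RO <- diag(k)
  dimnames(D) <- dimnames(RO) <- list(sp, sp)
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      D[i, j] <- D[j, i] <- schoener_d(maps[[i]], maps[[j]])
      ro <- range_overlap(maps[[i]], maps[[j]], threshold)
      RO[i, j] <- RO[j, i] <- as.numeric(ro)
    }
  }
  B2 <- vapply(maps, levins_b2, numeric(1))
  structure(list(species = sp, D = D, B2 = B2, range_overlap = RO,
                 threshold = threshold),
            class = "niche_metrics")
}

#' @export
print.niche_metrics <- function(x, ...) {
  cat("<niche_metrics> threshold", x$threshold, "\nSchoener's D:\n")
  print(round(x$D, 3))
  cat("Levins B2:\n"); print(round(x$B2, 3))
  cat("Range overlap:\n"); print(round(x$range_overlap, 3))
  invisible(x)
}

#' Tidy a niche-metrics object
#'
#' @param x A `niche_metrics` object.
#' @param ... Unused.
#' @return A tibble with one row per species pair (`species_a`,
#'   `species_b`, `schoener_d`, `range_overlap`) plus per-species rows of
#'   B2 (`species_b = NA`, column `b2`).
#' @method tidy niche_metrics
#' @export
tidy.niche_metrics <- function(x, ...) {
  sp <- x$species
  pairs <- if (length(sp) >= 2) {
    cmb <- utils::combn(sp, 2)
    tibble::tibble(species_a = cmb[1, ], species_b = cmb[2, ],
                   schoener_d = x$D[t(cmb)],
                   range_overlap = x$range_overlap[t(cmb)])
  } else tibble::tibble(species_a = character(), species_b = character(),
                        schoener_d = numeric(), range_overlap = numeric())
  breadth <- tibble::tibble(species_a = sp, species_b = NA_character_,
                            b2 = as.numeric(x$B2))
  dplyr::bind_rows(pairs, breadth)
}

#' Table-shaped niche metrics (D above, range overlap below the diagonal)
#'
#' @param x A `niche_metrics` object.
#' @return A square character-friendly tibble with a B2 column, shaped like
#'   the classic three-species report table.
#' @export
niche_metrics_table <- function(x) {
  k <- length(x$species)
  m <- matrix(1, k, k, dimnames = list(x$species, x$species))
  m[upper.tri(m)] <- x$D[upper.tri(x$D)]
  m[lower.tri(m)] <- x$range_overlap[lower.tri(x$range_overlap)]
  out <- tibble::as_tibble(m, rownames = "species")
  out$B2 <- as.numeric(x$B2)
  out
}
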