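#' Cluster centers
#'
#' A k x V matrix of cluster alt-allele fractions (stored clamped into the
#' count model's `[floor, 1-floor]` range) plus per-cluster lock flags.
#' Locked clusters keep their fractions bit-identical through center updates.
#'
#' @param fractions numeric k x V matrix of alt-allele fractions.
#' @param locked logical length-k lock flags (default all unlocked).
#' @return Object of class `cluster_centers` with elements `fractions`,
#'   `locked`, `k`.
#' @export
cluster_centers <- function(fractions, locked = rep(FALSE, nrow(fractions))) {
  fractions <- as.matrix(fractions)
  stopifnot(all(is.finite(fractions)), length(locked) == nrow(fractions))
  structure(list(fractions = fractions, locked = as.logical(locked),
                 k = nrow(fractions)),
            class = "cluster_centers")
}

#' @param x a `cluster_centers` object.
#' @param ... ignored.
#' @rdname cluster_centers
#' @method print cluster_centers
#' @export
print.cluster_centers <- function(x, ...) {
  cat(sprintf("cluster_centers: k = %d over %d variants (%d locked)\n",
              x$k, ncol(x$fractions), sum(x$locked)))
  invisible(x)
}

#' Per-variant merge weights
#'
#' The merge distance weights each variant by the number of alleles observed
#' there: by default the total read count (alt + ref over all cells), or the
#' number of cells with any coverage (`mode = "cells"`).
#'
#' @param counts an [allele_counts] object.
#' @param mode `"reads"` (default) or `"cells"`.
#' @return Nonnegative numeric vector, length `n_variants`.
#' @export
variant_weights <- function(counts, mode = c("reads", "cells")) {
  mode <- match.arg(mode)
  tot <- counts$ref + counts$alt
  w <- if (mode == "reads") Matrix::colSums(tot) else Matrix::colSums(tot > 0)
  if (!any(w > 0)) .stopf("no variant has any coverage")
  as.numeric(w)
}

#' Random preliminary centers seeded from cells
#'
#' Each preliminary center is built from one uniformly sampled cell (without
#' replacement). At sites the cell covers, the center fraction is the
#' add-one-smoothed cell fraction `(alt + 1) / (alt + ref + 2)`; at uncovered
#' sites it falls back to the dataset-wide smoothed alt fraction for that
#' variant. This answers the question kmeans++-style seeding cannot: what
#' value a center takes in the ~95% of dimensions where the seed cell has no
#' data.
#'
#' @param counts an [allele_counts] object.
#' @param n number of centers (`<= n_cells`).
#' @param config a [count_model_config] (for the fraction clamp).
#' @param seed integer seed; output is deterministic given it.
#' @param cells optional explicit cell indices to seed from (length `n`);
#'   overrides uniform sampling (used by refinement).
#' @return A [cluster_centers] object with `n` rows.
#' @export
random_centers <- function(counts, n, config = count_model_config(), seed = 0,
                           cells = NULL) {
  prep <- .ac_prep(counts)
  .random_centers_prep(prep, n, config, seed, cells)
}

.random_centers_prep <- function(prep, n, config, seed, cells = NULL) {
  if (n > prep$n) {
    .stopf("cannot seed %d centers from %d cells", n, prep$n)
  }
  idx <- if (is.null(cells)) {
    .local_seed(seed, sample.int(prep$n, n))
  } else {
    stopifnot(length(cells) == n, !anyDuplicated(cells))
    as.integer(cells)
  }
  fill <- (prep$col_alt + 1) / (prep$col_tot + 2)
  fr <- matrix(fill, nrow = n, ncol = prep$v, byrow = TRUE)
  tr <- prep$trip
  sel <- match(tr$i, idx)
  keep <- !is.na(sel)
  fr[cbind(sel[keep], tr$v[keep])] <-
    (tr$alt[keep] + 1) / (tr$tot[keep] + 2)
  cluster_centers(.clamp(fr, config$fraction_floor))
}

#' Coverage-weighted squared-difference distance between centers
#'
#' `sum_v w_v * (a_v - b_v)^2`: the merge criterion of the 10x merge
#' initializer. Variants with more observed alleles dominate, as they carry
#' more evidence about genotype differences.
#'
#' @param a,b numeric fraction vectors of equal length.
#' @param w nonnegative weights from [variant_weights].
#' @export
merge_distance <- function(a, b, w) {
  if (length(a) != length(b) || length(a) != length(w)) {
    .stopf("merge_distance: lengths differ (%d, %d, %d)",
           length(a), length(b), length(w))
  }
  sum(w * (a - b)^2)
}

#' Greedily merge centers down to k
#'
#' Repeatedly finds the closest pair of centers under [merge_distance] and
#' replaces it by the per-variant unweighted mean, until `k` centers remain.
#' Ties are broken by the lexicographically lowest index pair, so the result
#' is deterministic.
#'
#' @param centers a [cluster_centers] object with `centers$k >= k`.
#' @param k target number of centers.
#' @param w variant weights from [variant_weights].
#' @return A [cluster_centers] object with exactly `k` rows; attributes
#'   `n_merges` (merges performed) and `merged_distances` (the distance of
#'   each merged pair, in merge order).
#' @export
merge_to_k <- function(centers, k, w) {
  fr <- centers$fractions
  n0 <- nrow(fr)
  if (k > n0) .stopf("cannot merge %d centers up to %d", n0, k)
  if (k < 1) .stopf("k must be >= 1")
  merged <- numeric(0)
  if (n0 > k) {
    # Pairwise weighted sq distances via the Gram trick:
    # d(a,b) = s_a + s_b - 2 * (a W b'),  s_a = sum(w a^2).
    cw <- sweep(fr, 2, w, "*")
    g <- tcrossprod(cw, fr)
    s <- diag(g)
    d <- pmax(outer(s, s, "+") - 2 * g, 0)
    repeat {
      nn <- nrow(fr)
      if (nn <= k) break
      du <- d
      du[lower.tri(du, diag = TRUE)] <- Inf
      mval <- min(du)
      cand <- which(du == mval, arr.ind = TRUE)
      cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
      i <- cand[1, 1]; j <- cand[1, 2]
      merged <- c(merged, mval)
      newc <- (fr[i, ] + fr[j, ]) / 2
      fr[i, ] <- newc
      fr <- fr[-j, , drop = FALSE]
      # refresh row/col i, drop row/col j
      d <- d[-j, -j, drop = FALSE]
      s_new <- sum(w * newc^2)
      cross <- as.numeric(fr %*% (w * newc))
      s <- s[-j]; s[i] <- s_new
      drow <- pmax(s + s_new - 2 * cross, 0)
      drow[i] <- 0
      d[i, ] <- drow
      d[, i] <- drow
    }
  }
  out <- cluster_centers(fr)
  attr(out, "n_merges") <- n0 - nrow(fr)
  attr(out, "merged_distances") <- merged
  out
}

#' 10x merge initialization
#'
#' Over-generates `10 * k` preliminary centers from randomly sampled cells
#' (capped at `n_cells`), then merges the closest pairs down to `k` with
#' [merge_to_k]. The surviving centers are pairwise well separated, which
#' protects against splitting one true donor across two clusters.
#'
#' @param counts an [allele_counts] object.
#' @param k expected number of donors (>= 1).
#' @param config a [count_model_config].
#' @param seed integer seed.
#' @param weight_mode passed to [variant_weights].
#' @return A [cluster_centers] object with `k` rows; attribute
#'   `n_preliminary` records how many preliminary centers were generated,
#'   plus the [merge_to_k] attributes.
#' @export
initialize_10x <- function(counts, k, config = count_model_config(), seed = 0,
                           weight_mode = "reads") {
  if (k < 1) .stopf("k must be >= 1")
  n_pre <- min(10L * as.integer(k), n_cells(counts))
  pre <- random_centers(counts, n_pre, config, seed)
  w <- variant_weights(counts, weight_mode)
  out <- merge_to_k(pre, k, w)
  attr(out, "n_preliminary") <- n_pre
  out
}
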