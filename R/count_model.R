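#' Count-likelihood model configuration
#'
#' The clustering distance is the negated log-likelihood of a cell's allele
#' counts under a cluster's allele-fraction vector. The default family is
#' binomial: at a site with alt fraction p, observing `alt` alternate and
#' `ref` reference reads has log pmf
#' `log C(alt+ref, alt) + alt*log(p) + ref*log(1-p)`. The beta-binomial
#' family adds overdispersion with concentration `dispersion` (it converges
#' to the binomial as `dispersion` grows).
#'
#' @param family `"binomial"` (default) or `"beta_binomial"`.
#' @param dispersion beta-binomial concentration (> 0); ignored for binomial.
#' @param fraction_floor allele fractions are clamped into
#'   `[fraction_floor, 1 - fraction_floor]` before likelihood evaluation, so
#'   a center can never assign probability zero to an observed allele.
#' @param distance_epsilon small positive constant added to every distance;
#'   keeps K-Harmonic Means (which divides by powers of distances) finite for
#'   cells with no covered variants.
#' @return A list of class `count_model_config`.
#' @export
count_model_config <- function(family = c("binomial", "beta_binomial"),
                               dispersion = 100,
                               fraction_floor = 0.01,
                               distance_epsilon = 1e-6) {
  family <- match.arg(family)
  stopifnot(dispersion > 0, fraction_floor > 0, fraction_floor < 0.5,
            distance_epsilon > 0)
  structure(list(family = family, dispersion = dispersion,
                 fraction_floor = fraction_floor,
                 distance_epsilon = distance_epsilon),
            class = "count_model_config")
}

#' Site-level count log-probability
#'
#' Log pmf of observing `alt` alternate and `ref` reference reads at one site
#' given a cluster alt-allele fraction `p`. Vectorized over all arguments.
#'
#' @param alt,ref nonnegative read counts, `alt + ref >= 1`.
#' @param p alt-allele fraction; clamped to the config's floor before use.
#' @param config a [count_model_config].
#' @return Log-probability (always finite, <= 0).
#' @examples
#' site_log_pmf(3, 1, 0.5)  # log(0.25)
#' @export
site_log_pmf <- function(alt, ref, p, config = count_model_config()) {
  if (any(alt < 0) || any(ref < 0)) .stopf("negative read counts")
  p <- .clamp(p, config$fraction_floor)
  if (config$family == "binomial") {
    lchoose(alt + ref, alt) + alt * log(p) + ref * log1p(-p)
  } else {
    s1 <- p * config$dispersion
    s2 <- (1 - p) * config$dispersion
    lchoose(alt + ref, alt) + lbeta(alt + s1, ref + s2) - lbeta(s1, s2)
  }
}

#' Cell-versus-center log-likelihood
#'
#' Sum of [site_log_pmf] over the variants the cell actually covers (scRNA-seq
#' SNP counts are ~95% empty, so each cell is scored only on its ~5% of
#' observed sites). A cell covering no variants scores 0.
#'
#' @param counts an [allele_counts] object.
#' @param cell cell index (1-based row of `counts`).
#' @param center numeric vector of alt-allele fractions, length `n_variants`.
#' @param config a [count_model_config].
#' @export
cell_cluster_loglik <- function(counts, cell, center,
                                config = count_model_config()) {
  if (length(center) != n_variants(counts)) {
    .stopf("center has %d fractions but data has %d variants",
           length(center), n_variants(counts))
  }
  a <- counts$alt[cell, ]
  r <- counts$ref[cell, ]
  cov <- which(a + r >= 1)
  if (!length(cov)) return(0)
  sum(site_log_pmf(a[cov], r[cov], center[cov], config))
}

#' KHM distance between a cell and a cluster center
#'
#' The negated [cell_cluster_loglik] plus `distance_epsilon`; strictly
#' positive, as K-Harmonic Means requires.
#'
#' @inheritParams cell_cluster_loglik
#' @export
count_distance <- function(counts, cell, center,
                           config = count_model_config()) {
  -cell_cluster_loglik(counts, cell, center, config) + config$distance_epsilon
}

# n_cells x k log-likelihood matrix against the rows of a k x V fraction
# matrix P. Binomial family is pure sparse linear algebra: zero alt (or ref)
# entries contribute nothing to the A %*% log(p) (R %*% log(1-p)) terms, and
# the lchoose term depends on the cell only.
.loglik_matrix <- function(prep, p_mat, config) {
  p_mat <- .clamp(p_mat, config$fraction_floor)
  if (config$family == "binomial") {
    ll <- as.matrix(prep$A %*% t(log(p_mat)) + prep$R %*% t(log1p(-p_mat)))
    ll + prep$lch
  } else {
    k <- nrow(p_mat)
    out <- matrix(0, prep$n, k)
    tr <- prep$trip
    for (j in seq_len(k)) {
      s1 <- p_mat[j, ] * config$dispersion
      s2 <- (1 - p_mat[j, ]) * config$dispersion
      ll <- tr$lch + lbeta(tr$alt + s1[tr$v], tr$ref + s2[tr$v]) -
        lbeta(s1[tr$v], s2[tr$v])
      out[, j] <- .rowsum_to(ll, tr$i, prep$n)
    }
    out
  }
}

.distance_matrix <- function(prep, p_mat, config) {
  -.loglik_matrix(prep, p_mat, config) + config$distance_epsilon
}
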