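#' Doublet log-likelihood for a cluster pair
#'
#' A cross-donor doublet contains RNA from two cells in roughly equal
#' proportion, so its expected alt fraction at every site is the mean of the
#' two clusters' fractions. The doublet log-likelihood is the cell's
#' [cell_cluster_loglik] against that synthetic center.
#'
#' @param counts an [allele_counts] object.
#' @param cell cell index (1-based).
#' @param centers a [cluster_centers] object.
#' @param a,b distinct 1-based cluster indices.
#' @param config a [count_model_config].
#' @export
doublet_loglik <- function(counts, cell, centers, a, b,
                           config = count_model_config()) {
  if (a == b) .stopf("doublet clusters must differ (got %d, %d)", a, b)
  mix <- .clamp((centers$fractions[a, ] + centers$fractions[b, ]) / 2,
                config$fraction_floor)
  cell_cluster_loglik(counts, cell, mix, config)
}

#' Call singlets, doublets and unassigned cells
#'
#' For every barcode, computes the best singlet log-likelihood `L_s` over all
#' k clusters and the best doublet log-likelihood `L_d` over all k(k-1)/2
#' cluster pairs (exact search), then the posterior probability of being a
#' singlet under prior doublet rate `doublet_prior`:
#' `(1-pi) exp(L_s) / ((1-pi) exp(L_s) + pi exp(L_d))`, evaluated in log
#' space. Cells covering fewer than `min_coverage` variants are reported
#' `unassigned`; otherwise the call is `doublet` when the posterior drops
#' below 0.5 and `singlet` otherwise.
#'
#' @param counts an [allele_counts] object.
#' @param centers fitted [cluster_centers].
#' @param doublet_prior prior doublet probability in `[0, 1)`; ~0.08 is
#'   typical for a 20k-cell 10x load.
#' @param min_coverage minimum covered variants for a confident call.
#' @param config a [count_model_config].
#' @return data frame with one row per barcode: `barcode`, `status`,
#'   `assignment` (0-based id, `id1/id2`, or `.`), `log_prob_singlet`,
#'   `log_prob_doublet`, `posterior_singlet`, `primary_cluster`,
#'   `secondary_cluster` (0-based, NA unless doublet), `n_covered`, then one
#'   `cluster<j>` log-likelihood column per cluster.
#' @export
call_cells <- function(counts, centers, doublet_prior = 0.08,
                       min_coverage = 10, config = count_model_config()) {
  stopifnot(doublet_prior >= 0, doublet_prior < 1)
  prep <- .ac_prep(counts)
  k <- centers$k
  ll <- .loglik_matrix(prep, centers$fractions, config)
  best_j <- max.col(ll, ties.method = "first")
  l_s <- ll[cbind(seq_len(prep$n), best_j)]

  if (k >= 2) {
    pairs <- utils::combn(k, 2)
    pair_fr <- (centers$fractions[pairs[1, ], , drop = FALSE] +
                  centers$fractions[pairs[2, ], , drop = FALSE]) / 2
    lld <- .loglik_matrix(prep, pair_fr, config)
    best_p <- max.col(lld, ties.method = "first")
    l_d <- lld[cbind(seq_len(prep$n), best_p)]
    pa <- pairs[1, best_p]
    pb <- pairs[2, best_p]
  } else {
    l_d <- rep(-Inf, prep$n)
    pa <- pb <- rep(NA_integer_, prep$n)
  }

  # log-space posterior; doublet_prior = 0 closes the doublet channel.
  ls_term <- log1p(-doublet_prior) + l_s
  ld_term <- if (doublet_prior > 0) log(doublet_prior) + l_d else rep(-Inf, prep$n)
  mx <- pmax(ls_term, ld_term)
  post_singlet <- exp(ls_term - (mx + log(exp(ls_term - mx) + exp(ld_term - mx))))

  status <- ifelse(post_singlet < 0.5, "doublet", "singlet")
  status[prep$ncov < min_coverage] <- "unassigned"
  is_dbl <- status == "doublet"
  primary <- best_j - 1L
  secondary <- rep(NA_integer_, prep$n)
  if (any(is_dbl)) {
    # primary = pair member with the higher singlet log-likelihood
    lla <- ll[cbind(which(is_dbl), pa[is_dbl])]
    llb <- ll[cbind(which(is_dbl), pb[is_dbl])]
    pri <- ifelse(lla >= llb, pa[is_dbl], pb[is_dbl])
    sec <- ifelse(lla >= llb, pb[is_dbl], pa[is_dbl])
    primary[is_dbl] <- pri - 1L
    secondary[is_dbl] <- sec - 1L
  }
  assignment <- as.character(primary)
  assignment[is_dbl] <- sprintf("%d/%d",
                                pmin(primary[is_dbl], secondary[is_dbl]),
                                pmax(primary[is_dbl], secondary[is_dbl]))
  assignment[status == "unassigned"] <- "."

  out <- data.frame(
    barcode = counts$barcodes, status = status, assignment = assignment,
    log_prob_singlet = l_s, log_prob_doublet = l_d,
    posterior_singlet = post_singlet,
    primary_cluster = primary, secondary_cluster = secondary,
    n_covered = prep$ncov, stringsAsFactors = FALSE
  )
  lldf <- as.data.frame(ll)
  names(lldf) <- paste0("cluster", seq_len(k) - 1L)
  cbind(out, lldf)
}
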