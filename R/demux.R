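#' Demultiplex a pooled mixture by genotype
#'
#' The package's main fitting function. Runs the full clustering pipeline on
#' per-cell allele counts:
#'
#' 1. 10x merge initialization ([initialize_10x]) of
#'    `overcluster * k` centers — overclustering at this stage means every
#'    donor can claim at least one center, so donors are almost never merged
#'    by the optimizer;
#' 2. annealed K-Harmonic Means ([anneal_fit]) over the overclustered set;
#' 3. reduction to `k`: centers whose hard occupancy falls below
#'    `prune_occupancy` times the median occupancy are dropped as junk,
#'    then the closest surviving pairs (duplicated donors) are merged with
#'    [merge_to_k];
#' 4. a second [anneal_fit] at `k` followed by the hard maximum-likelihood
#'    polish ([polish_centers]) that turns soft blended centers into sharp
#'    per-donor consensus genotypes;
#' 5. iterative refinement with cluster locking ([refine]);
#' 6. per-cell singlet/doublet calling ([call_cells]).
#'
#' @param counts an [allele_counts] object.
#' @param k expected number of donors (>= 1); not inferred.
#' @param doublet_prior prior doublet probability (see [call_cells]).
#' @param min_coverage minimum covered variants for a confident call.
#' @param count_config a [count_model_config].
#' @param khm a [khm_config]; defaults to one built from `count_config`.
#' @param refine_cfg a [refine_config]; defaults to seed `seed + 1`.
#' @param overcluster multiple of `k` used for the organizing fit (stage 2);
#'   1 disables overclustering.
#' @param prune_occupancy junk threshold on hard occupancy, as a fraction of
#'   the median occupancy of non-empty centers.
#' @param seed integer master seed; the whole fit is deterministic given it.
#' @param verbose print per-stage progress to stderr.
#' @return An object of class `demux_fit` with elements `calls` (per-cell
#'   data frame), `centers`, `assignment`, `scores` (cluster quality table),
#'   `loss` (final KHM loss), `trace` (full loss trace), `rounds_used`,
#'   `converged`, `k`, `counts`, and the configs. Methods: [print.demux_fit],
#'   [summary.demux_fit], [coef.demux_fit], [predict.demux_fit],
#'   [plot.demux_fit], [fitted.demux_fit].
#' @examples
#' sim <- simulate_mixture(sim_config(n_donors = 3, n_cells = 120,
#'                                    n_variants = 150, seed = 1))
#' fit <- demux(sim$counts, k = 3, seed = 1)
#' fit
#' table(fitted(fit), sim$truth$donor)
#' @export
demux <- function(counts, k, doublet_prior = 0.08, min_coverage = 10,
                  count_config = count_model_config(),
                  khm = khm_config(count_model = count_config),
                  refine_cfg = refine_config(seed = seed + 1),
                  overcluster = 2, prune_occupancy = 0.25,
                  seed = 0, verbose = FALSE) {
  if (k < 1) .stopf("k must be >= 1")
  stopifnot(overcluster >= 1)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what) {
    say("[demux] %-18s %6.1fs", what, proc.time()[["elapsed"]] - t0)
  }
  prep <- .ac_prep(counts)
  cm <- khm$count_model
  k_over <- min(ceiling(overcluster * k), n_cells(counts))

  init <- initialize_10x(counts, k_over, cm, seed = seed)
  stage(sprintf("initialized (%d)", k_over))
  fit_over <- suppressWarnings(.anneal_fit_prep(prep, init, khm))
  stage("organizing fit")

  centers <- fit_over$centers
  trace <- fit_over$trace
  if (k_over > k) {
    hard <- hard_assignment(fit_over$assignment)
    occ <- tabulate(hard, k_over)
    # Junk centers are both starved and a poor fit for what they hold; a
    # genuine minority donor's center is small but fits its cells well, so
    # the loss signal protects it from pruning.
    d_over <- .distance_matrix(prep, centers$fractions, cm)
    own <- d_over[cbind(seq_len(prep$n), hard)]
    cov <- prep$ncov > 0
    mean_loss <- rep(Inf, k_over)
    if (any(cov)) {
      sums <- .rowsum_to(own[cov], hard[cov], k_over)
      cnts <- tabulate(hard[cov], k_over)
      mean_loss[cnts > 0] <- sums[cnts > 0] / cnts[cnts > 0]
    }
    floor_occ <- max(1, prune_occupancy * stats::median(occ[occ > 0]))
    junk <- occ < floor_occ & (mean_loss > stats::median(mean_loss) | occ == 0)
    keep <- which(!junk)
    if (length(keep) < k) {
      keep <- order(occ, decreasing = TRUE)[seq_len(k)]
    }
    surv <- cluster_centers(centers$fractions[keep, , drop = FALSE])
    centers <- merge_to_k(surv, k, variant_weights(counts))
    stage(sprintf("reduced (%d kept)", length(keep)))
  }
  khm_k <- khm
  khm_k$schedule$max_sweeps <- min(khm$schedule$max_sweeps, 300L)
  fit <- suppressWarnings(.anneal_fit_prep(prep, centers, khm_k))
  trace <- c(trace, fit$trace)
  centers <- .polish_prep(prep, fit$centers, cm)
  stage("khm fit + polish")

  d <- .distance_matrix(prep, centers$fractions, cm)
  asg <- khm_soft_assignment(d, khm$power, 1)
  ref <- refine(counts, centers, asg, khm, refine_cfg)
  trace <- c(trace, ref$trace)
  stage(sprintf("refined (%d rounds)", ref$rounds_used))

  # final genotype-space sharpening: donors are diploid, so shrink centers
  # onto dosage fractions before calling cells
  centers <- .genotype_polish_prep(prep, ref$centers, cm)
  d <- .distance_matrix(prep, centers$fractions, cm)
  asg <- khm_soft_assignment(d, khm$power, 1)
  stage("genotype polish")

  calls <- call_cells(counts, centers, doublet_prior, min_coverage, cm)
  stage("called")
  structure(list(
    calls = calls, centers = centers, assignment = asg,
    scores = ref$scores, loss = khm_loss(d, khm$power),
    trace = trace, rounds_used = ref$rounds_used,
    converged = fit$converged && ref$clean, k = as.integer(k),
    counts = counts, doublet_prior = doublet_prior,
    min_coverage = min_coverage, count_config = cm,
    khm = khm, refine_cfg = refine_cfg, seed = as.integer(seed)
  ), class = "demux_fit")
}

#' @param x,object a `demux_fit`.
#' @param ... ignored.
#' @rdname demux
#' @method print demux_fit
#' @export
print.demux_fit <- function(x, ...) {
  st <- table(factor(x$calls$status,
                     levels = c("singlet", "doublet", "unassigned")))
  cat(sprintf("demux_fit: %d cells x %d variants, k = %d donors\n",
              n_cells(x$counts), n_variants(x$counts), x$k))
  cat(sprintf("  calls: %d singlet, %d doublet, %d unassigned\n",
              st[["singlet"]], st[["doublet"]], st[["unassigned"]]))
  cat(sprintf("  KHM loss %.4g after %d refinement round(s)%s\n",
              x$loss, x$rounds_used,
              if (x$converged) "" else " (not fully converged)"))
  invisible(x)
}

#' @rdname demux
#' @method summary demux_fit
#' @export
summary.demux_fit <- function(object, ...) {
  sizes <- table(factor(object$calls$primary_cluster[
    object$calls$status == "singlet"], levels = seq_len(object$k) - 1L))
  out <- list(fit = object, scores = object$scores,
              singlet_sizes = as.integer(sizes),
              doublet_rate_called =
                mean(object$calls$status == "doublet"))
  class(out) <- "summary.demux_fit"
  out
}

#' @method print summary.demux_fit
#' @export
print.summary.demux_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  called doublet rate: %.3f\n", x$doublet_rate_called))
  cat("  cluster quality:\n")
  print(x$scores, row.names = FALSE)
  invisible(x)
}

#' @rdname demux
#' @export
coef.demux_fit <- function(object, ...) {
  fr <- object$centers$fractions
  rownames(fr) <- paste0("cluster", seq_len(nrow(fr)) - 1L)
  colnames(fr) <- paste0(object$counts$variants$chrom, ":",
                         object$counts$variants$pos)
  fr
}

#' @rdname demux
#' @export
fitted.demux_fit <- function(object, ...) {
  factor(object$calls$primary_cluster, levels = seq_len(object$k) - 1L)
}

#' @param newdata optional [allele_counts] over the same variants; defaults
#'   to the training data.
#' @param type `"calls"` (data frame from [call_cells]), `"cluster"`
#'   (0-based hard labels) or `"membership"` (KHM membership matrix).
#' @rdname demux
#' @export
predict.demux_fit <- function(object, newdata = NULL,
                              type = c("calls", "cluster", "membership"),
                              ...) {
  type <- match.arg(type)
  counts <- if (is.null(newdata)) object$counts else newdata
  if (n_variants(counts) != ncol(object$centers$fractions)) {
    .stopf("newdata has %d variants but the fit has %d",
           n_variants(counts), ncol(object$centers$fractions))
  }
  if (type == "calls") {
    return(call_cells(counts, object$centers, object$doublet_prior,
                      object$min_coverage, object$count_config))
  }
  d <- .distance_matrix(.ac_prep(counts), object$centers$fractions,
                        object$count_config)
  asg <- khm_soft_assignment(d, object$khm$power, 1)
  if (type == "membership") asg$memberships else hard_assignment(asg) - 1L
}

#' @param y ignored.
#' @rdname demux
#' @export
plot.demux_fit <- function(x, y, ...) {
  plot(seq_along(x$trace), x$trace, type = "l", xlab = "KHM sweep",
       ylab = "KHM loss (T = 1)", main = "Annealed K-Harmonic Means fit",
       ...)
  invisible(x)
}
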