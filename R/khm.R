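#' Deterministic-annealing schedule
#'
#' K-Harmonic Means sweeps run at a decreasing sequence of temperatures.
#' Annealing raises distances to the power `1/T` (equivalently divides the
#' negative log-likelihoods by T), flattening the assignment landscape early
#' so centers can cross basins, then sharpening it as T falls to 1.
#'
#' @param t_start initial temperature (>= `t_min`). On log-likelihood
#'   distances the membership landscape is already nearly flat, so only mild
#'   annealing is productive; large values drive all centers into the global
#'   mean, a symmetric fixed point they cannot leave.
#' @param t_min final temperature; 1 means un-annealed KHM.
#' @param decay multiplicative temperature decay per stage, in (0, 1).
#' @param inner_iters center-update sweeps per temperature stage.
#' @param tol relative loss-change convergence threshold at `t_min`.
#' @param max_sweeps total sweep cap across the whole schedule.
#' @export
anneal_schedule <- function(t_start = 1.2, t_min = 1, decay = 0.8,
                            inner_iters = 3, tol = 1e-7, max_sweeps = 600) {
  stopifnot(t_start >= t_min, t_min >= 1, decay > 0, decay < 1,
            inner_iters >= 1, tol > 0, max_sweeps >= 1)
  structure(list(t_start = t_start, t_min = t_min, decay = decay,
                 inner_iters = inner_iters, tol = tol,
                 max_sweeps = max_sweeps),
            class = "anneal_schedule")
}

#' K-Harmonic Means configuration
#'
#' @param power KHM exponent p (>= 2). On count log-likelihood distances the
#'   membership contrast between clusters scales with the ratio of distances,
#'   which is close to 1; a higher exponent than the p ~ 3.5 used for
#'   Euclidean KHM is needed for clusters to specialize. The default 8 keeps
#'   the dynamics soft enough to self-organize from weak initial centers yet
#'   sharp enough to separate donors at high k.
#' @param schedule an [anneal_schedule].
#' @param count_model a [count_model_config].
#' @param seed integer seed (recorded for provenance; the sweeps themselves
#'   are deterministic).
#' @export
khm_config <- function(power = 8, schedule = anneal_schedule(),
                       count_model = count_model_config(), seed = 0) {
  stopifnot(power >= 2)
  structure(list(power = power, schedule = schedule,
                 count_model = count_model, seed = as.integer(seed)),
            class = "khm_config")
}

#' K-Harmonic Means loss
#'
#' `sum_i k / sum_j d_ij^(-p)`: the harmonic mean of a cell's distances to
#' all centers, summed over cells. Unlike the k-means objective, every center
#' feels every cell, which is what blunts sensitivity to initialization.
#'
#' @param distances strictly positive n x k matrix of cell-center distances.
#' @param power KHM exponent p.
#' @export
khm_loss <- function(distances, power) {
  distances <- as.matrix(distances)
  if (any(distances <= 0)) .stopf("khm_loss requires strictly positive distances")
  ld <- log(distances)
  sum(ncol(distances) * exp(-.row_lse(-power * ld)))
}

#' KHM soft assignment and per-cell weights
#'
#' Standard KHM quantities, computed in log space, with deterministic
#' annealing applied to the distances first (`d' = d^(1/T)`):
#' memberships `m_ij = d'_ij^(-p-2) / sum_l d'_il^(-p-2)` and cell weights
#' `w_i = sum_j d'_ij^(-p-2) / (sum_j d'_ij^(-p))^2`. Cells far from every
#' center get large weights, pulling centers toward unexplained data.
#'
#' @param distances strictly positive n x k matrix.
#' @param power KHM exponent p.
#' @param temperature annealing temperature T >= 1.
#' @return List of class `soft_assignment` with `memberships` (rows sum to 1)
#'   and `cell_weights` (positive).
#' @export
khm_soft_assignment <- function(distances, power, temperature = 1) {
  distances <- as.matrix(distances)
  if (any(distances <= 0)) .stopf("distances must be strictly positive")
  stopifnot(temperature >= 1)
  ld <- log(distances) / temperature
  a1 <- -(power + 2) * ld
  a2 <- -power * ld
  lse1 <- .row_lse(a1)
  memberships <- exp(a1 - lse1)
  cell_weights <- exp(lse1 - 2 * .row_lse(a2))
  structure(list(memberships = memberships, cell_weights = cell_weights),
            class = "soft_assignment")
}

#' Weighted maximum-likelihood center update
#'
#' For each unlocked cluster j and variant v, the new fraction is the
#' add-one-smoothed weighted binomial MLE
#' `(sum_i q_ij a_iv + 1) / (sum_i q_ij (a_iv + r_iv) + 2)` with
#' `q_ij = m_ij * w_i`; only cells covering v contribute. Locked clusters are
#' returned bit-identical.
#'
#' @param counts an [allele_counts] object.
#' @param assignment a `soft_assignment` from [khm_soft_assignment].
#' @param centers current [cluster_centers] (source of lock flags).
#' @param config a [khm_config].
#' @export
update_centers <- function(counts, assignment, centers, config = khm_config()) {
  prep <- .ac_prep(counts)
  .update_centers_prep(prep, assignment, centers, config$count_model)
}

.update_centers_prep <- function(prep, assignment, centers, cm_config) {
  q <- assignment$memberships * assignment$cell_weights
  num <- as.matrix(Matrix::crossprod(prep$A, q)) + 1    # V x k
  den <- as.matrix(Matrix::crossprod(prep$Tot, q)) + 2
  fr_new <- .clamp(t(num / den), cm_config$fraction_floor)
  fr <- centers$fractions
  fr[!centers$locked, ] <- fr_new[!centers$locked, , drop = FALSE]
  cluster_centers(fr, centers$locked)
}

#' Fit KHM under a deterministic-annealing schedule
#'
#' Runs distance -> soft assignment -> center update sweeps at each
#' temperature of the schedule, then iterates at the final temperature until
#' the relative change of the loss falls below `tol` or the sweep cap is hit
#' (in which case the best state is returned with `converged = FALSE`, not an
#' error). The loss trace is always evaluated at T = 1 distances.
#'
#' @param counts an [allele_counts] object.
#' @param centers initial [cluster_centers], typically from [initialize_10x].
#' @param config a [khm_config].
#' @return List of class `khm_fit`: `centers`, `assignment` (at T = 1),
#'   `loss`, `trace` (per-sweep T = 1 KHM loss), `sweeps`, `converged`.
#' @export
anneal_fit <- function(counts, centers, config = khm_config()) {
  prep <- .ac_prep(counts)
  .anneal_fit_prep(prep, centers, config)
}

.anneal_fit_prep <- function(prep, centers, config) {
  sch <- config$schedule
  cm <- config$count_model
  p <- config$power
  temps <- numeric(0)
  tt <- sch$t_start
  while (tt > sch$t_min) {
    temps <- c(temps, tt)
    tt <- max(sch$t_min, tt * sch$decay)
  }
  trace <- numeric(0)
  sweeps <- 0L
  sweep1 <- function(temperature) {
    d <- .distance_matrix(prep, centers$fractions, cm)
    trace[length(trace) + 1L] <<- khm_loss(d, p)
    asg <- khm_soft_assignment(d, p, temperature)
    centers <<- .update_centers_prep(prep, asg, centers, cm)
    sweeps <<- sweeps + 1L
  }
  for (temperature in temps) {
    for (it in seq_len(sch$inner_iters)) {
      if (sweeps >= sch$max_sweeps) break
      sweep1(temperature)
    }
  }
  converged <- FALSE
  repeat {
    if (sweeps >= sch$max_sweeps) break
    sweep1(sch$t_min)
    nt <- length(trace)
    if (nt >= 2) {
      rel <- abs(trace[nt] - trace[nt - 1]) / max(1, abs(trace[nt - 1]))
      if (rel < sch$tol) { converged <- TRUE; break }
    }
  }
  if (!converged) {
    warning("anneal_fit: sweep cap reached before loss converged",
            call. = FALSE)
  }
  d <- .distance_matrix(prep, centers$fractions, cm)
  asg <- khm_soft_assignment(d, p, 1)
  structure(list(centers = centers, assignment = asg,
                 loss = khm_loss(d, p), trace = trace,
                 sweeps = sweeps, converged = converged),
            class = "khm_fit")
}

#' Hard maximum-likelihood center polish
#'
#' Alternates hard maximum-likelihood assignment with a center update
#' (Lloyd-style) until centers stop moving. Soft KHM blends neighboring
#' clusters into each center; once the cluster structure is correct, this
#' sharpening step recovers per-donor consensus genotypes and measurably
#' improves per-cell assignment. Locked clusters keep their centers; their
#' cells still participate in the assignment.
#'
#' Two update modes are available. `"mle"` is the add-one-smoothed binomial
#' MLE of the cluster's pooled counts. `"genotype"` exploits that donors are
#' diploid, so true alt fractions lie in dosage space: each (cluster,
#' variant) fraction becomes the posterior mean of the dosage fractions
#' (floor, 1/2, 1 - floor) given the cluster's pooled counts, under a
#' Hardy-Weinberg prior built from the pooled population alt frequency.
#' This empirical-Bayes shrinkage matters most for small clusters (minority
#' donors), whose raw fraction estimates are noisy enough to strand their
#' own cells in neighboring clusters.
#'
#' @param counts an [allele_counts] object.
#' @param centers fitted [cluster_centers].
#' @param config a [khm_config].
#' @param max_iters iteration cap.
#' @param mode `"mle"` (default) or `"genotype"`.
#' @return A [cluster_centers] object.
#' @export
polish_centers <- function(counts, centers, config = khm_config(),
                           max_iters = 50, mode = c("mle", "genotype")) {
  mode <- match.arg(mode)
  prep <- .ac_prep(counts)
  if (mode == "mle") {
    .polish_prep(prep, centers, config$count_model, max_iters)
  } else {
    .genotype_polish_prep(prep, centers, config$count_model, max_iters)
  }
}

# Dosage-space EM: hard assignment + per-(cluster, variant) posterior-mean
# dosage fraction under a Hardy-Weinberg prior from the pooled alt frequency.
.genotype_polish_prep <- function(prep, centers, cm_config, max_iters = 80) {
  fr <- centers$fractions
  k <- nrow(fr)
  eps <- cm_config$fraction_floor
  doses <- c(eps, 0.5, 1 - eps)
  f_v <- (prep$col_alt + 1) / (prep$col_tot + 2)
  log_prior <- cbind(2 * log1p(-f_v),
                     log(2) + log(f_v) + log1p(-f_v),
                     2 * log(f_v))
  for (it in seq_len(max_iters)) {
    ll <- .loglik_matrix(prep, fr, cm_config)
    hard <- max.col(ll, ties.method = "first")
    q <- matrix(0, prep$n, k)
    q[cbind(seq_len(prep$n), hard)] <- 1
    a <- as.matrix(Matrix::crossprod(prep$A, q))        # V x k alt sums
    tt <- as.matrix(Matrix::crossprod(prep$Tot, q))     # V x k totals
    lp <- lapply(1:3, function(j)
      a * log(doses[j]) + (tt - a) * log1p(-doses[j]) + log_prior[, j])
    mx <- pmax(lp[[1]], lp[[2]], lp[[3]])
    w1 <- exp(lp[[1]] - mx); w2 <- exp(lp[[2]] - mx); w3 <- exp(lp[[3]] - mx)
    fr_new <- .clamp(t((doses[1] * w1 + doses[2] * w2 + doses[3] * w3) /
                         (w1 + w2 + w3)), eps)
    fr_new[centers$locked, ] <- fr[centers$locked, , drop = FALSE]
    if (max(abs(fr_new - fr)) < 1e-12) { fr <- fr_new; break }
    fr <- fr_new
  }
  cluster_centers(fr, centers$locked)
}

.polish_prep <- function(prep, centers, cm_config, max_iters = 50) {
  fr <- centers$fractions
  k <- nrow(fr)
  for (it in seq_len(max_iters)) {
    ll <- .loglik_matrix(prep, fr, cm_config)
    hard <- max.col(ll, ties.method = "first")
    q <- matrix(0, prep$n, k)
    q[cbind(seq_len(prep$n), hard)] <- 1
    num <- as.matrix(Matrix::crossprod(prep$A, q)) + 1
    den <- as.matrix(Matrix::crossprod(prep$Tot, q)) + 2
    fr_new <- .clamp(t(num / den), cm_config$fraction_floor)
    fr_new[centers$locked, ] <- fr[centers$locked, , drop = FALSE]
    if (max(abs(fr_new - fr)) < 1e-12) { fr <- fr_new; break }
    fr <- fr_new
  }
  cluster_centers(fr, centers$locked)
}

#' Hard cluster assignment from a soft assignment
#'
#' Argmax membership per cell; ties go to the lowest cluster id.
#'
#' @param assignment a `soft_assignment`.
#' @return Integer vector of 1-based cluster indices.
#' @export
hard_assignment <- function(assignment) {
  max.col(assignment$memberships, ties.method = "first")
}
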