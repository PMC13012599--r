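#' Refinement configuration
#'
#' After the first KHM fit, clusters are scored on how many cells they hold
#' and how badly they fit them; outliers are reinitialized and the healthy
#' clusters are locked while the model refits.
#'
#' @param size_z_cut robust z-score threshold on `log(1 + n_cells)`: clusters
#'   below `-size_z_cut` are size outliers.
#' @param loss_z_cut robust z-score threshold on per-member mean loss:
#'   clusters above `loss_z_cut` are fit outliers.
#' @param lock_fraction fraction of non-outlier clusters locked each round
#'   (resampled every round). The default locks all of them: an accepted
#'   round can then only change what the outlier clusters explain.
#' @param max_rounds refinement-round cap.
#' @param seed integer seed driving the reinitialization and lock sampling.
#' @param reinit_from `"members"` (default): reinitialization runs on the
#'   cells currently assigned to the outlier clusters (the worst-explained
#'   cells in the fit); `"worst_fit"`: on the globally worst-explained cells;
#'   `"uniform"`: preliminary centers are seeded from uniformly sampled cells.
#' @export
refine_config <- function(size_z_cut = 2.5, loss_z_cut = 2.5,
                          lock_fraction = 1.0, max_rounds = 10, seed = 0,
                          reinit_from = c("members", "worst_fit", "uniform")) {
  stopifnot(lock_fraction >= 0, lock_fraction <= 1, max_rounds >= 1)
  structure(list(size_z_cut = size_z_cut, loss_z_cut = loss_z_cut,
                 lock_fraction = lock_fraction,
                 max_rounds = as.integer(max_rounds),
                 seed = as.integer(seed),
                 reinit_from = match.arg(reinit_from)),
            class = "refine_config")
}

# Robust z-scores: median/MAD (mad() already scales by 1.4826). The MAD is
# floored at 2% of |median| so that near-degenerate dispersion (a handful of
# clusters with almost identical scores) cannot inflate z-scores; a zero
# effective MAD means no dispersion to judge against, and callers handle
# that case explicitly.
.robust_z <- function(x) {
  madv <- max(stats::mad(x), 0.02 * abs(stats::median(x)))
  if (madv == 0) rep(0, length(x)) else (x - stats::median(x)) / madv
}

#' Score cluster quality
#'
#' Each cluster is scored by its hard-assigned cell count and the mean KHM
#' distance of its members to its own center (zero-coverage cells excluded).
#' A cluster is an outlier if its size is a low robust-z outlier (or it is
#' empty) or its mean loss a high robust-z outlier. With zero MAD on sizes,
#' only truly empty clusters are size outliers; with zero MAD on losses, no
#' loss outliers are flagged.
#'
#' @param counts an [allele_counts] object.
#' @param centers fitted [cluster_centers].
#' @param assignment the matching `soft_assignment`.
#' @param config a [khm_config].
#' @param refine a [refine_config] (for the two thresholds).
#' @return data frame with `cluster_id` (0-based), `n_cells`, `mean_loss`,
#'   `is_outlier`.
#' @export
score_clusters <- function(counts, centers, assignment,
                           config = khm_config(), refine = refine_config()) {
  prep <- .ac_prep(counts)
  .score_clusters_prep(prep, centers, assignment, config, refine)
}

.score_clusters_prep <- function(prep, centers, assignment, config, refine) {
  k <- centers$k
  hard <- hard_assignment(assignment)
  d <- .distance_matrix(prep, centers$fractions, config$count_model)
  own <- d[cbind(seq_len(prep$n), hard)]
  covered <- prep$ncov > 0
  n_cells <- tabulate(hard, k)
  mean_loss <- numeric(k)
  if (any(covered)) {
    sums <- .rowsum_to(own[covered], hard[covered], k)
    cnts <- tabulate(hard[covered], k)
    mean_loss[cnts > 0] <- sums[cnts > 0] / cnts[cnts > 0]
  }
  size_out <- .robust_z(log1p(n_cells)) < -refine$size_z_cut | n_cells == 0
  loss_out <- .robust_z(mean_loss) > refine$loss_z_cut
  data.frame(cluster_id = seq_len(k) - 1L, n_cells = n_cells,
             mean_loss = mean_loss, is_outlier = size_out | loss_out)
}

#' Reinitialization centers for outlier clusters
#'
#' Builds `m` replacement centers with the same 10x merge recipe as
#' [initialize_10x]: `10 * m` preliminary centers seeded from cells, merged
#' down to `m`. The seeding pool depends on `refine$reinit_from`: by default
#' the members of the outlier clusters themselves — outlier clusters sit
#' exactly where probability mass is unexplained, so their member cells are
#' the material the replacements must explain. When a current fit is
#' supplied, the merged centers are additionally optimized against that
#' pool (a small KHM fit plus hard polish restricted to the pool cells),
#' which turns blurred preliminary averages into genuine sub-genotypes.
#'
#' @param counts an [allele_counts] object.
#' @param m number of outlier clusters to replace.
#' @param centers current [cluster_centers] (used to pick the seeding pool);
#'   may be `NULL` with `reinit_from = "uniform"`.
#' @param config a [khm_config].
#' @param refine a [refine_config].
#' @param seed integer seed.
#' @param pool optional explicit cell indices overriding the pool choice.
#' @return A [cluster_centers] with `m` rows and attribute `n_preliminary`
#'   (`min(10 * m, pool size)`).
#' @export
reinit_centers <- function(counts, m, centers = NULL, config = khm_config(),
                           refine = refine_config(), seed = 0, pool = NULL) {
  prep <- .ac_prep(counts)
  .reinit_centers_prep(counts, prep, m, centers, config, refine, seed, pool)
}

.reinit_pool <- function(prep, centers, config, refine, m) {
  if (refine$reinit_from == "uniform" || is.null(centers)) {
    return(seq_len(prep$n))
  }
  ll <- .loglik_matrix(prep, centers$fractions, config$count_model)
  eligible <- which(prep$ncov > 0)
  if (refine$reinit_from == "members") {
    # .reinit_pool is only called without an explicit pool; members-mode
    # callers (refine) pass the member pool themselves, so fall through to
    # worst-fit behaviour here.
  }
  best <- ll[cbind(seq_len(prep$n), max.col(ll, ties.method = "first"))]
  per_site <- best[eligible] / prep$ncov[eligible]
  ord <- eligible[order(per_site)]                  # worst-explained first
  ord[seq_len(max(min(10L * m, length(ord)),
                  min(length(ord), ceiling(length(ord) / 4))))]
}

.reinit_centers_prep <- function(counts, prep, m, centers, config, refine,
                                 seed, pool = NULL) {
  stopifnot(m >= 1)
  cm <- config$count_model
  if (is.null(pool)) pool <- .reinit_pool(prep, centers, config, refine, m)
  pool <- pool[prep$ncov[pool] > 0]
  if (length(pool) < 2L * m) pool <- order(prep$ncov, decreasing = TRUE)[
    seq_len(min(prep$n, max(2L * m, 20L)))]
  n_pre <- min(10L * as.integer(m), length(pool))
  cells <- if (length(pool) == n_pre) pool else
    .local_seed(seed, sample(pool, n_pre))
  pre <- .random_centers_prep(prep, n_pre, cm, seed, cells)
  w <- as.numeric(prep$col_tot)
  out <- merge_to_k(pre, m, w)
  if (!is.null(centers)) {
    # optimize the merged centers against the pool cells only
    sub <- allele_counts(counts$ref[pool, , drop = FALSE],
                         counts$alt[pool, , drop = FALSE],
                         counts$barcodes[pool], counts$variants)
    sub_prep <- .ac_prep(sub)
    sub_cfg <- khm_config(power = config$power,
                          schedule = anneal_schedule(
                            t_start = config$schedule$t_start,
                            tol = 1e-6, max_sweeps = 200),
                          count_model = cm, seed = seed)
    sub_fit <- suppressWarnings(.anneal_fit_prep(sub_prep, out, sub_cfg))
    out <- .polish_prep(sub_prep, sub_fit$centers, cm)
  }
  attr(out, "n_preliminary") <- n_pre
  out
}

#' Iterative cluster refinement with locking
#'
#' Loop: score clusters; if none is an outlier, stop. Otherwise rebuild the
#' m outlier centers with [reinit_centers] (seeded from the outlier
#' clusters' own cells), lock `ceil(lock_fraction * (k - m))` randomly
#' chosen non-outlier clusters, rerun the annealed KHM fit plus hard polish
#' with the locks in place, and unlock. A round is accepted only if it
#' improves the total best-assignment log-likelihood; a rejected round is
#' rolled back and the next round draws a different seed. Runs up to
#' `max_rounds` rounds; deterministic given the seeds in the configs.
#'
#' @param counts an [allele_counts] object.
#' @param centers fitted [cluster_centers] from [anneal_fit].
#' @param assignment the matching `soft_assignment`.
#' @param config a [khm_config].
#' @param refine a [refine_config].
#' @return List of class `refine_result`: `centers`, `assignment`,
#'   `rounds_used`, `clean` (TRUE iff the final scoring has no outliers),
#'   `reinit_preliminary` (preliminary-center count per round),
#'   `accepted` (logical per round), `trace` (refit loss traces), `scores`
#'   (final cluster scores).
#' @export
refine <- function(counts, centers, assignment, config = khm_config(),
                   refine = refine_config()) {
  prep <- .ac_prep(counts)
  k <- centers$k
  rounds <- 0L
  reinit_pre <- integer(0)
  accepted <- logical(0)
  trace <- numeric(0)
  obj <- function(cc) {
    ll <- .loglik_matrix(prep, cc$fractions, config$count_model)
    sum(ll[cbind(seq_len(prep$n), max.col(ll, ties.method = "first"))])
  }
  best_obj <- obj(centers)
  # Refits start from a locked, nearly-converged state; a shorter sweep cap
  # loses nothing (the hard polish finishes the job).
  refit_cfg <- config
  refit_cfg$schedule$max_sweeps <- min(config$schedule$max_sweeps, 200L)
  consecutive_rejects <- 0L
  repeat {
    scores <- .score_clusters_prep(prep, centers, assignment, config, refine)
    out_idx <- which(scores$is_outlier)
    if (!length(out_idx) || rounds >= refine$max_rounds) break
    rounds <- rounds + 1L
    m <- length(out_idx)
    round_seed <- refine$seed + 101L * rounds
    hard <- hard_assignment(assignment)
    pool <- if (refine$reinit_from == "members") {
      which(hard %in% out_idx)
    } else NULL
    newc <- .reinit_centers_prep(counts, prep, m, centers, config, refine,
                                 round_seed, pool)
    reinit_pre <- c(reinit_pre, attr(newc, "n_preliminary"))
    fr <- centers$fractions
    fr[out_idx, ] <- newc$fractions
    locked <- rep(FALSE, k)
    keep <- setdiff(seq_len(k), out_idx)
    n_lock <- ceiling(refine$lock_fraction * length(keep))
    if (n_lock > 0) {
      lock_ids <- .local_seed(round_seed + 1L,
                              keep[sample.int(length(keep), n_lock)])
      locked[lock_ids] <- TRUE
    }
    fit <- suppressWarnings(
      .anneal_fit_prep(prep, cluster_centers(fr, locked), refit_cfg))
    polished <- .polish_prep(prep, fit$centers, config$count_model)
    cand <- cluster_centers(polished$fractions)        # release locks
    cand_obj <- obj(cand)
    if (cand_obj > best_obj) {
      best_obj <- cand_obj
      centers <- cand
      d <- .distance_matrix(prep, centers$fractions, config$count_model)
      assignment <- khm_soft_assignment(d, config$power, 1)
      trace <- c(trace, fit$trace)
      accepted <- c(accepted, TRUE)
      consecutive_rejects <- 0L
    } else {
      accepted <- c(accepted, FALSE)
      consecutive_rejects <- consecutive_rejects + 1L
      if (consecutive_rejects >= 3L) break
    }
  }
  if (any(scores$is_outlier) && rounds > 0) {
    warning("refine: stopped with outlier clusters remaining", call. = FALSE)
  }
  structure(list(centers = centers, assignment = assignment,
                 rounds_used = rounds, clean = !any(scores$is_outlier),
                 reinit_preliminary = reinit_pre, accepted = accepted,
                 trace = trace, scores = scores),
            class = "refine_result")
}
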