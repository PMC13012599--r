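# K-Harmonic Means: loss, soft assignment, center updates, annealed fit.

test_that("KHM loss matches hand calculations and the brute-force oracle", {
  expect_equal(khm_loss(matrix(c(1, 1), 1), power = 2), 1.0)
  expect_equal(khm_loss(matrix(c(1, 10), 1), power = 2), 2 / (1 + 0.01),
               tolerance = 1e-12)
  # equidistant cell: loss is d^p
  for (d in c(0.5, 2, 7)) {
    expect_equal(khm_loss(matrix(d, 1, 3), power = 3), d^3, tolerance = 1e-9)
  }
  set.seed(23)
  for (rep in 1:20) {
    d <- matrix(runif(6 * 4, 0.1, 20), 6, 4)
    p <- sample(c(2, 3, 3.5, 8), 1)
    expect_equal(khm_loss(d, p), oracle_khm_loss(d, p), tolerance = 1e-9)
  }
  expect_error(khm_loss(matrix(c(1, 0), 1), 2), "positive")
})

test_that("soft assignment matches hand values and the brute-force oracle", {
  # equidistant: uniform memberships at any temperature
  for (tt in c(1, 2, 10)) {
    sa <- khm_soft_assignment(matrix(3, 2, 3), power = 3, temperature = tt)
    expect_equal(sa$memberships, matrix(1 / 3, 2, 3), tolerance = 1e-12)
  }
  # distances (1, 10), p = 2: memberships proportional to (1, 1e-4)
  sa <- khm_soft_assignment(matrix(c(1, 10), 1), power = 2)
  expect_equal(sa$memberships[1, ], c(1, 1e-4) / (1 + 1e-4),
               tolerance = 1e-9)
  # high temperature flattens toward uniform
  hot <- khm_soft_assignment(matrix(c(1, 10), 1), power = 2,
                             temperature = 1000)
  expect_equal(hot$memberships[1, ], c(0.5, 0.5), tolerance = 1e-2)
  set.seed(41)
  for (rep in 1:20) {
    d <- matrix(runif(5 * 4, 0.2, 30), 5, 4)
    p <- sample(c(2, 3, 8), 1)
    tt <- sample(c(1, 1.5, 4), 1)
    o <- oracle_khm_soft(d, p, tt)
    got <- khm_soft_assignment(d, p, tt)
    expect_equal(got$memberships, o$memberships, tolerance = 1e-9)
    expect_equal(got$cell_weights, o$cell_weights, tolerance = 1e-9)
  }
})

test_that("membership rows sum to one and weights stay positive", {
  set.seed(2)
  d <- matrix(exp(runif(200 * 8, log(1e-6), log(500))), 200, 8)
  sa <- khm_soft_assignment(d, power = 8)
  expect_equal(rowSums(sa$memberships), rep(1, 200), tolerance = 1e-9)
  expect_true(all(sa$cell_weights > 0))
  expect_true(all(is.finite(sa$cell_weights)))
})

test_that("center update is the smoothed weighted MLE and honors locks", {
  ac <- make_counts(ref = rbind(c(1, 0), c(2, 5)),
                    alt = rbind(c(3, 0), c(2, 5)))
  # all mass on cell 1 for cluster 1; cluster 2 starves
  asg <- structure(list(memberships = rbind(c(1, 0), c(0, 0)),
                        cell_weights = c(1, 1e-12)),
                   class = "soft_assignment")
  centers <- cluster_centers(rbind(c(0.5, 0.5), c(0.42, 0.37)))
  up <- update_centers(ac, asg, centers, khm_config())
  expect_equal(up$fractions[1, 1], (3 + 1) / (4 + 2), tolerance = 1e-9)
  # variant 2 unobserved by cell 1: falls to the 1/2 smoothing prior
  expect_equal(up$fractions[1, 2], 0.5, tolerance = 1e-6)
  # starved cluster: both variants at the prior
  expect_equal(up$fractions[2, ], c(0.5, 0.5), tolerance = 1e-6,
               ignore_attr = TRUE)
  # a locked cluster is returned bit-identical
  locked <- cluster_centers(rbind(c(0.5, 0.5), c(0.42, 0.37)),
                            locked = c(FALSE, TRUE))
  up2 <- update_centers(ac, asg, locked, khm_config())
  expect_identical(up2$fractions[2, ], locked$fractions[2, ])
})

test_that("the T=1 loss settles from a well-separated start", {
  # the center update is a fixed-point iteration, not an exact descent step,
  # so the trace may wobble at the relative 1e-4 level while it relaxes from
  # the true dosage centers to the smoothed fixed point
  sim <- simulate_mixture(sim_config(n_donors = 4, n_cells = 240,
                                     n_variants = 600, coverage_density = 0.2,
                                     depth_mean = 2, error_rate = 0.001,
                                     maf_alpha = 1, maf_beta = 1, seed = 13))
  truth_centers <- cluster_centers(demuxkhm:::.clamp(sim$genotypes / 2, 0.01))
  cfg <- khm_config(power = 3,
                    schedule = anneal_schedule(t_start = 1, max_sweeps = 60))
  fit <- anneal_fit(sim$counts, truth_centers, cfg)
  dl <- diff(fit$trace)
  expect_true(all(dl <= 1e-4 * abs(fit$trace[-length(fit$trace)])))
  expect_lte(fit$trace[length(fit$trace)], fit$trace[1])
  expect_true(fit$converged)
  # and the fit stays at the truth
  hard <- hard_assignment(fit$assignment)
  expect_identical(adjusted_rand_index(sim$truth$donor, hard), 1)
})

test_that("k=1 converges to the pooled smoothed allele fractions", {
  # at p=2 the KHM cell weights are identically 1 for a single cluster, so
  # the single-center fixed point is exactly the pooled smoothed fraction
  sim <- sep_mixture(2, 50, 40, seed = 19)
  init <- random_centers(sim$counts, 1, seed = 1)
  fit <- anneal_fit(sim$counts, init, khm_config(power = 2))
  tot <- sim$counts$ref + sim$counts$alt
  pooled <- demuxkhm:::.clamp(
    (Matrix::colSums(sim$counts$alt) + 1) / (Matrix::colSums(tot) + 2), 0.01)
  expect_equal(fit$centers$fractions[1, ], pooled, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("permuting initial centers permutes the fitted state identically", {
  sim <- sep_mixture(3, 90, 70, seed = 22)
  init <- initialize_10x(sim$counts, 3, seed = 7)
  cfg <- khm_config(schedule = anneal_schedule(max_sweeps = 40))
  fit1 <- suppressWarnings(anneal_fit(sim$counts, init, cfg))
  perm <- c(3, 1, 2)
  init_p <- cluster_centers(init$fractions[perm, , drop = FALSE])
  fit2 <- suppressWarnings(anneal_fit(sim$counts, init_p, cfg))
  expect_equal(fit2$centers$fractions, fit1$centers$fractions[perm, ],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit2$assignment$memberships,
               fit1$assignment$memberships[, perm], tolerance = 1e-9)
})

test_that("cells with no covered variants stay uniform and finite", {
  ref <- rbind(c(2, 1), c(0, 0), c(1, 3))
  alt <- rbind(c(1, 0), c(0, 0), c(2, 0))
  ac <- make_counts(ref, alt)
  init <- cluster_centers(rbind(c(0.2, 0.8), c(0.7, 0.3)))
  fit <- anneal_fit(ac, init, khm_config(schedule = anneal_schedule(max_sweeps = 20)))
  expect_true(all(is.finite(fit$centers$fractions)))
  expect_equal(fit$assignment$memberships[2, ], c(0.5, 0.5),
               tolerance = 1e-9)
})

test_that("two-donor mixtures are solved exactly from the 10x merge init", {
  # sparse shallow regime the tool targets: ~80 covered sites per cell
  sim <- simulate_mixture(sim_config(n_donors = 2, n_cells = 200,
                                     n_variants = 800, coverage_density = 0.1,
                                     depth_mean = 2, error_rate = 0.001,
                                     maf_alpha = 1, maf_beta = 1, seed = 33))
  fit <- suppressWarnings(anneal_fit(sim$counts, initialize_10x(sim$counts, 2, seed = 1),
                                     khm_config()))
  hard <- hard_assignment(fit$assignment)
  expect_identical(adjusted_rand_index(sim$truth$donor, hard), 1)
})

test_that("hard polish sharpens centers toward per-donor consensus", {
  sim <- sep_mixture(4, 200, 120, seed = 44)
  fit <- suppressWarnings(demux(sim$counts, k = 4, seed = 2))
  soft <- suppressWarnings(anneal_fit(sim$counts,
    cluster_centers(fit$centers$fractions), khm_config(
      schedule = anneal_schedule(t_start = 1, max_sweeps = 30))))
  pol <- polish_centers(sim$counts, soft$centers)
  truth_centers <- demuxkhm:::.clamp(sim$genotypes / 2, 0.01)
  mm <- donor_modal_map(sim$truth$donor, fit$calls$primary_cluster)
  ord <- as.integer(mm$modal_cluster) + 1L
  mae_pol <- mean(abs(pol$fractions[ord, ] - truth_centers))
  mae_soft <- mean(abs(soft$centers$fractions[ord, ] - truth_centers))
  expect_lte(mae_pol, mae_soft + 1e-9)
  expect_lt(mae_pol, 0.05)
})
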