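# Cluster quality scoring and the reinitialize-and-lock refinement loop.

test_that("clusters of identical size and loss are never outliers", {
  # perfectly symmetric two-cluster data: zero dispersion in both signals
  ref <- rbind(matrix(rep(c(2, 0), each = 10), 10, 2),
               matrix(rep(c(0, 2), each = 10), 10, 2))
  alt <- rbind(matrix(rep(c(0, 2), each = 10), 10, 2),
               matrix(rep(c(2, 0), each = 10), 10, 2))
  ac <- make_counts(ref, alt)
  centers <- cluster_centers(rbind(c(0.01, 0.99), c(0.99, 0.01)))
  d <- demuxkhm:::.distance_matrix(demuxkhm:::.ac_prep(ac),
                                   centers$fractions, count_model_config())
  asg <- khm_soft_assignment(d, 8, 1)
  sc <- score_clusters(ac, centers, asg)
  expect_identical(sc$n_cells, c(10L, 10L))
  expect_equal(sc$mean_loss[1], sc$mean_loss[2])
  expect_false(any(sc$is_outlier))
})

test_that("a balanced solved mixture scores clean", {
  sim <- sep_mixture(8, 400, 200, seed = 61)
  fit <- suppressWarnings(demux(sim$counts, k = 8, seed = 3))
  sc <- score_clusters(sim$counts, fit$centers, fit$assignment)
  expect_identical(nrow(sc), 8L)
  expect_true(all(sc$n_cells > 0))
  expect_false(any(sc$is_outlier))
})

test_that("an empty cluster is always flagged", {
  sim <- sep_mixture(3, 120, 80, seed = 62)
  fit <- suppressWarnings(anneal_fit(sim$counts,
    initialize_10x(sim$counts, 3, seed = 2), khm_config()))
  # append a center far outside the data: it attracts nothing
  fr <- rbind(fit$centers$fractions, rep(0.5, 80))
  fr[4, ] <- demuxkhm:::.clamp(rep(0.99, 80), 0.01)
  centers <- cluster_centers(fr)
  d <- demuxkhm:::.distance_matrix(demuxkhm:::.ac_prep(sim$counts),
                                   centers$fractions, count_model_config())
  asg <- khm_soft_assignment(d, 8, 1)
  if (any(tabulate(hard_assignment(asg), 4) == 0)) {
    sc <- score_clusters(sim$counts, centers, asg)
    expect_true(sc$is_outlier[which(sc$n_cells == 0)][1])
  } else {
    skip("constructed center captured cells; nothing to flag")
  }
})

test_that("a duplicated-center initialization flags the starved cluster", {
  sim <- sep_mixture(8, 480, 240, seed = 63)
  truthP <- demuxkhm:::.clamp(sim$genotypes / 2, 0.01)
  # clusters 7 and 8 both sit on donor 8; donor 7 has no center
  fr <- truthP
  fr[7, ] <- truthP[8, ]
  fit <- suppressWarnings(anneal_fit(sim$counts, cluster_centers(fr),
    khm_config(schedule = anneal_schedule(t_start = 1, max_sweeps = 60))))
  sc <- score_clusters(sim$counts, fit$centers, fit$assignment)
  expect_true(any(sc$is_outlier))
})

test_that("reinitialization draws ten preliminary centers per outlier", {
  sim <- sep_mixture(6, 300, 150, seed = 64)
  fit <- suppressWarnings(demux(sim$counts, k = 6, seed = 1))
  rc <- reinit_centers(sim$counts, 2, fit$centers, khm_config(), seed = 9)
  expect_identical(attr(rc, "n_preliminary"), 20L)
  expect_identical(nrow(rc$fractions), 2L)
  rc3 <- reinit_centers(sim$counts, 3, fit$centers, khm_config(), seed = 9)
  expect_identical(attr(rc3, "n_preliminary"), 30L)
})

test_that("a clean clustering passes through refine unchanged", {
  sim <- sep_mixture(8, 400, 200, seed = 61)
  fit <- suppressWarnings(demux(sim$counts, k = 8, seed = 3))
  res <- refine(sim$counts, fit$centers, fit$assignment, fit$khm,
                refine_config(seed = 1))
  expect_identical(res$rounds_used, 0L)
  expect_true(res$clean)
  expect_identical(res$centers$fractions, fit$centers$fractions)
})

test_that("refinement repairs a deliberately broken initialization", {
  sim <- sep_mixture(8, 560, 300, seed = 66)
  truthP <- demuxkhm:::.clamp(sim$genotypes / 2, 0.01)
  # duplicate one donor's center and drop another donor entirely
  fr <- truthP
  fr[3, ] <- truthP[5, ]
  cfg <- khm_config(schedule = anneal_schedule(t_start = 1, max_sweeps = 80))
  broken <- suppressWarnings(anneal_fit(sim$counts, cluster_centers(fr), cfg))
  hard0 <- hard_assignment(broken$assignment)
  ari0 <- adjusted_rand_index(sim$truth$donor, hard0)
  res <- suppressWarnings(refine(sim$counts, broken$centers,
                                 broken$assignment, cfg,
                                 refine_config(seed = 2)))
  hard1 <- hard_assignment(res$assignment)
  ari1 <- adjusted_rand_index(sim$truth$donor, hard1)
  expect_gt(ari1, ari0)
  expect_gte(length(res$reinit_preliminary), 1)
  # reinitialization drew 10 preliminary centers per outlier each round
  sc_flags <- res$reinit_preliminary
  expect_true(all(sc_flags %% 1 == 0))
  # refinement never increased the number of empty clusters
  expect_lte(sum(tabulate(hard1, 8) == 0), sum(tabulate(hard0, 8) == 0))
})

test_that("locked clusters are bit-identical through a locked refit", {
  sim <- sep_mixture(5, 250, 120, seed = 67)
  fit <- suppressWarnings(anneal_fit(sim$counts,
    initialize_10x(sim$counts, 5, seed = 4), khm_config()))
  locked <- cluster_centers(fit$centers$fractions,
                            locked = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  refit <- suppressWarnings(anneal_fit(sim$counts, locked, khm_config()))
  expect_identical(refit$centers$fractions[1, ], fit$centers$fractions[1, ])
  expect_identical(refit$centers$fractions[3, ], fit$centers$fractions[3, ])
  expect_false(identical(refit$centers$fractions[2, ],
                         fit$centers$fractions[2, ]))
  pol <- polish_centers(sim$counts, locked)
  expect_identical(pol$fractions[1, ], fit$centers$fractions[1, ])
})
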