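# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately avoid the package's vectorized code paths.

# KHM loss by direct elementwise evaluation of sum_i k / sum_j d_ij^-p.
oracle_khm_loss <- function(d, p) {
  d <- as.matrix(d)
  total <- 0
  for (i in seq_len(nrow(d))) {
    total <- total + ncol(d) / sum(d[i, ]^(-p))
  }
  total
}

# KHM memberships/weights by direct evaluation (no log-space tricks).
oracle_khm_soft <- function(d, p, temperature = 1) {
  d <- as.matrix(d)^(1 / temperature)
  m <- matrix(0, nrow(d), ncol(d))
  w <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    num <- d[i, ]^(-p - 2)
    m[i, ] <- num / sum(num)
    w[i] <- sum(num) / sum(d[i, ]^(-p))^2
  }
  list(memberships = m, cell_weights = w)
}

# Hubert-Arabie ARI by exhaustive pair counting over all C(n,2) cell pairs.
oracle_ari_pairs <- function(a, b) {
  n <- length(a)
  ss <- sd <- ds <- dd <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) ss <- ss + 1
      else if (same_a && !same_b) sd <- sd + 1
      else if (!same_a && same_b) ds <- ds + 1
      else dd <- dd + 1
    }
  }
  npairs <- ss + sd + ds + dd
  expected <- (ss + sd) * (ss + ds) / npairs
  maxidx <- ((ss + sd) + (ss + ds)) / 2
  (ss - expected) / (maxidx - expected)
}

# Tiny allele_counts fixture built from dense integer matrices.
make_counts <- function(ref, alt, barcodes = NULL) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (is.null(barcodes)) barcodes <- sprintf("BC%03d", seq_len(nrow(ref)))
  sites <- data.frame(chrom = "1", pos = seq_len(ncol(ref)),
                      ref_allele = "A", alt_allele = "C",
                      stringsAsFactors = FALSE)
  allele_counts(Matrix::Matrix(ref, sparse = TRUE),
                Matrix::Matrix(alt, sparse = TRUE), barcodes, sites)
}

# Well-separated small mixture for clustering tests.
sep_mixture <- function(n_donors, n_cells, n_variants, seed,
                        doublet_rate = 0, coverage = 0.3, depth = 4) {
  simulate_mixture(sim_config(
    n_donors = n_donors, n_cells = n_cells, n_variants = n_variants,
    maf_alpha = 1, maf_beta = 1, coverage_density = coverage,
    depth_mean = depth, error_rate = 0.001, doublet_rate = doublet_rate,
    seed = seed))
}
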