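#' Simulator configuration for pooled-mixture benchmarks
#'
#' Generates a synthetic multiplexed scRNA-seq experiment with known truth:
#' D donor genotypes over V biallelic SNPs (Hardy-Weinberg dosages from a
#' Beta-distributed population alt frequency), sparse per-cell coverage,
#' low-depth reads with a base miscall rate, cross-donor doublets at a set
#' rate, and optional donor imbalance. Defaults emulate the sparse (~5%
#' covered), shallow (mean ~2 reads/site) regime of real droplet data.
#'
#' @param n_donors number of pooled donors D (>= 1).
#' @param n_cells number of cell barcodes.
#' @param n_variants number of biallelic SNPs V.
#' @param maf_alpha,maf_beta Beta parameters of the population alt-allele
#'   frequency; Beta(1, 3) skews toward low-frequency variants as SNP panels do.
#' @param coverage_density probability a (cell, variant) pair has any reads.
#' @param depth_mean mean reads at a covered site (total ~ 1 + Poisson(mean - 1)).
#' @param error_rate per-read base miscall probability.
#' @param doublet_rate fraction of barcodes containing two cells.
#' @param donor_proportions optional length-D simplex of donor loading
#'   fractions (default uniform).
#' @param seed integer seed; all outputs are deterministic given it.
#' @export
sim_config <- function(n_donors, n_cells, n_variants,
                       maf_alpha = 1, maf_beta = 3,
                       coverage_density = 0.05, depth_mean = 2,
                       error_rate = 0.005, doublet_rate = 0,
                       donor_proportions = NULL, seed = 0) {
  stopifnot(n_donors >= 1, n_cells >= 1, n_variants >= 1,
            coverage_density > 0, coverage_density <= 1,
            doublet_rate >= 0, doublet_rate < 1,
            depth_mean >= 1, error_rate >= 0, error_rate < 0.5)
  if (is.null(donor_proportions)) {
    donor_proportions <- rep(1 / n_donors, n_donors)
  }
  stopifnot(length(donor_proportions) == n_donors,
            abs(sum(donor_proportions) - 1) < 1e-8,
            all(donor_proportions > 0))
  structure(list(n_donors = as.integer(n_donors),
                 n_cells = as.integer(n_cells),
                 n_variants = as.integer(n_variants),
                 maf_alpha = maf_alpha, maf_beta = maf_beta,
                 coverage_density = coverage_density, depth_mean = depth_mean,
                 error_rate = error_rate, doublet_rate = doublet_rate,
                 donor_proportions = donor_proportions / sum(donor_proportions),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate donor genotypes
#'
#' Per variant, a population alt frequency `f ~ Beta(maf_alpha, maf_beta)`;
#' per donor, an alt dosage `~ Binomial(2, f)` (Hardy-Weinberg equilibrium).
#'
#' @param config a [sim_config].
#' @return Integer D x V matrix of alt dosages in {0, 1, 2}.
#' @export
simulate_genotypes <- function(config) {
  .local_seed(config$seed, {
    f <- stats::rbeta(config$n_variants, config$maf_alpha, config$maf_beta)
    matrix(stats::rbinom(config$n_donors * config$n_variants, 2,
                         rep(f, each = config$n_donors)),
           nrow = config$n_donors, ncol = config$n_variants)
  })
}

#' Simulate cell barcodes from donor genotypes
#'
#' Each barcode draws its donor(s) from `donor_proportions`, becoming a
#' doublet with probability `doublet_rate` (second donor distinct from the
#' first). Each (cell, variant) pair is covered independently with
#' probability `coverage_density`; covered sites draw
#' `total ~ 1 + Poisson(depth_mean - 1)` reads and
#' `alt ~ Binomial(total, p_eff)` with expected alt fraction `dosage/2`
#' (singlets) or `(dosage_a + dosage_b)/4` (doublets), perturbed by the
#' miscall rate: `p_eff = p (1 - e) + (1 - p) e`.
#'
#' @param genotypes D x V dosage matrix from [simulate_genotypes].
#' @param config the same [sim_config].
#' @return List with `counts` (an [allele_counts]) and `truth` (data frame:
#'   `barcode`, `donor`, `donor2` (0-based ids; NA for singlets),
#'   `is_doublet`).
#' @export
simulate_cells <- function(genotypes, config) {
  stopifnot(nrow(genotypes) == config$n_donors,
            ncol(genotypes) == config$n_variants)
  n <- config$n_cells; v <- config$n_variants
  .local_seed(config$seed + 1L, {
    donor1 <- sample.int(config$n_donors, n, replace = TRUE,
                         prob = config$donor_proportions)
    is_dbl <- stats::runif(n) < config$doublet_rate
    donor2 <- rep(NA_integer_, n)
    for (i in which(is_dbl)) {
      pr <- config$donor_proportions
      pr[donor1[i]] <- 0
      donor2[i] <- sample.int(config$n_donors, 1, prob = pr)
    }
    ii <- jj <- aa <- tt <- vector("list", n)
    for (i in seq_len(n)) {
      ncov <- stats::rbinom(1, v, config$coverage_density)
      if (!ncov) next
      sites <- sample.int(v, ncov)
      tot <- 1 + stats::rpois(ncov, config$depth_mean - 1)
      p <- if (is_dbl[i]) {
        (genotypes[donor1[i], sites] + genotypes[donor2[i], sites]) / 4
      } else {
        genotypes[donor1[i], sites] / 2
      }
      p_eff <- p * (1 - config$error_rate) + (1 - p) * config$error_rate
      alt <- stats::rbinom(ncov, tot, p_eff)
      ii[[i]] <- rep.int(i, ncov); jj[[i]] <- sites
      aa[[i]] <- alt; tt[[i]] <- tot
    }
    i_all <- unlist(ii); j_all <- unlist(jj)
    a_all <- unlist(aa); t_all <- unlist(tt)
    altm <- Matrix::drop0(Matrix::sparseMatrix(
      i = i_all, j = j_all, x = a_all, dims = c(n, v)))
    refm <- Matrix::drop0(Matrix::sparseMatrix(
      i = i_all, j = j_all, x = t_all - a_all, dims = c(n, v)))
    barcodes <- sprintf("BC%06d", seq_len(n))
    variants <- data.frame(chrom = "1", pos = seq_len(v),
                           ref_allele = "A", alt_allele = "C",
                           stringsAsFactors = FALSE)
    truth <- data.frame(barcode = barcodes, donor = donor1 - 1L,
                        donor2 = donor2 - 1L, is_doublet = is_dbl,
                        stringsAsFactors = FALSE)
    list(counts = allele_counts(refm, altm, barcodes, variants),
         truth = truth)
  })
}

#' Simulate a full dataset
#'
#' Convenience wrapper: [simulate_genotypes] then [simulate_cells].
#'
#' @param config a [sim_config].
#' @return List with `counts`, `truth` and `genotypes`.
#' @export
simulate_mixture <- function(config) {
  g <- simulate_genotypes(config)
  sim <- simulate_cells(g, config)
  sim$genotypes <- g
  sim
}

#' Write a simulated dataset to disk
#'
#' Emits the exact dialects [read_allele_matrices] consumes — `ref.mtx` /
#' `alt.mtx` (variants x cells on disk), `barcodes.tsv`, `variants.vcf` —
#' plus `truth.tsv` (barcode, donor, donor2, is_doublet; 0-based donor ids,
#' `.` for no second donor).
#'
#' @param sim output of [simulate_cells] or [simulate_mixture].
#' @param outdir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_sim <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- sim$counts
  Matrix::writeMM(Matrix::t(counts$ref), file.path(outdir, "ref.mtx"))
  Matrix::writeMM(Matrix::t(counts$alt), file.path(outdir, "alt.mtx"))
  writeLines(counts$barcodes, file.path(outdir, "barcodes.tsv"))
  .write_sites_vcf(counts$variants, file.path(outdir, "variants.vcf"))
  tr <- sim$truth
  out <- data.frame(barcode = tr$barcode, donor = tr$donor,
                    donor2 = ifelse(is.na(tr$donor2), ".",
                                    as.character(tr$donor2)),
                    is_doublet = as.integer(tr$is_doublet),
                    stringsAsFactors = FALSE)
  utils::write.table(out, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Read a truth table written by [write_sim]
#'
#' @param path truth.tsv file.
#' @return data frame with `barcode`, `donor`, `donor2` (NA for singlets),
#'   `is_doublet` (logical).
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character",
                                         "integer"))
  df$donor2 <- suppressWarnings(as.integer(ifelse(df$donor2 == ".", NA,
                                                  df$donor2)))
  df$is_doublet <- df$is_doublet == 1L
  df
}
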