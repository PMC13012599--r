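# Reading/writing the pipeline's file formats: MTX count matrices, barcode
# lists, VCF site lists, cell-call TSVs, cluster-genotype VCFs.

write_mtx_lines <- function(path, nrow, ncol, entries) {
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow, ncol, nrow(entries)),
               sprintf("%d %d %d", entries[, 1], entries[, 2], entries[, 3])),
             path)
}

write_vcf_lines <- function(path, n, alt = rep("C", n)) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("1\t%d\t.\tA\t%s\t.\t.\t.", seq_len(n), alt)), path)
}

io_fixture <- function(dir, ref_entries, alt_entries, nv = 3, nc = 2,
                       alt_alleles = rep("C", nv)) {
  paths <- file.path(dir, c("ref.mtx", "alt.mtx", "bc.tsv", "sites.vcf"))
  write_mtx_lines(paths[1], nv, nc, ref_entries)
  write_mtx_lines(paths[2], nv, nc, alt_entries)
  writeLines(sprintf("BC%02d", seq_len(nc)), paths[3])
  write_vcf_lines(paths[4], nv, alt_alleles)
  paths
}

test_that("matrices round-trip through disk and transpose to cells x variants", {
  dir <- withr::local_tempdir()
  # variants x cells on disk, 1-based; alt entry (variant 2, cell 1) = 3
  p <- io_fixture(dir,
                  ref_entries = rbind(c(1, 1, 2), c(3, 2, 1)),
                  alt_entries = rbind(c(2, 1, 3), c(3, 2, 2)))
  ac <- read_allele_matrices(p[1], p[2], p[3], p[4])
  expect_equal(dim(ac$ref), c(2, 3))
  expect_equal(as.matrix(ac$ref), rbind(c(2, 0, 0), c(0, 0, 1)),
               ignore_attr = TRUE)
  expect_equal(ac$alt[1, 2], 3)   # cell 1, variant 2 after transpose
  expect_equal(as.matrix(ac$alt), rbind(c(0, 3, 0), c(0, 0, 2)),
               ignore_attr = TRUE)
  expect_equal(ac$barcodes, c("BC01", "BC02"))
  expect_equal(nrow(ac$variants), 3)
})

test_that("read is insensitive to MTX entry order and sums duplicates", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "a"))
  p1 <- io_fixture(file.path(dir, "a"),
                   ref_entries = rbind(c(1, 1, 2), c(3, 2, 1)),
                   alt_entries = rbind(c(2, 1, 3), c(3, 2, 2)))
  dir.create(file.path(dir, "b"))
  p2 <- io_fixture(file.path(dir, "b"),
                   ref_entries = rbind(c(3, 2, 1), c(1, 1, 2)),
                   alt_entries = rbind(c(3, 2, 2), c(2, 1, 3)))
  a <- read_allele_matrices(p1[1], p1[2], p1[3], p1[4])
  b <- read_allele_matrices(p2[1], p2[2], p2[3], p2[4])
  expect_equal(as.matrix(a$ref), as.matrix(b$ref))
  expect_equal(as.matrix(a$alt), as.matrix(b$alt))

  dir.create(file.path(dir, "d"))
  p3 <- io_fixture(file.path(dir, "d"),
                   ref_entries = rbind(c(1, 1, 2), c(1, 1, 3), c(3, 2, 1)),
                   alt_entries = rbind(c(2, 1, 3), c(3, 2, 2)))
  d <- read_allele_matrices(p3[1], p3[2], p3[3], p3[4])
  expect_equal(d$ref[1, 1], 5)    # duplicates summed
})

test_that("dimension and content mismatches are rejected with both sizes named", {
  dir <- withr::local_tempdir()
  p <- io_fixture(dir, rbind(c(1, 1, 2)), rbind(c(1, 1, 1)))
  write_mtx_lines(file.path(dir, "alt54.mtx"), 5, 4, rbind(c(1, 1, 1)))
  write_mtx_lines(file.path(dir, "alt53.mtx"), 5, 3, rbind(c(1, 1, 1)))
  expect_error(read_allele_matrices(file.path(dir, "alt54.mtx"),
                                    file.path(dir, "alt53.mtx"), p[3], p[4]),
               "5x4.*5x3")
  # matrices disagree with barcode/VCF counts
  write_vcf_lines(file.path(dir, "sites5.vcf"), 5)
  expect_error(read_allele_matrices(p[1], p[2], p[3],
                                    file.path(dir, "sites5.vcf")),
               "5 records.*3 variants")
  writeLines(c("B1", "B2", "B3"), file.path(dir, "bc3.tsv"))
  expect_error(read_allele_matrices(p[1], p[2], file.path(dir, "bc3.tsv"),
                                    p[4]),
               "3 barcodes.*2 cells")
  # negative and non-integer values
  write_mtx_lines(file.path(dir, "neg.mtx"), 3, 2, rbind(c(1, 1, -2)))
  expect_error(read_allele_matrices(file.path(dir, "neg.mtx"), p[2], p[3],
                                    p[4]), "negative")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "3 2 1", "1 1 2.5"), file.path(dir, "frac.mtx"))
  expect_error(read_allele_matrices(file.path(dir, "frac.mtx"), p[2], p[3],
                                    p[4]), "non-integer")
})

test_that("multiallelic VCF records are rejected, not split", {
  dir <- withr::local_tempdir()
  p <- io_fixture(dir, rbind(c(1, 1, 2)), rbind(c(1, 1, 1)),
                  alt_alleles = c("C", "C,G", "C"))
  expect_error(read_allele_matrices(p[1], p[2], p[3], p[4]), "multiallelic")
})

test_that("cell-call table has the contract columns and round-trips exactly", {
  calls <- data.frame(
    barcode = c("BC1", "BC2", "BC3"),
    status = c("singlet", "doublet", "unassigned"),
    assignment = c("1", "0/2", "."),
    log_prob_singlet = c(-1.23456789012345, -20.5, 0),
    log_prob_doublet = c(-8.1, -15.25, -Inf),
    cluster0 = c(-3.5, -20.5, 0),
    cluster1 = c(-1.23456789012345, -33.125, 0),
    cluster2 = c(-9.75, -21.0625, 0),
    stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cell_calls(calls, path)
  lines <- readLines(path)
  expect_length(lines, 4)                        # header + 3 barcodes
  expect_length(strsplit(lines[1], "\t")[[1]], 5 + 3)
  back <- read_cell_calls(path)
  expect_identical(back$assignment[2], "0/2")
  for (cn in names(calls)) expect_equal(back[[cn]], calls[[cn]],
                                        tolerance = 0)
})

test_that("cluster genotypes are called from fractions at the het thresholds", {
  fr <- rbind(c(0.0, 0.5, 0.95, 0.2),
              c(0.19, 0.8, 0.81, 0.5))
  cc <- cluster_centers(fr)
  sites <- data.frame(chrom = "1", pos = 1:4, ref_allele = "A",
                      alt_allele = "C", stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_cluster_genotypes(cc, sites, path)
  lines <- readLines(path)
  records <- grep("^[^#]", lines, value = TRUE)
  expect_length(records, 4)
  fields <- strsplit(records, "\t")
  expect_length(fields[[1]], 9 + 2)              # 2 sample columns
  gts <- t(vapply(fields, function(f) f[10:11], character(2)))
  expect_equal(gts[, 1], c("0/0", "0/1", "1/1", "0/1"))
  expect_equal(gts[, 2], c("0/0", "0/1", "1/1", "0/1"))
})

test_that("a larger genotype VCF has one record per variant, one column per cluster", {
  fr <- matrix(runif(4 * 10), 4, 10)
  sites <- data.frame(chrom = "1", pos = 1:10, ref_allele = "A",
                      alt_allele = "G", stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_cluster_genotypes(cluster_centers(fr), sites, path)
  records <- grep("^[^#]", readLines(path), value = TRUE)
  expect_length(records, 10)
  expect_length(strsplit(records[1], "\t")[[1]], 9 + 4)
})
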