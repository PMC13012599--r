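# File-format frontier of the pipeline: MatrixMarket count matrices, barcode
# lists and VCF site lists in; cell-call TSV and cluster-genotype VCF out.

#' Read vartrix/cellSNP-style allele count matrices
#'
#' Loads the sparse ref/alt count matrix pair produced by allele counters such
#' as vartrix or cellSNP, together with the matching barcode list and VCF of
#' counted sites. On disk the matrices are variants x cells (the counters'
#' convention, 1-based MatrixMarket coordinates); in memory they are
#' transposed to cells x variants. Duplicate coordinate entries are summed,
#' per MatrixMarket semantics.
#'
#' @param ref_path,alt_path MatrixMarket (.mtx) files of reference / alternate
#'   read counts with identical declared dimensions.
#' @param barcodes_path plain-text file, one cell barcode per line.
#' @param vcf_path VCF (v4.x) listing the counted biallelic sites, one record
#'   per matrix row on disk.
#' @return An [allele_counts] object.
#' @export
read_allele_matrices <- function(ref_path, alt_path, barcodes_path, vcf_path) {
  refm <- Matrix::readMM(ref_path)
  altm <- Matrix::readMM(alt_path)
  if (!all(dim(refm) == dim(altm))) {
    .stopf("ref matrix is %dx%d but alt matrix is %dx%d",
           nrow(refm), ncol(refm), nrow(altm), ncol(altm))
  }
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  variants <- read_sites_vcf(vcf_path)
  if (nrow(variants) != nrow(refm)) {
    .stopf("VCF has %d records but matrices declare %d variants",
           nrow(variants), nrow(refm))
  }
  if (length(barcodes) != ncol(refm)) {
    .stopf("barcode file has %d barcodes but matrices declare %d cells",
           length(barcodes), ncol(refm))
  }
  allele_counts(Matrix::t(methods::as(refm, "CsparseMatrix")),
                Matrix::t(methods::as(altm, "CsparseMatrix")),
                barcodes, variants)
}

#' Read a VCF site list
#'
#' Extracts chrom/pos/ref/alt for each record. Multiallelic records are
#' rejected: the count matrices carry a single alt count per site.
#'
#' @param path VCF file.
#' @return data frame with columns `chrom`, `pos`, `ref_allele`, `alt_allele`.
#' @export
read_sites_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  .validate_variants(data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref_allele = as.character(fix[, "REF"]),
    alt_allele = as.character(fix[, "ALT"]),
    stringsAsFactors = FALSE
  ))
}

# Minimal sites-only VCF writer (simulator output; also reread by
# read_sites_vcf).
.write_sites_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                     variants$chrom, variants$pos,
                     variants$ref_allele, variants$alt_allele), con)
  invisible(path)
}

#' Write per-cell demultiplexing calls
#'
#' Tab-separated table with columns `barcode`, `status`
#' (singlet/doublet/unassigned), `assignment` (a 0-based cluster id, `id1/id2`
#' for doublets, `.` for unassigned), `log_prob_singlet`, `log_prob_doublet`,
#' then one log-likelihood column per cluster (`cluster0` ...). Row order
#' follows the input. Numbers are written at full precision so that
#' [read_cell_calls] reproduces them exactly.
#'
#' @param calls data frame of cell calls as returned by [call_cells].
#' @param path output file.
#' @export
write_cell_calls <- function(calls, path) {
  stopifnot(is.data.frame(calls), nrow(calls) > 0)
  llcols <- grep("^cluster[0-9]+$", names(calls), value = TRUE)
  out <- data.frame(
    barcode = calls$barcode,
    status = calls$status,
    assignment = calls$assignment,
    log_prob_singlet = .num17(calls$log_prob_singlet),
    log_prob_doublet = .num17(calls$log_prob_doublet),
    stringsAsFactors = FALSE
  )
  for (cn in llcols) out[[cn]] <- .num17(calls[[cn]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.num17 <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  out[is.infinite(x)] <- ifelse(x[is.infinite(x)] > 0, "Inf", "-Inf")
  out
}

#' @rdname write_cell_calls
#' @return `read_cell_calls` returns the calls data frame with numeric
#'   log-likelihood columns.
#' @export
read_cell_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  numcols <- setdiff(names(df), c("barcode", "status", "assignment"))
  for (cn in numcols) df[[cn]] <- as.numeric(df[[cn]])
  df
}

#' Write cluster consensus genotypes as VCF
#'
#' One record per variant, one sample column per cluster. A cluster's genotype
#' at a site is called from its alt-allele fraction: `0/0` below `het_range[1]`,
#' `1/1` above `het_range[2]`, `0/1` between (inclusive).
#'
#' @param centers a [cluster_centers] object.
#' @param variants variant site data frame (as in [allele_counts]).
#' @param path output VCF path.
#' @param het_range numeric length 2: heterozygous band on the alt fraction.
#' @export
write_cluster_genotypes <- function(centers, variants, path,
                                    het_range = c(0.2, 0.8)) {
  fr <- centers$fractions
  stopifnot(ncol(fr) == nrow(variants), length(het_range) == 2)
  k <- nrow(fr)
  gt <- matrix("0/1", k, ncol(fr))
  gt[fr < het_range[1]] <- "0/0"
  gt[fr > het_range[2]] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("CLUSTER", seq_len(k) - 1)), collapse = "\t")
  ), con)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT",
                  variants$chrom, variants$pos,
                  variants$ref_allele, variants$alt_allele)
  writeLines(paste(body, apply(gt, 2, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}
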