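#' Per-cell allele count matrices
#'
#' Container for the observed data of a pooled single-cell experiment: sparse
#' reference and alternate read counts for every cell at every biallelic SNP.
#' Rows are cells, columns are variants. An entry absent from the sparse
#' storage means "no reads", which is equivalent to an explicit zero.
#'
#' @param ref,alt sparse (or dense) nonnegative integer matrices, cells x
#'   variants, with identical dimensions.
#' @param barcodes character vector of unique cell barcodes, one per row.
#' @param variants data frame of variant sites with columns `chrom`, `pos`
#'   (1-based), `ref_allele`, `alt_allele`; one row per column of the count
#'   matrices. Sites must be biallelic.
#' @return An object of class `allele_counts`: a list with elements `ref`,
#'   `alt` (`dgCMatrix`), `barcodes` and `variants`.
#' @examples
#' ref <- Matrix::sparseMatrix(i = 1, j = 1, x = 2, dims = c(2, 3))
#' alt <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(2, 3))
#' sites <- data.frame(chrom = "1", pos = 1:3, ref_allele = "A", alt_allele = "C")
#' ac <- allele_counts(ref, alt, c("BC1", "BC2"), sites)
#' n_cells(ac)
#' @export
allele_counts <- function(ref, alt, barcodes, variants) {
  ref <- .as_count_matrix(ref, "ref")
  alt <- .as_count_matrix(alt, "alt")
  if (!all(dim(ref) == dim(alt))) {
    .stopf("ref and alt count matrices differ in shape: %dx%d vs %dx%d",
           nrow(ref), ncol(ref), nrow(alt), ncol(alt))
  }
  barcodes <- as.character(barcodes)
  if (length(barcodes) != nrow(ref)) {
    .stopf("barcode count (%d) does not match matrix cell count (%d)",
           length(barcodes), nrow(ref))
  }
  if (anyDuplicated(barcodes)) .stopf("cell barcodes are not unique")
  variants <- .validate_variants(variants)
  if (nrow(variants) != ncol(ref)) {
    .stopf("variant count (%d) does not match matrix variant count (%d)",
           nrow(variants), ncol(ref))
  }
  structure(list(ref = ref, alt = alt, barcodes = barcodes, variants = variants),
            class = "allele_counts")
}

.as_count_matrix <- function(m, what) {
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  m <- Matrix::drop0(m)
  if (length(m@x)) {
    if (any(m@x < 0)) .stopf("%s counts contain negative values", what)
    if (any(m@x != round(m@x))) .stopf("%s counts contain non-integer values", what)
  }
  m
}

.validate_variants <- function(variants) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref_allele", "alt_allele")
  if (!all(need %in% names(variants))) {
    .stopf("variants must have columns %s", paste(need, collapse = ", "))
  }
  variants$pos <- as.integer(variants$pos)
  if (any(variants$pos < 1L)) .stopf("variant positions must be >= 1 (1-based)")
  multi <- grepl(",", variants$alt_allele, fixed = TRUE)
  if (any(multi)) {
    .stopf("multiallelic records are not supported (first at %s:%d); split upstream",
           variants$chrom[which(multi)[1]], variants$pos[which(multi)[1]])
  }
  same <- variants$ref_allele == variants$alt_allele
  if (any(same)) {
    .stopf("ref and alt allele identical at %s:%d",
           variants$chrom[which(same)[1]], variants$pos[which(same)[1]])
  }
  variants[, need]
}

#' @rdname allele_counts
#' @param x an `allele_counts` object.
#' @export
n_cells <- function(x) length(x$barcodes)

#' @rdname allele_counts
#' @export
n_variants <- function(x) nrow(x$variants)

#' @param ... ignored.
#' @rdname allele_counts
#' @method print allele_counts
#' @export
print.allele_counts <- function(x, ...) {
  tot <- x$ref + x$alt
  nz <- length(Matrix::drop0(tot)@x)
  cat(sprintf("allele_counts: %d cells x %d variants\n", n_cells(x), n_variants(x)))
  cat(sprintf("  covered entries: %d (%.2f%% density)\n",
              nz, 100 * nz / (n_cells(x) * n_variants(x))))
  invisible(x)
}

# Preprocessed view of an allele_counts object used by the hot paths:
# coverage triplets with per-entry alt/ref/binomial coefficients, per-cell
# coverage and lchoose sums, per-variant totals.
.ac_prep <- function(x) {
  n <- n_cells(x); v <- n_variants(x)
  tot <- Matrix::drop0(x$ref + x$alt)
  st <- Matrix::summary(tot)
  sa <- Matrix::summary(Matrix::drop0(x$alt))
  key_t <- (as.numeric(st$j) - 1) * n + st$i
  key_a <- (as.numeric(sa$j) - 1) * n + sa$i
  altv <- numeric(nrow(st))
  altv[match(key_a, key_t)] <- sa$x
  refv <- st$x - altv
  lch_trip <- lchoose(st$x, altv)
  list(
    A = x$alt, R = x$ref, Tot = tot, n = n, v = v,
    trip = data.frame(i = st$i, v = st$j, tot = st$x,
                      alt = altv, ref = refv, lch = lch_trip),
    lch = .rowsum_to(lch_trip, st$i, n),
    ncov = tabulate(st$i, n),
    col_alt = Matrix::colSums(x$alt),
    col_tot = Matrix::colSums(tot)
  )
}
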