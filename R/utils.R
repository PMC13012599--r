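# Internal numerical helpers shared across modules.

# Clamp allele fractions into [floor, 1 - floor]; log pmfs must stay finite.
.clamp <- function(x, floor) pmin(pmax(x, floor), 1 - floor)

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG stream.
.local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Row-wise log-sum-exp of a finite matrix.
.row_lse <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  m + log(rowSums(exp(x - m)))
}

# rowsum() onto a fixed-length vector, groups may be missing.
.rowsum_to <- function(values, groups, n) {
  out <- numeric(n)
  agg <- rowsum(values, group = groups)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
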