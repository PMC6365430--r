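## Small shared helpers.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; tabulated summary statistics here use
#' commercial rounding (0.005 -> 0.01) so that printed means match what a
#' spreadsheet would report.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Weighted median
#'
#' Lower weighted median: the smallest value whose cumulative weight reaches
#' half of the total weight. Used as the chromosomal depth baseline, where
#' weights are contig lengths, so that a handful of short high-copy contigs
#' cannot shift the baseline.
#'
#' @param x numeric values.
#' @param w non-negative weights, same length as `x`.
#' @return scalar weighted median.
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  if (length(x) == 0L || sum(w) == 0) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

## Evaluate an expression under a temporary RNG state; the caller's
## .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## All permutations of seq_len(n); n is guarded by the caller.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

## Atomic write: run writer(fn) on a temp path in the same directory,
## then rename over the target.
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not write ", path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write_atomic(path, function(tmp)
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
}
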