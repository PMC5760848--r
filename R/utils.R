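# Internal helpers shared across modules.
#
# Coordinate convention: every interval inside the package is 0-based,
# half-open [start, end) in base pairs.  Conversion to the 1-based closed
# conventions of VCF/GFF3 and of GenomicRanges happens only at the I/O
# boundary (see `gr_from_intervals()` and the readers/writers in io.R).

# Evaluate `code` under a fixed RNG state, restoring the caller's state
# afterwards so generators are pure functions of their arguments.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
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

# Derive a child seed from a base seed and a stream index, kept < 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + 104729 * as.double(stream)) %% 2147483647
}

#' Convert internal 0-based half-open intervals to a GRanges
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open.
#' @param ... further metadata columns.
#' @return a [GenomicRanges::GRanges] (1-based closed coordinates).
#' @keywords internal
#' @noRd
gr_from_intervals <- function(chrom, start, end, ...) {
  if (any(start < 0)) stop("negative coordinates are not allowed")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end), ...)
}

# Points (0-based positions) as width-1 GRanges.
gr_from_points <- function(chrom, pos) {
  gr_from_intervals(chrom, pos, pos + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimum gap in bp between two half-open intervals; 0 if they overlap.
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

check_interval_df <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$start < 0)) stop(what, ": negative coordinates")
  if (any(df$end <= df$start)) stop(what, ": end must be > start")
  invisible(df)
}

# Median that tolerates but never receives NA in internal callers.
median_ <- function(x) stats::median(x, na.rm = TRUE)
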