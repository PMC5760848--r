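#' Squared Pearson correlation between two dosage vectors
#'
#' Pairwise-complete observations only; both vectors must be
#' non-constant on the retained samples and leave >= 3 pairs.
#'
#' @param a,b dosage vectors.
#' @return R-squared in `[0, 1]`.
#' @export
compute_ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("undefined LD: fewer than 3 complete pairs")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("undefined LD: constant dosage vector")
  stats::cor(a, b)^2
}

#' Extend a variant interval to its furthest linked SNVs
#'
#' The first stage of the twofold span extension: the interval grows to
#' cover every SNV (within `search_window` bp of the original interval,
#' on the same chromosome) whose dosage has squared correlation strictly
#' greater than `r2_threshold` with the variant's dosage.  The result is
#' the union of the original interval with `[min pos, max pos + 1)` over
#' qualifying SNVs; with no qualifying SNV on a side that boundary is
#' unchanged.  SNVs with undefined LD (constant dosage) never qualify.
#'
#' @param chrom,start,end the variant's interval (0-based half-open).
#' @param dosage the variant's per-sample dosage vector.
#' @param snvs a `genotype_matrix` of SNVs (position = `start`).
#' @param r2_threshold strict lower bound on R-squared (default 0.5).
#' @param search_window scan limit in bp on each side (default 1 Mb).
#' @return list(`start`, `end`, `snv_ids`, `boundary_r2`): the LD
#'   interval plus the qualifying SNVs at its boundaries.
#' @export
extend_by_ld <- function(chrom, start, end, dosage, snvs,
                         r2_threshold = 0.5, search_window = 1e6) {
  cand <- which(snvs$variants$chrom == chrom &
                  snvs$variants$start >= start - search_window &
                  snvs$variants$start < end + search_window)
  qual_pos <- numeric(0); qual_id <- character(0); qual_r2 <- numeric(0)
  for (i in cand) {
    r2 <- tryCatch(compute_ld_r2(dosage, snvs$dosage[i, ]),
                   error = function(e) 0)
    if (r2 > r2_threshold) {
      qual_pos <- c(qual_pos, snvs$variants$start[i])
      qual_id <- c(qual_id, snvs$variants$variant_id[i])
      qual_r2 <- c(qual_r2, r2)
    }
  }
  if (!length(qual_pos))
    return(list(start = start, end = end, snv_ids = character(0),
                boundary_r2 = numeric(0)))
  new_start <- min(start, min(qual_pos))
  new_end <- max(end, max(qual_pos) + 1)
  at_bound <- qual_pos == min(qual_pos) | qual_pos == max(qual_pos)
  list(start = new_start, end = new_end,
       snv_ids = qual_id[at_bound], boundary_r2 = qual_r2[at_bound])
}

#' Extend an interval outward to the next recombination sites
#'
#' The second stage of the twofold extension: the start moves to the
#' greatest recombination site at or below it (chromosome start if none),
#' the end to the smallest site at or above it (chromosome end if none).
#' A boundary already on a site is unchanged.
#'
#' @param start,end LD interval (0-based half-open).
#' @param sites sorted recombination positions on the chromosome.
#' @param chrom_length chromosome length in bp (fallback end bound).
#' @return list(`start`, `end`).
#' @export
extend_to_recombination_sites <- function(start, end, sites,
                                          chrom_length) {
  below <- sites[sites <= start]
  above <- sites[sites >= end]
  list(start = if (length(below)) max(below) else 0,
       end = if (length(above)) min(above) else chrom_length)
}

#' Twofold span extension for a set of variants
#'
#' Applies [extend_by_ld()] then [extend_to_recombination_sites()] to
#' every variant, producing the final spans used for cis-window
#' assignment.  The nesting `original ⊆ ld ⊆ final` holds by
#' construction.
#'
#' @param variants an `sv_set` or `genotype_matrix`.
#' @param snvs a `genotype_matrix` of SNVs.
#' @param model a `genome_model` (recombination sites, chromosome
#'   lengths).
#' @param r2_threshold,search_window see [extend_by_ld()].
#' @return data frame of class `extended_spans`: one row per variant with
#'   original (`start`, `end`), `ld_start`, `ld_end`, `final_start`,
#'   `final_end`, `boundary_snvs`, `boundary_r2`.
#' @export
extend_spans <- function(variants, snvs, model, r2_threshold = 0.5,
                         search_window = 1e6) {
  v <- if (inherits(variants, "sv_set"))
    data.frame(variant_id = variants$events$sv_id,
               chrom = variants$events$chrom,
               start = variants$events$start, end = variants$events$end,
               stringsAsFactors = FALSE)
  else variants$variants
  dosage <- if (inherits(variants, "sv_set")) variants$dosage else
    variants$dosage

  out <- v
  out$ld_start <- out$ld_end <- out$final_start <-
    out$final_end <- NA_real_
  out$boundary_snvs <- out$boundary_r2 <- ""
  for (i in seq_len(nrow(v))) {
    ld <- extend_by_ld(v$chrom[i], v$start[i], v$end[i], dosage[i, ],
                       snvs, r2_threshold, search_window)
    sites <- model$recomb$pos[model$recomb$chrom == v$chrom[i]]
    cl <- model$chromosomes$length[
      model$chromosomes$name == v$chrom[i]]
    fin <- extend_to_recombination_sites(ld$start, ld$end, sites, cl)
    out$ld_start[i] <- ld$start; out$ld_end[i] <- ld$end
    out$final_start[i] <- fin$start; out$final_end[i] <- fin$end
    out$boundary_snvs[i] <- paste(ld$snv_ids, collapse = ",")
    out$boundary_r2[i] <- paste(signif(ld$boundary_r2, 6),
                                collapse = ",")
  }
  class(out) <- c("extended_spans", "data.frame")
  out
}
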