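#' Read structural-variant calls from a VCF
#'
#' Parses a Delly-style SV VCF (4.2) via \pkg{vcfR}.  Each record must
#' carry `SVTYPE` and `END` INFO keys and a per-sample `GT`.  Genotypes
#' are encoded as alternate-allele dosages: `0/0 -> 0`, `0/1`/`1/0 -> 1`,
#' `1/1 -> 2`, `./. -> NA`; phased separators are accepted.  VCF 1-based
#' inclusive coordinates become internal 0-based half-open intervals
#' (`POS=1001, END=2000` becomes `[1000, 2000)`).
#'
#' Records with an unknown `SVTYPE` are skipped; the number skipped is
#' attached as attribute `n_skipped` with a warning.
#'
#' @param path VCF file (plain or bgzipped).
#' @param depth_ratios optional matrix or path to a TSV
#'   (sv_id x sample) of normalized read-depth ratios to attach.
#' @return an `sv_set`.
#' @export
read_sv_vcf <- function(path, depth_ratios = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  svtype <- vcfR::extract.info(v, "SVTYPE")
  end1 <- suppressWarnings(as.numeric(vcfR::extract.info(v, "END")))
  bad <- which(is.na(svtype) | is.na(end1))
  if (length(bad))
    stop("record(s) ", paste(bad, collapse = ", "),
         " lack SVTYPE/END INFO keys")
  known <- c("DEL", "DUP", "INV", "INVDEL", "INVDUP")
  keep <- svtype %in% known
  n_skipped <- sum(!keep)
  if (n_skipped)
    warning(n_skipped, " record(s) with unknown SVTYPE skipped")

  gt <- vcfR::extract.gt(v)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(gt)))
  dosage <- apply(gt, c(1, 2), gt_to_dosage)

  bpu <- vcfR::extract.info(v, "BPU")
  bpd <- vcfR::extract.info(v, "BPD")
  events <- data.frame(
    sv_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                   sprintf("sv%d", seq_len(nrow(fix))), fix[, "ID"]),
    chrom = fix[, "CHROM"],
    start = as.numeric(fix[, "POS"]) - 1,
    end = end1,
    sv_type = svtype,
    af = NA_real_,
    bp_up = if (all(is.na(bpu))) TRUE else bpu %in% c("1", "TRUE"),
    bp_down = if (all(is.na(bpd))) TRUE else bpd %in% c("1", "TRUE"),
    stringsAsFactors = FALSE)

  events <- events[keep, , drop = FALSE]
  dosage <- dosage[keep, , drop = FALSE]
  rownames(events) <- NULL

  dr <- NULL
  if (!is.null(depth_ratios)) {
    if (is.character(depth_ratios))
      depth_ratios <- as.matrix(utils::read.table(depth_ratios,
                                                  header = TRUE, sep = "\t",
                                                  row.names = 1,
                                                  check.names = FALSE))
    dr <- depth_ratios[events$sv_id, colnames(dosage), drop = FALSE]
  }
  out <- new_sv_set(events, dosage, dr)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a plain (SNV) VCF into a genotype matrix
#'
#' Point variants only: each record becomes a width-1 interval
#' `[POS-1, POS)` with GT-derived dosages as in [read_sv_vcf()].
#'
#' @param path VCF file.
#' @return a `genotype_matrix`.
#' @export
read_snv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(gt)))
  dosage <- apply(gt, c(1, 2), gt_to_dosage)
  variants <- data.frame(
    variant_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                        sprintf("snv%d", seq_len(nrow(fix))),
                        fix[, "ID"]),
    chrom = fix[, "CHROM"],
    start = as.numeric(fix[, "POS"]) - 1,
    end = as.numeric(fix[, "POS"]),
    stringsAsFactors = FALSE)
  new_genotype_matrix(variants, dosage)
}

gt_to_dosage <- function(gt) {
  if (is.na(gt)) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  sum(as.integer(alleles) > 0)
}

#' Write an sv_set (or genotype_matrix) as VCF 4.2
#'
#' SV records carry `SVTYPE` and `END` (1-based inclusive) INFO keys plus
#' `BPU`/`BPD` breakpoint-support flags; plain variants are written as
#' point substitutions.  Dosages map back to unphased GT strings.
#'
#' @param x an `sv_set` or `genotype_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(x, path) {
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
              "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
              "##INFO=<ID=BPU,Number=1,Type=Integer,Description=\"Upstream breakpoint support\">",
              "##INFO=<ID=BPD,Number=1,Type=Integer,Description=\"Downstream breakpoint support\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (inherits(x, "sv_set")) {
    ev <- x$events; dosage <- x$dosage
    info <- sprintf("SVTYPE=%s;END=%d;BPU=%d;BPD=%d", ev$sv_type,
                    as.integer(ev$end), as.integer(ev$bp_up),
                    as.integer(ev$bp_down))
    ids <- ev$sv_id; alt <- paste0("<", sub("INV(DEL|DUP)", "INV", ev$sv_type), ">")
  } else {
    ev <- x$variants; dosage <- x$dosage
    info <- rep(".", nrow(ev))
    ids <- ev$variant_id; alt <- rep("C", nrow(ev))
  }
  gt_str <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L],
                   nrow = nrow(dosage))
  gt_str[is.na(gt_str)] <- "./."
  body <- cbind(ev$chrom, format(ev$start + 1, scientific = FALSE,
                                 trim = TRUE),
                ids, "N", alt, ".", "PASS", info, "GT", gt_str)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", colnames(dosage)),
                   collapse = "\t"), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read-depth-ratio inclusion filter for deletions and duplications
#'
#' A DEL (or INVDEL) is kept when the median normalized read-depth ratio
#' over its heterozygous carriers is strictly below `del_max`; a DUP (or
#' INVDUP) when it is strictly above `dup_min`.  Ratios are assumed
#' pre-normalized to the non-carrier median.  Inversions pass unchanged.
#' DEL/DUP events with no heterozygous carrier are rejected with reason
#' `"no_het_carriers"`.  Boundary equality rejects.
#'
#' @param sv an `sv_set` with `depth_ratio`.
#' @param del_max,dup_min thresholds (defaults 0.8 and 1.3).
#' @return list(`kept`, `rejected`: `sv_set`s; `report`: data frame with
#'   sv_id, sv_type, median_het_ratio, decision, reason).
#' @export
filter_by_depth_ratio <- function(sv, del_max = 0.8, dup_min = 1.3) {
  stopifnot(inherits(sv, "sv_set"))
  ev <- sv$events
  n <- nrow(ev)
  keep <- logical(n); med <- rep(NA_real_, n); reason <- character(n)
  del_like <- ev$sv_type %in% c("DEL", "INVDEL")
  dup_like <- ev$sv_type %in% c("DUP", "INVDUP")
  for (i in seq_len(n)) {
    if (!del_like[i] && !dup_like[i]) {
      keep[i] <- TRUE; reason[i] <- "not_applicable"; next
    }
    if (is.null(sv$depth_ratio))
      stop("depth ratios required for DEL/DUP filtering")
    het <- which(!is.na(sv$dosage[i, ]) & sv$dosage[i, ] == 1L &
                   !is.na(sv$depth_ratio[i, ]))
    if (!length(het)) {
      keep[i] <- FALSE; reason[i] <- "no_het_carriers"; next
    }
    med[i] <- median_(sv$depth_ratio[i, het])
    if (del_like[i]) {
      keep[i] <- med[i] < del_max
      reason[i] <- if (keep[i]) "median_below_threshold" else
        "median_not_below_threshold"
    } else {
      keep[i] <- med[i] > dup_min
      reason[i] <- if (keep[i]) "median_above_threshold" else
        "median_not_above_threshold"
    }
  }
  report <- data.frame(sv_id = ev$sv_id, sv_type = ev$sv_type,
                       median_het_ratio = med,
                       decision = ifelse(keep, "kept", "rejected"),
                       reason = reason, stringsAsFactors = FALSE)
  list(kept = subset_sv_set(sv, keep),
       rejected = subset_sv_set(sv, !keep),
       report = report)
}

#' Breakpoint-support filter for inversions
#'
#' Inversions are kept only when both breakpoints have inversion-
#' supporting paired ends; all non-inversion events pass unchanged.
#'
#' @param sv an `sv_set`.
#' @return list(`kept`, `rejected`) of `sv_set`s.
#' @export
filter_inversions <- function(sv) {
  stopifnot(inherits(sv, "sv_set"))
  inv <- sv$events$sv_type == "INV"
  keep <- !inv | (sv$events$bp_up & sv$events$bp_down)
  list(kept = subset_sv_set(sv, keep),
       rejected = subset_sv_set(sv, !keep))
}

subset_sv_set <- function(sv, idx) {
  ev <- sv$events[idx, , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(events = ev,
                 dosage = sv$dosage[idx, , drop = FALSE],
                 depth_ratio = if (is.null(sv$depth_ratio)) NULL else
                   sv$depth_ratio[idx, , drop = FALSE]),
            class = "sv_set")
}

#' Allele frequency and population class of an SV
#'
#' Allele frequency is the dosage sum over twice the number of samples
#' with a non-missing genotype.  The class follows carrier (individual)
#' frequency: `private` = exactly one carrier; `common` = carriers in at
#' least `common_cutoff` of genotyped samples; `rare` otherwise.
#'
#' @param dosages per-sample dosage vector (0/1/2/NA), or an `sv_set`
#'   (then one row per SV is returned).
#' @param common_cutoff carrier-frequency threshold for "common".
#' @return data frame with `allele_freq`, `carrier_freq`, `n_carriers`,
#'   `class`.
#' @export
allele_frequency <- function(dosages, common_cutoff = 0.05) {
  if (inherits(dosages, "sv_set")) {
    res <- do.call(rbind, lapply(seq_len(nrow(dosages$events)), function(i)
      allele_frequency(dosages$dosage[i, ], common_cutoff)))
    return(cbind(sv_id = dosages$events$sv_id, res))
  }
  ok <- !is.na(dosages)
  if (!any(ok)) stop("undefined frequency: all dosages missing")
  n <- sum(ok)
  af <- sum(dosages[ok]) / (2 * n)
  carriers <- sum(dosages[ok] >= 1)
  cf <- carriers / n
  cls <- if (carriers == 1L) "private" else
    if (cf >= common_cutoff) "common" else "rare"
  data.frame(allele_freq = af, carrier_freq = cf, n_carriers = carriers,
             class = cls, stringsAsFactors = FALSE)
}
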