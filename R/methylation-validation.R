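#' Methylation probes inside an SV
#'
#' Returns the probes whose position falls within the ORIGINAL SV
#' interval (half-open, so a probe at the interval end is excluded):
#' array intensity reflects local copy number, not LD, so the extended
#' span is never used here.
#'
#' @param chrom,start,end the SV interval.
#' @param probes probe data frame (`probe_id`, `chrom`, `pos`).
#' @return the matching rows of `probes`.
#' @export
probes_in_sv <- function(chrom, start, end, probes) {
  probes[probes$chrom == chrom & probes$pos >= start &
           probes$pos < end, , drop = FALSE]
}

#' One-sided directional test of probe intensity on SV dosage
#'
#' OLS of total (methylated + unmethylated) intensity on dosage with
#' tissue indicator covariates.  The one-sided p-value is the t-tail in
#' the tested direction: when the fitted slope's sign matches the
#' direction the p is half the two-sided value, otherwise
#' `1 - two_sided / 2`.
#'
#' @param dosage per-sample dosage vector.
#' @param total_intensity per-sample total intensity.
#' @param tissue per-sample tissue labels (a single level drops the
#'   covariate).
#' @param direction `"decrease"` (deletions) or `"increase"`
#'   (duplications).
#' @return one-sided p-value.
#' @export
directional_probe_test <- function(dosage, total_intensity, tissue,
                                   direction = c("decrease",
                                                 "increase")) {
  direction <- match.arg(direction)
  ok <- !is.na(dosage) & !is.na(total_intensity)
  if (sum(ok) < 4) stop("untestable: fewer than 4 complete samples")
  tissue <- as.factor(tissue[ok])
  covars <- if (nlevels(tissue) > 1)
    stats::model.matrix(~tissue)[, -1, drop = FALSE] else NULL
  fit <- fit_additive_model(dosage[ok], total_intensity[ok], covars)
  want <- if (direction == "decrease") -1 else 1
  if (sign(fit$beta) == want) fit$p / 2 else 1 - fit$p / 2
}

#' Simes combination of per-probe p-values
#'
#' With order statistics `p_(1) <= ... <= p_(m)`, the aggregate is
#' `min_i m * p_(i) / i`, capped at 1 — valid under positive dependence
#' among the probe tests, order-invariant, and never below the minimum
#' input p.
#'
#' @param p vector of p-values in `[0, 1]`, length >= 1.
#' @return the Simes aggregate p-value.
#' @export
simes_aggregate <- function(p) {
  if (!length(p)) stop("simes_aggregate: empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] and be non-missing")
  m <- length(p)
  ps <- sort(p)
  min(1, min(m * ps / seq_len(m)))
}

#' Validate SV calls from methylation-array intensities
#'
#' For each deletion the per-probe tests ask for reduced total intensity
#' in carriers, for each duplication for increased intensity; inversions
#' and complex events are copy-ambiguous for this assay and are marked
#' untestable, as are SVs covering no probe or with a monomorphic
#' dosage.  Per-probe one-sided p-values are combined with the Simes
#' procedure; an SV is validated when the aggregate p is at most
#' `alpha`.
#'
#' @param sv an `sv_set`.
#' @param methyl a `methyl_set` (see
#'   [simulate_methylation_intensities()] or [read_methyl_tsv()]).
#' @param alpha validation significance level.
#' @return list(`results` data frame (sv_id, sv_type, direction,
#'   n_probes, simes_p, validated), `probe_p` per-probe detail,
#'   `untestable` data frame (sv_id, reason)).
#' @export
validate_svs <- function(sv, methyl, alpha = 0.05) {
  stopifnot(inherits(sv, "sv_set"))
  total <- methyl$meth + methyl$unmeth
  samples <- intersect(colnames(sv$dosage), colnames(total))
  total <- total[, samples, drop = FALSE]
  tissue <- methyl$tissue[samples]

  res <- list(); detail <- list(); untest <- list()
  dir_of <- c(DEL = "decrease", INVDEL = "decrease",
              DUP = "increase", INVDUP = "increase")
  for (i in seq_len(nrow(sv$events))) {
    ev <- sv$events[i, ]
    if (!ev$sv_type %in% names(dir_of)) {
      untest[[length(untest) + 1L]] <-
        data.frame(sv_id = ev$sv_id, reason = "copy_neutral_type")
      next
    }
    pr <- probes_in_sv(ev$chrom, ev$start, ev$end, methyl$probes)
    if (!nrow(pr)) {
      untest[[length(untest) + 1L]] <-
        data.frame(sv_id = ev$sv_id, reason = "no_probes")
      next
    }
    d <- sv$dosage[i, samples]
    pp <- vapply(pr$probe_id, function(pid)
      tryCatch(directional_probe_test(d, total[pid, ], tissue,
                                      dir_of[[ev$sv_type]]),
               error = function(e) NA_real_), numeric(1))
    if (all(is.na(pp))) {
      untest[[length(untest) + 1L]] <-
        data.frame(sv_id = ev$sv_id, reason = "monomorphic_dosage")
      next
    }
    pp <- pp[!is.na(pp)]
    sp <- simes_aggregate(pp)
    res[[length(res) + 1L]] <- data.frame(
      sv_id = ev$sv_id, sv_type = ev$sv_type,
      direction = dir_of[[ev$sv_type]], n_probes = length(pp),
      min_p = min(pp), simes_p = sp, validated = sp <= alpha,
      stringsAsFactors = FALSE)
    detail[[length(detail) + 1L]] <- data.frame(
      sv_id = ev$sv_id, probe_id = names(pp), p = unname(pp),
      stringsAsFactors = FALSE)
  }
  list(results = if (length(res)) do.call(rbind, res) else
         data.frame(sv_id = character(), sv_type = character(),
                    direction = character(), n_probes = integer(),
                    min_p = numeric(), simes_p = numeric(),
                    validated = logical()),
       probe_p = if (length(detail)) do.call(rbind, detail) else NULL,
       untestable = if (length(untest)) do.call(rbind, untest) else
         data.frame(sv_id = character(), reason = character()))
}
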