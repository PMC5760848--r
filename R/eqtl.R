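#' Remove genes with very low expression
#'
#' A gene is dropped when its mean raw count over samples is <= `min_mean`
#' or it is detected (count > 0) in fewer than `min_detect_frac` of the
#' samples.
#'
#' @param expr an `expression_matrix` with raw counts.
#' @param min_mean mean-count threshold (gene removed when mean <= this).
#' @param min_detect_frac minimum fraction of samples with a non-zero
#'   count.
#' @return a filtered `expression_matrix`.
#' @export
filter_low_expression <- function(expr, min_mean = 1,
                                  min_detect_frac = 0.5) {
  stopifnot(inherits(expr, "expression_matrix"))
  m <- rowMeans(expr$counts)
  det <- rowMeans(expr$counts > 0)
  keep <- m > min_mean & det >= min_detect_frac
  new_expression_matrix(expr$genes[keep, , drop = FALSE],
                        expr$counts[keep, , drop = FALSE])
}

# Median-of-ratios size factors over genes with all-positive counts.
size_factors_median_ratio <- function(counts) {
  zero_samples <- colnames(counts)[colSums(counts) == 0]
  if (length(zero_samples))
    stop("cannot compute size factors: all-zero counts for sample(s) ",
         paste(zero_samples, collapse = ", "))
  allpos <- rowSums(counts <= 0) == 0
  if (!any(allpos))
    stop("cannot compute size factors: no gene with all-positive counts")
  logref <- rowMeans(log(counts[allpos, , drop = FALSE]))
  apply(counts[allpos, , drop = FALSE], 2,
        function(cnt) exp(median_(log(cnt) - logref)))
}

#' Normalize expression counts to a log2 scale
#'
#' Computes per-sample size factors by the median-of-ratios method over
#' genes with all-positive counts, then transforms each count to
#' `log2(count / size_factor + 1)`.  This is a variance-stabilizing,
#' monotone substitute for a regularized-log transform; the choice is
#' recorded in the `normalization` field.
#'
#' @param expr an `expression_matrix` with (filtered) raw counts.
#' @return the `expression_matrix` with `values`, `size_factors` and
#'   `normalization` filled in.
#' @export
normalize_expression <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  sf <- size_factors_median_ratio(expr$counts)
  values <- log2(sweep(expr$counts, 2, sf, `/`) + 1)
  new_expression_matrix(expr$genes, expr$counts, values = values,
                        size_factors = sf,
                        normalization =
                          "median-of-ratios size factors, log2(x+1)")
}

#' Enumerate cis variant-gene pairs from extended spans
#'
#' A pair is emitted when the minimum gap between the variant's final
#' extended span and the gene interval is at most `window` bp (0 when
#' they overlap).  The overlap class records how contact is made:
#' `direct_overlap` when the original variant interval overlaps the
#' gene, `ld_overlap` when only the LD-extended interval does, and
#' `within_1Mb` otherwise.  Pairs whose variant (original interval) or
#' gene overlaps `hla_region` are dropped.
#'
#' @param spans an [extend_spans()] result.
#' @param genes gene index data frame (`gene_id`, `chrom`, `start`,
#'   `end`), e.g. `expression_matrix$genes`.
#' @param window cis window in bp (default 1 Mb).
#' @param hla_region optional `list(chrom =, start =, end =)` to exclude.
#' @return data frame (`variant_id`, `gene_id`, `distance`,
#'   `overlap_class`).
#' @export
cis_pairs <- function(spans, genes, window = 1e6, hla_region = NULL) {
  out <- list()
  in_hla <- function(chrom, s, e) {
    !is.null(hla_region) && chrom == hla_region$chrom &&
      s < hla_region$end && e > hla_region$start
  }
  gene_hla <- if (is.null(hla_region)) rep(FALSE, nrow(genes)) else
    genes$chrom == hla_region$chrom & genes$start < hla_region$end &
    genes$end > hla_region$start
  for (i in seq_len(nrow(spans))) {
    if (in_hla(spans$chrom[i], spans$start[i], spans$end[i])) next
    on_chrom <- which(genes$chrom == spans$chrom[i] & !gene_hla)
    if (!length(on_chrom)) next
    gs <- genes$start[on_chrom]; ge <- genes$end[on_chrom]
    gap_final <- interval_gap(spans$final_start[i], spans$final_end[i],
                              gs, ge)
    sel <- gap_final <= window
    if (!any(sel)) next
    gap_orig <- interval_gap(spans$start[i], spans$end[i], gs, ge)
    gap_ld <- interval_gap(spans$ld_start[i], spans$ld_end[i], gs, ge)
    cls <- ifelse(gap_orig == 0, "direct_overlap",
                  ifelse(gap_ld == 0, "ld_overlap", "within_1Mb"))
    out[[length(out) + 1L]] <- data.frame(
      variant_id = spans$variant_id[i],
      gene_id = genes$gene_id[on_chrom][sel],
      distance = gap_final[sel], overlap_class = cls[sel],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(variant_id = character(), gene_id = character(),
                      distance = numeric(), overlap_class = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Additive linear dosage model for one variant-gene pair
#'
#' Ordinary least squares of expression on genotype dosage, with an
#' intercept and optional covariates.  Samples with missing dosage are
#' dropped casewise.  The two-sided p-value uses the t distribution with
#' the residual degrees of freedom.
#'
#' @param dosage numeric vector (0/1/2, NA allowed).
#' @param expression numeric vector, same length.
#' @param covariates optional numeric matrix (samples x covariates).
#' @return list(`beta`, `se`, `t`, `p`, `n`).
#' @export
fit_additive_model <- function(dosage, expression, covariates = NULL) {
  ok <- !is.na(dosage) & !is.na(expression)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  d <- dosage[ok]; y <- expression[ok]
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (length(d) < 3 + k)
    stop("too few complete observations: need >= ", 3 + k)
  if (stats::var(d) == 0)
    stop("monomorphic variant: constant dosage")
  X <- cbind(`(Intercept)` = 1, dosage = d,
             if (!is.null(covariates)) covariates[ok, , drop = FALSE])
  fit <- stats::lm.fit(X, y)
  df <- length(y) - fit$rank
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  piv <- fit$qr$pivot
  cov_unscaled <- matrix(NA_real_, ncol(X), ncol(X))
  cov_unscaled[piv, piv] <- chol2inv(qr.R(fit$qr))
  se <- sqrt(sigma2 * cov_unscaled[2, 2])
  beta <- unname(fit$coefficients["dosage"])
  tval <- beta / se
  list(beta = beta, se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df), n = length(y))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values (adjusted p-values), same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] and be non-missing")
  stats::p.adjust(p, method = "BH")
}

#' Run the cis-eQTL association scan
#'
#' Fits the additive model for every testable pair, attaches BH q-values
#' computed over all tested pairs in the run, and flags the significant
#' set at `fdr_alpha`.  Pairs with a monomorphic dosage or fewer than 3
#' complete observations are skipped and reported in the `skipped`
#' attribute.  Without covariates the scan uses a vectorized closed-form
#' simple-regression path (missing dosages handled casewise per pair).
#'
#' @param genotypes a `genotype_matrix` or `sv_set`.
#' @param expression a normalized `expression_matrix` (see
#'   [normalize_expression()]); raw-count matrices are normalized on the
#'   fly.
#' @param pairs data frame from [cis_pairs()] (`variant_id`, `gene_id`,
#'   optional `distance`, `overlap_class`); `NULL` tests all
#'   variant x gene combinations (distance set to `NA`).
#' @param covariates optional samples x covariates matrix.
#' @param fdr_alpha FDR level for the `significant` flag.
#' @param cis_window window used for the `cis` flag (on `distance`).
#' @return data frame of class `eqtl_result`, one row per tested pair:
#'   variant_id, gene_id, beta, se, t, p, q, n, distance, cis,
#'   overlap_class, significant.
#' @export
run_eqtl <- function(genotypes, expression, pairs = NULL,
                     covariates = NULL, fdr_alpha = 0.05,
                     cis_window = 1e6) {
  if (inherits(genotypes, "sv_set"))
    genotypes <- as_genotype_matrix(genotypes)
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(expression, "expression_matrix"))
  if (is.null(expression$values))
    expression <- normalize_expression(expression)
  vals <- expression$values
  samples <- intersect(colnames(genotypes$dosage), colnames(vals))
  if (length(samples) < 3) stop("fewer than 3 shared samples")
  D <- genotypes$dosage[, samples, drop = FALSE]
  E <- vals[, samples, drop = FALSE]

  if (is.null(pairs)) {
    pairs <- expand.grid(variant_id = genotypes$variants$variant_id,
                         gene_id = expression$genes$gene_id,
                         stringsAsFactors = FALSE)
    pairs$distance <- NA_real_
    pairs$overlap_class <- NA_character_
  }
  if (is.null(pairs$distance)) pairs$distance <- NA_real_
  if (is.null(pairs$overlap_class)) pairs$overlap_class <- NA_character_
  vi <- match(pairs$variant_id, rownames(D))
  gi <- match(pairs$gene_id, rownames(E))
  if (any(is.na(vi)) || any(is.na(gi)))
    stop("pairs reference unknown variant or gene ids")
  if (!nrow(pairs)) {
    warning("zero testable pairs")
    return(empty_eqtl_result())
  }

  if (is.null(covariates)) {
    res <- ols_scan(D, E, vi, gi)
  } else {
    res <- data.frame(beta = NA_real_, se = NA_real_, t = NA_real_,
                      p = NA_real_, n = NA_integer_)[rep(1, nrow(pairs)), ]
    for (r in seq_len(nrow(pairs))) {
      f <- tryCatch(fit_additive_model(D[vi[r], ], E[gi[r], ],
                                       covariates),
                    error = function(e) NULL)
      if (!is.null(f)) res[r, ] <- f[c("beta", "se", "t", "p", "n")]
    }
  }

  tested <- !is.na(res$p)
  skipped <- pairs[!tested, c("variant_id", "gene_id"), drop = FALSE]
  if (!any(tested)) {
    warning("zero testable pairs")
    out <- empty_eqtl_result()
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- data.frame(pairs[tested, c("variant_id", "gene_id")],
                    res[tested, c("beta", "se", "t", "p")],
                    q = bh_fdr(res$p[tested]),
                    n = res$n[tested],
                    distance = pairs$distance[tested],
                    cis = !is.na(pairs$distance[tested]) &
                      pairs$distance[tested] <= cis_window,
                    overlap_class = pairs$overlap_class[tested],
                    stringsAsFactors = FALSE)
  out$significant <- out$q <= fdr_alpha
  rownames(out) <- NULL
  class(out) <- c("eqtl_result", "data.frame")
  attr(out, "skipped") <- skipped
  attr(out, "fdr_alpha") <- fdr_alpha
  out
}

empty_eqtl_result <- function() {
  out <- data.frame(variant_id = character(), gene_id = character(),
                    beta = numeric(), se = numeric(), t = numeric(),
                    p = numeric(), q = numeric(), n = integer(),
                    distance = numeric(), cis = logical(),
                    overlap_class = character(), significant = logical())
  class(out) <- c("eqtl_result", "data.frame")
  out
}

# Vectorized per-pair simple OLS with casewise-missing dosages.
# Returns beta/se/t/p/n with NA rows for untestable pairs.
ols_scan <- function(D, E, vi, gi, chunk = 100000L) {
  npair <- length(vi)
  beta <- se <- tval <- pval <- rep(NA_real_, npair)
  nn <- rep(NA_integer_, npair)
  for (lo in seq(1L, npair, by = chunk)) {
    hi <- min(npair, lo + chunk - 1L)
    idx <- lo:hi
    X <- D[vi[idx], , drop = FALSE]
    Y <- E[gi[idx], , drop = FALSE]
    M <- !is.na(X)
    X0 <- ifelse(M, X, 0)
    YM <- Y * M
    n <- rowSums(M)
    Sx <- rowSums(X0); Sy <- rowSums(YM)
    Sxx <- rowSums(X0^2); Syy <- rowSums(YM^2)
    Sxy <- rowSums(X0 * YM)
    ssx <- Sxx - Sx^2 / n
    ssy <- Syy - Sy^2 / n
    sxy <- Sxy - Sx * Sy / n
    ok <- n >= 3 & ssx > 0
    b <- ifelse(ok, sxy / ssx, NA_real_)
    rss <- pmax(0, ssy - b^2 * ssx)
    df <- n - 2
    s <- sqrt(rss / df / ssx)
    tv <- b / s
    tv[ok & s == 0] <- sign(b[ok & s == 0]) * Inf
    beta[idx] <- b
    se[idx] <- ifelse(ok, s, NA_real_)
    tval[idx] <- ifelse(ok, tv, NA_real_)
    pval[idx] <- ifelse(ok, 2 * stats::pt(-abs(tv), df), NA_real_)
    nn[idx] <- ifelse(ok, n, NA_integer_)
  }
  data.frame(beta = beta, se = se, t = tval, p = pval, n = nn)
}

#' Compare SV-driven and SNV-driven eQTL signals
#'
#' Reports (i) the fraction of significant SV-eQTL links whose gene has
#' no significant SNV-eQTL (i.e. the SV association cannot be explained
#' by a nearby tagging SNV), and (ii) per-gene median betas of the
#' significant associations in each run, paired across runs for sign
#' agreement and Spearman rank correlation.
#'
#' @param sv_records,snv_records `eqtl_result` data frames from
#'   [run_eqtl()] over the same expression matrix.
#' @param alpha significance level on the q-values (defaults to the FDR
#'   level stored in the records).
#' @return list(`sv_only_fraction`, `n_sv_eqtls`, `per_gene` data frame
#'   with `gene_id`, `sv_median_beta`, `snv_median_beta`,
#'   `sign_agreement`, `spearman_rho`).
#' @export
compare_sv_snv <- function(sv_records, snv_records, alpha = NULL) {
  alpha <- alpha %||% attr(sv_records, "fdr_alpha") %||% 0.05
  sig_sv <- sv_records[sv_records$q <= alpha, , drop = FALSE]
  sig_snv <- snv_records[snv_records$q <= alpha, , drop = FALSE]
  supported <- sig_sv$gene_id %in% sig_snv$gene_id
  sv_only <- if (nrow(sig_sv)) mean(!supported) else NA_real_

  med_by_gene <- function(rec) {
    if (!nrow(rec)) return(stats::setNames(numeric(0), character(0)))
    vapply(split(rec$beta, rec$gene_id), median_, numeric(1))
  }
  msv <- med_by_gene(sig_sv); msnv <- med_by_gene(sig_snv)
  shared <- intersect(names(msv), names(msnv))
  per_gene <- data.frame(gene_id = shared,
                         sv_median_beta = unname(msv[shared]),
                         snv_median_beta = unname(msnv[shared]),
                         stringsAsFactors = FALSE)
  sign_agree <- if (length(shared))
    mean(sign(per_gene$sv_median_beta) ==
           sign(per_gene$snv_median_beta)) else NA_real_
  rho <- if (length(shared) >= 3)
    suppressWarnings(stats::cor(per_gene$sv_median_beta,
                                per_gene$snv_median_beta,
                                method = "spearman")) else NA_real_
  list(sv_only_fraction = sv_only, n_sv_eqtls = nrow(sig_sv),
       n_snv_eqtls = nrow(sig_snv), per_gene = per_gene,
       sign_agreement = sign_agree, spearman_rho = rho)
}
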