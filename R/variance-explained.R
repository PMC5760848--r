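#' Total and residual variance of expression under a dosage model
#'
#' Fits the simple additive model and returns the variance of the
#' expression vector and of its OLS residuals, both with the `n - 1`
#' denominator.
#'
#' @param dosage,expression numeric vectors (missing dosages dropped
#'   casewise).
#' @return list(`total`, `residual`).
#' @export
residual_variance <- function(dosage, expression) {
  ok <- !is.na(dosage) & !is.na(expression)
  d <- dosage[ok]; y <- expression[ok]
  if (length(y) < 3) stop("too few complete observations")
  if (stats::var(d) == 0) stop("monomorphic variant: constant dosage")
  beta <- stats::cov(d, y) / stats::var(d)
  resid <- y - mean(y) - beta * (d - mean(d))
  list(total = stats::var(y), residual = sum(resid^2) / (length(y) - 1))
}

#' Set-level coefficient of determination
#'
#' Aggregates per-gene (total, residual) variance pairs into
#' `R2 = 1 - sum(residual) / sum(total)`; each gene contributes exactly
#' one pair.
#'
#' @param pairs data frame (or list) with numeric `total` and `residual`.
#' @return the set R-squared in `[0, 1]`.
#' @export
set_r2 <- function(pairs) {
  total <- pairs$total; residual <- pairs$residual
  stopifnot(length(total) >= 1, length(total) == length(residual))
  if (any(residual < 0) || any(residual > total + 1e-12))
    stop("invalid pair: need 0 <= residual <= total per gene")
  st <- sum(total)
  if (st == 0) stop("undefined set R2: total variance is zero")
  1 - sum(residual) / st
}

#' Global variance of expression explained by SV associations
#'
#' Each gene linked to at least one SV at nominal `p <= p_cut`
#' contributes the (total, residual) variance pair of its smallest-p
#' SV model; unlinked genes contribute (total, total).  The set-level
#' R-squared is reported both over the full expression universe (or the
#' supplied `gene_list`) and over linked genes only.
#'
#' @param records an `eqtl_result` from [run_eqtl()] (SV run, all tested
#'   pairs, nominal p-values).
#' @param genotypes the `genotype_matrix`/`sv_set` used in the run.
#' @param expression the normalized `expression_matrix` used in the run.
#' @param p_cut nominal p-value threshold for a link (default 0.01).
#' @param gene_list optional character vector restricting the universe
#'   (e.g. disease genes).
#' @return a `variance_report`: list(`r2_universe`, `r2_linked_only`,
#'   `n_genes`, `n_linked`, `per_gene` data frame).
#' @export
global_sv_variance <- function(records, genotypes, expression,
                               p_cut = 0.01, gene_list = NULL) {
  if (inherits(genotypes, "sv_set"))
    genotypes <- as_genotype_matrix(genotypes)
  stopifnot(inherits(expression, "expression_matrix"),
            !is.null(expression$values))
  universe <- gene_list %||% expression$genes$gene_id
  universe <- intersect(universe, rownames(expression$values))
  samples <- intersect(colnames(genotypes$dosage),
                       colnames(expression$values))
  E <- expression$values[, samples, drop = FALSE]
  D <- genotypes$dosage[, samples, drop = FALSE]

  linked <- records[records$p <= p_cut &
                      records$gene_id %in% universe, , drop = FALSE]
  best <- if (nrow(linked)) {
    o <- order(linked$gene_id, linked$p)
    lo <- linked[o, ]
    lo[!duplicated(lo$gene_id), c("gene_id", "variant_id", "p")]
  } else data.frame(gene_id = character(), variant_id = character(),
                    p = numeric())

  per_gene <- data.frame(gene_id = universe,
                         total = apply(E[universe, , drop = FALSE], 1,
                                       stats::var),
                         residual = NA_real_, variant_id = NA_character_,
                         stringsAsFactors = FALSE)
  per_gene$residual <- per_gene$total
  bi <- match(best$gene_id, per_gene$gene_id)
  for (k in seq_len(nrow(best))) {
    rv <- tryCatch(
      residual_variance(D[best$variant_id[k], ],
                        E[best$gene_id[k], ]),
      error = function(e) NULL)
    if (is.null(rv)) next
    per_gene$residual[bi[k]] <- rv$residual
    per_gene$total[bi[k]] <- rv$total
    per_gene$variant_id[bi[k]] <- best$variant_id[k]
  }
  is_linked <- !is.na(per_gene$variant_id)
  structure(list(
    r2_universe = set_r2(per_gene),
    r2_linked_only = if (any(is_linked))
      set_r2(per_gene[is_linked, , drop = FALSE]) else 0,
    n_genes = nrow(per_gene), n_linked = sum(is_linked),
    p_cut = p_cut, per_gene = per_gene),
    class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat(sprintf(paste0("variance_report: %d/%d genes SV-linked at p <= %g\n",
                     "  R2 (universe)    = %.4f\n",
                     "  R2 (linked only) = %.4f\n"),
              x$n_linked, x$n_genes, x$p_cut, x$r2_universe,
              x$r2_linked_only))
  invisible(x)
}

#' Variance explained by one SV in its locus
#'
#' Restricts the set-level R-squared to genes whose interval lies within
#' `window` bp of the SV's final extended span, using that SV's dosage
#' model for every gene in the locus.
#'
#' @param sv_id the SV to evaluate.
#' @param spans [extend_spans()] result containing the SV.
#' @param genotypes `genotype_matrix`/`sv_set` with the SV's dosages.
#' @param expression normalized `expression_matrix`.
#' @param window locus half-width in bp from the final span (default
#'   1 Mb).
#' @return list(`r2`, `n_genes`, `per_gene`).
#' @export
locus_r2 <- function(sv_id, spans, genotypes, expression,
                     window = 1e6) {
  if (inherits(genotypes, "sv_set"))
    genotypes <- as_genotype_matrix(genotypes)
  stopifnot(!is.null(expression$values))
  sp <- spans[spans$variant_id == sv_id, ]
  if (!nrow(sp)) stop("unknown sv_id: ", sv_id)
  g <- expression$genes
  gap <- interval_gap(sp$final_start, sp$final_end, g$start, g$end)
  sel <- g$chrom == sp$chrom & gap <= window
  if (!any(sel)) stop("empty locus: no expressed genes within ",
                      window, " bp of ", sv_id)
  samples <- intersect(colnames(genotypes$dosage),
                       colnames(expression$values))
  d <- genotypes$dosage[sv_id, samples]
  per_gene <- do.call(rbind, lapply(g$gene_id[sel], function(gid) {
    y <- expression$values[gid, samples]
    rv <- tryCatch(residual_variance(d, y),
                   error = function(e) list(total = stats::var(y),
                                            residual = stats::var(y)))
    data.frame(gene_id = gid, total = rv$total, residual = rv$residual,
               stringsAsFactors = FALSE)
  }))
  list(r2 = set_r2(per_gene), n_genes = nrow(per_gene),
       per_gene = per_gene)
}
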