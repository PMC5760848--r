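#' Simulate RNA-seq counts driven by SV genotypes
#'
#' Counts follow a negative-binomial (or Poisson, or noiseless) model
#' whose mean combines four factors per gene and sample:
#' `baseline * library_size * dosage_factor * 2^(beta * dosage + eps)`,
#' with `eps ~ N(0, noise$expression_sd)` the biological log2-scale noise.
#'
#' The dosage factor models physical loss or gain of exonic copies: for a
#' gene with a fraction `f` of its exons entirely inside a DEL/DUP of a
#' carrier with dosage `d`, the factor is `1 - f * (1 - c)` where
#' `c = max(0, 1 + d * (m - 1))` and `m` is the per-copy multiplier from
#' `truth$dosage_model`.  With the default `DEL = 0.5` a homozygous
#' deletion covering all exons gives `c = 0` and hence zero counts;
#' a heterozygous one halves the mean.  The eQTL factor
#' `2^(beta * dosage)` uses base 2 so the planted beta is recovered on the
#' log2-normalized scale used downstream.
#'
#' @param model a `genome_model`.
#' @param sv an `sv_set` (intervals, types and dosages drive the exon
#'   dosage factor).  Effects in `truth$effect_table` may reference SV ids
#'   or ids from `extra_genotypes`.
#' @param truth a [sim_truth()] object.
#' @param library_sizes per-sample scale factors (recycled; default 1).
#' @param baseline per-gene baseline mean counts: a scalar, a vector of
#'   length `n_genes`, or `NULL` to draw log-normal means around 100.
#' @param extra_genotypes optional `genotype_matrix` (e.g. SNVs) whose
#'   dosages may also appear in the effect table.
#' @param family one of `"nb"` (negative binomial with dispersion
#'   `truth$noise$dispersion`; 0 falls back to Poisson), `"poisson"`,
#'   `"deterministic"` (counts = round(mean); use with
#'   `expression_sd = 0` for fully noiseless cohorts).
#' @param seed integer seed.
#'
#' @return an `expression_matrix`: list(`genes` data frame, `counts`
#'   integer matrix genes x samples).
#' @export
simulate_expression <- function(model, sv, truth,
                                library_sizes = NULL,
                                baseline = NULL,
                                extra_genotypes = NULL,
                                family = c("nb", "poisson",
                                           "deterministic"),
                                seed = 1L) {
  stopifnot(inherits(model, "genome_model"), inherits(sv, "sv_set"),
            inherits(truth, "sim_truth"))
  family <- match.arg(family)
  genes <- model$genes
  samples <- colnames(sv$dosage)
  n_g <- nrow(genes); n_s <- length(samples)
  bad <- setdiff(truth$effect_table$gene_id, genes$gene_id)
  if (length(bad))
    stop("effect_table references unknown genes: ",
         paste(bad, collapse = ", "))

  dosage_lookup <- function(id) {
    if (id %in% rownames(sv$dosage)) return(sv$dosage[id, ])
    if (!is.null(extra_genotypes) &&
        id %in% rownames(extra_genotypes$dosage))
      return(extra_genotypes$dosage[id, ])
    stop("effect_table references unknown variant: ", id)
  }

  with_seed(seed, {
    if (is.null(baseline))
      baseline <- round(stats::rlnorm(n_g, log(100), 0.7)) + 1
    baseline <- rep_len(baseline, n_g)
    libs <- rep_len(library_sizes %||% 1, n_s)

    log2_mu <- matrix(0, n_g, n_s, dimnames = list(genes$gene_id, samples))
    for (k in seq_len(nrow(truth$effect_table))) {
      ef <- truth$effect_table[k, ]
      d <- dosage_lookup(ef$variant_id)
      d[is.na(d)] <- 0
      gi <- match(ef$gene_id, genes$gene_id)
      log2_mu[gi, ] <- log2_mu[gi, ] + ef$beta * d
    }

    dos_factor <- exon_dosage_factor(model, sv, truth$dosage_model)

    sd_e <- truth$noise$expression_sd
    eps <- if (sd_e > 0)
      matrix(stats::rnorm(n_g * n_s, 0, sd_e), n_g, n_s) else 0
    mu <- baseline * dos_factor * 2^(log2_mu + eps)
    mu <- sweep(mu, 2, libs, `*`)

    counts <- switch(family,
      nb = {
        disp <- truth$noise$dispersion
        if (disp > 0)
          matrix(stats::rnbinom(n_g * n_s, mu = mu, size = 1 / disp),
                 n_g, n_s)
        else matrix(stats::rpois(n_g * n_s, mu), n_g, n_s)
      },
      poisson = matrix(stats::rpois(n_g * n_s, mu), n_g, n_s),
      deterministic = round(mu))
    dimnames(counts) <- list(genes$gene_id, samples)
    new_expression_matrix(
      data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                 start = genes$start, end = genes$end,
                 stringsAsFactors = FALSE),
      counts)
  })
}

# Gene x sample multiplier from exons contained in carried DEL/DUP events.
exon_dosage_factor <- function(model, sv, dosage_model) {
  genes <- model$genes
  n_g <- nrow(genes); n_s <- ncol(sv$dosage)
  fac <- matrix(1, n_g, n_s,
                dimnames = list(genes$gene_id, colnames(sv$dosage)))
  type_mult <- c(DEL = dosage_model$DEL, INVDEL = dosage_model$DEL,
                 DUP = dosage_model$DUP, INVDUP = dosage_model$DUP)
  cnv <- sv$events$sv_type %in% names(type_mult)
  if (!any(cnv)) return(fac)
  ev <- sv$events[cnv, , drop = FALSE]
  dmat <- sv$dosage[cnv, , drop = FALSE]
  ex_gr <- gr_from_intervals(model$exons$chrom, model$exons$start,
                             model$exons$end)
  sv_gr <- gr_from_intervals(ev$chrom, ev$start, ev$end)
  hits <- GenomicRanges::findOverlaps(ex_gr, sv_gr, type = "within")
  if (!length(hits)) return(fac)
  ex_per_gene <- table(model$exons$gene_id)
  hit_df <- data.frame(
    gene_id = model$exons$gene_id[S4Vectors::queryHits(hits)],
    sv_row = S4Vectors::subjectHits(hits))
  # fraction of the gene's exons inside each SV
  agg <- stats::aggregate(rep(1, nrow(hit_df)),
                          by = hit_df[c("gene_id", "sv_row")], FUN = sum)
  for (r in seq_len(nrow(agg))) {
    gi <- match(agg$gene_id[r], genes$gene_id)
    frac <- agg$x[r] / as.numeric(ex_per_gene[[agg$gene_id[r]]])
    m <- type_mult[[ev$sv_type[agg$sv_row[r]]]]
    d <- dmat[agg$sv_row[r], ]
    d[is.na(d)] <- 0
    copyfac <- pmax(0, 1 + d * (m - 1))
    fac[gi, ] <- pmax(0, fac[gi, ] * (1 - frac * (1 - copyfac)))
  }
  fac
}

new_expression_matrix <- function(genes, counts, values = NULL,
                                  size_factors = NULL,
                                  normalization = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            nrow(genes) == nrow(counts))
  rownames(counts) <- genes$gene_id
  structure(list(genes = genes, counts = counts, values = values,
                 size_factors = size_factors,
                 normalization = normalization),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$genes), "genes x", ncol(x$counts),
      "samples",
      if (!is.null(x$values)) paste0("(normalized: ", x$normalization, ")")
      else "(raw counts)", "\n")
  invisible(x)
}
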