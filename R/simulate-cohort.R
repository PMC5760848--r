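#' Simulate a complete cohort with known ground truth
#'
#' Convenience wrapper wiring the generators together: genome model, SV
#' genotypes with read-depth ratios, tagging + background SNVs,
#' expression counts and methylation intensities.  Planted eQTL effects
#' and tagging-SNV targets are drawn here (or supplied) and recorded in
#' the returned `truth`.
#'
#' @param n_samples cohort size (the study design this emulates has ~50
#'   genomes with expression for 42).
#' @param n_genes,n_sv,n_snv model sizes.
#' @param n_eqtl number of planted SV eQTLs (random SV-gene cis pairs).
#' @param beta effect size(s) for planted eQTLs (recycled).
#' @param n_ld_tags number of SVs given a tagging SNV at `tag_r2`.
#' @param tag_r2 target LD R-squared of tagging SNVs.
#' @param noise noise list for [sim_truth()].
#' @param tissue_labels per-sample tissue labels for the methylation
#'   channel.
#' @param seed master seed; all stage seeds derive from it.
#' @param ... further arguments to [generate_genome_model()].
#' @return list(`model`, `sv`, `snvs`, `expr`, `methyl`, `truth`).
#' @export
simulate_cohort <- function(n_samples = 50L, n_genes = 100L,
                            n_sv = 60L, n_snv = 300L, n_eqtl = 10L,
                            beta = 1, n_ld_tags = 10L, tag_r2 = 0.9,
                            noise = list(expression_sd = 0.5,
                                         dispersion = 0.05,
                                         intensity_sd = 0.1,
                                         depth_sd = 0.05),
                            tissue_labels = c("heart", "blood"),
                            seed = 1L, ...) {
  model <- generate_genome_model(n_genes = n_genes,
                                 seed = child_seed(seed, 1), ...)
  sv <- simulate_sv_genotypes(model, n_sv = n_sv, n_samples = n_samples,
                              depth_noise_sd = noise$depth_sd %||% 0.05,
                              seed = child_seed(seed, 2))

  with_seed(child_seed(seed, 3), {
    # plant eQTLs on polymorphic SVs and nearby genes
    poly <- which(apply(sv$dosage, 1, function(d)
      stats::var(d, na.rm = TRUE) > 0))
    effect <- NULL
    if (n_eqtl > 0 && length(poly)) {
      picked <- sample(poly, min(n_eqtl, length(poly)))
      gene_for <- vapply(picked, function(i) {
        g <- model$genes
        gap <- interval_gap(sv$events$start[i], sv$events$end[i],
                            g$start, g$end)
        cand <- which(g$chrom == sv$events$chrom[i] & gap <= 1e6)
        if (!length(cand)) cand <- seq_len(nrow(g))
        sample(cand, 1)
      }, numeric(1))
      effect <- data.frame(variant_id = sv$events$sv_id[picked],
                           gene_id = model$genes$gene_id[gene_for],
                           beta = rep_len(beta, length(picked)),
                           stringsAsFactors = FALSE)
    }
    tags <- NULL
    if (n_ld_tags > 0 && length(poly)) {
      tsv <- sample(poly, min(n_ld_tags, length(poly)))
      tags <- data.frame(sv_id = sv$events$sv_id[tsv],
                         snv_id = sprintf("SNVtag%03d", seq_along(tsv)),
                         r2 = tag_r2, stringsAsFactors = FALSE)
    }
    truth <- sim_truth(effect_table = effect, ld_targets = tags,
                       noise = noise, seed = seed)

    snvs <- simulate_snv_genotypes_with_ld(model, sv,
                                           ld_targets = truth$ld_targets,
                                           n_background_snvs = n_snv,
                                           seed = child_seed(seed, 4))
    expr <- simulate_expression(model, sv, truth,
                                seed = child_seed(seed, 5))
    methyl <- simulate_methylation_intensities(
      model, sv, truth = truth, tissue_labels = tissue_labels,
      seed = child_seed(seed, 6))
    list(model = model, sv = sv, snvs = snvs, expr = expr,
         methyl = methyl, truth = truth)
  })
}

#' Write a simulated cohort to disk in standard formats
#'
#' SV and SNV genotypes as VCF 4.2, depth ratios and expression counts
#' and probe intensities as TSV, gene models as GFF3, elements and
#' recombination sites as BED, the ground truth as a JSON sidecar.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    sv_vcf = file.path(dir, "sv.vcf"),
    snv_vcf = file.path(dir, "snv.vcf"),
    depth_ratios = file.path(dir, "depth_ratios.tsv"),
    genes_gff3 = file.path(dir, "genes.gff3"),
    elements_bed = file.path(dir, "elements.bed"),
    recomb_bed = file.path(dir, "recomb.bed"),
    expression_tsv = file.path(dir, "expression.tsv"),
    methyl_tsv = file.path(dir, "methylation.tsv"),
    truth_json = file.path(dir, "truth.json"))
  write_sv_vcf(cohort$sv, paths["sv_vcf"])
  write_sv_vcf(cohort$snvs, paths["snv_vcf"])
  write_depth_ratio_tsv(cohort$sv, paths["depth_ratios"])
  write_gff3(cohort$model, paths["genes_gff3"])
  write_bed(cohort$model$elements, paths["elements_bed"])
  write_recomb_bed(cohort$model$recomb, paths["recomb_bed"])
  write_expression_tsv(cohort$expr, paths["expression_tsv"])
  write_methyl_tsv(cohort$methyl, paths["methyl_tsv"])
  write_truth_json(cohort$truth, paths["truth_json"])
  invisible(paths)
}
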