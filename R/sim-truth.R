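#' Ground truth container for synthetic cohorts
#'
#' Collects every planted effect so parameter-recovery tests can compare
#' pipeline output against a single authoritative record.
#'
#' @param effect_table data frame with columns `variant_id`, `gene_id`,
#'   `beta` — the additive effect of one alternate-allele dosage unit on
#'   normalized (log2-scale) expression.
#' @param dosage_model named list giving the heterozygous-carrier
#'   expression multiplier per affected copy for deletions and
#'   duplications; the gene-level factor for dosage `d` is
#'   `max(0, 1 + d * (m - 1))`, so the default `DEL = 0.5` yields 0.5 for
#'   heterozygous and 0 for homozygous full-gene deletions.
#' @param intensity_effect fractional change of total methylation-probe
#'   intensity per affected copy (0.5 means a heterozygous deletion drops
#'   total intensity to (2 - 0.5)/2 = 75% of the diploid mean).
#' @param ld_targets data frame (`sv_id`, `snv_id`, `r2`, optional `pos`)
#'   of tagging SNVs to synthesize at a target squared correlation.
#' @param noise list with `expression_sd` (log2-scale biological SD),
#'   `dispersion` (negative-binomial overdispersion; 0 = Poisson),
#'   `intensity_sd` (sdlog of multiplicative intensity noise) and
#'   `depth_sd` (SD of read-depth-ratio noise).
#' @param seed integer master seed.
#'
#' @return a `sim_truth` list.
#' @export
sim_truth <- function(effect_table = NULL,
                      dosage_model = list(DEL = 0.5, DUP = 1.5),
                      intensity_effect = 0.5,
                      ld_targets = NULL,
                      noise = list(expression_sd = 0.5, dispersion = 0.05,
                                   intensity_sd = 0.1, depth_sd = 0.05),
                      seed = 1L) {
  effect_table <- effect_table %||%
    data.frame(variant_id = character(), gene_id = character(),
               beta = numeric())
  ld_targets <- ld_targets %||%
    data.frame(sv_id = character(), snv_id = character(), r2 = numeric())
  stopifnot(all(c("variant_id", "gene_id", "beta") %in% names(effect_table)),
            all(c("sv_id", "snv_id", "r2") %in% names(ld_targets)))
  if (nrow(ld_targets) && any(ld_targets$r2 < 0 | ld_targets$r2 > 1))
    stop("ld_targets$r2 must lie in [0, 1]")
  defaults <- list(expression_sd = 0.5, dispersion = 0.05,
                   intensity_sd = 0.1, depth_sd = 0.05)
  noise <- utils::modifyList(defaults, noise)
  if (any(unlist(noise) < 0)) stop("noise parameters must be >= 0")
  structure(list(effect_table = effect_table, dosage_model = dosage_model,
                 intensity_effect = intensity_effect,
                 ld_targets = ld_targets, noise = noise,
                 seed = as.integer(seed)),
            class = "sim_truth")
}

#' Effect size needed for a target global variance-explained fraction
#'
#' For a universe of `n_genes` genes with residual log2-expression SD
#' `noise_sd`, of which `n_affected` carry one eQTL each at allele
#' frequency `af`, the summed-variance coefficient of determination is
#' `R2 = k*v*beta^2 / (k*v*beta^2 + G*sd^2)` with `v = 2*af*(1-af)` the
#' Hardy-Weinberg dosage variance.  Solving for beta gives the planted
#' effect that makes the cohort explain the requested fraction.
#'
#' @param target_r2 desired set-level R-squared in (0, 1).
#' @param n_genes size of the gene universe.
#' @param n_affected number of genes with one planted eQTL.
#' @param noise_sd residual SD on the normalized (log2) scale.
#' @param af allele frequency of the planted variants.
#' @return the common beta (positive root).
#' @export
beta_for_global_r2 <- function(target_r2, n_genes, n_affected,
                               noise_sd = 1, af = 0.5) {
  stopifnot(target_r2 > 0, target_r2 < 1, n_affected >= 1,
            n_genes >= n_affected)
  v <- 2 * af * (1 - af)
  sqrt(target_r2 * n_genes * noise_sd^2 /
         ((1 - target_r2) * n_affected * v))
}
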