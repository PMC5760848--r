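#' Default thresholds for a pipeline run
#'
#' Every threshold the stages use, spelled out so the emitted report can
#' embed the exact configuration: read-depth-ratio bounds 0.8 (DEL) /
#' 1.3 (DUP), LD R-squared 0.5 (strict), 1 Mb cis window, FDR 0.05,
#' variance-explained nominal p cut 0.01, common-SV carrier frequency
#' 0.05, methylation validation alpha 0.05.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(depth_ratio_del = 0.8, depth_ratio_dup = 1.3,
       ld_r2 = 0.5, ld_search_window = 1e6,
       cis_window = 1e6, fdr_alpha = 0.05,
       variance_p_cut = 0.01, common_carrier_freq = 0.05,
       validation_alpha = 0.05)
}

#' Read and validate a pipeline configuration
#'
#' The configuration is a plain YAML file with `inputs` (paths to
#' sv_vcf, depth_ratios, snv_vcf, genes_gff3, elements_bed, recomb_bed,
#' expression_tsv, methyl_tsv), optional `chromosomes` (name: length),
#' optional `hla_region` (chrom/start/end), `thresholds` overriding
#' [default_thresholds()], `seed` and `outdir`.  Every referenced input
#' path must exist; unknown threshold names are an error.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a config list (as from [yaml::read_yaml()]).
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$inputs), !is.null(cfg$outdir))
  missing <- unlist(cfg$inputs)[!file.exists(unlist(cfg$inputs))]
  if (length(missing))
    stop("config references missing input file(s): ",
         paste(missing, collapse = ", "))
  thr <- default_thresholds()
  extra <- setdiff(names(cfg$thresholds %||% list()), names(thr))
  if (length(extra))
    stop("unknown threshold(s) in config: ", paste(extra, collapse = ", "))
  cfg$thresholds <- utils::modifyList(thr, cfg$thresholds %||% list())
  t <- cfg$thresholds
  stopifnot(t$fdr_alpha >= 0, t$fdr_alpha <= 1, t$ld_r2 >= 0,
            t$ld_r2 <= 1, t$cis_window > 0, t$variance_p_cut >= 0,
            t$variance_p_cut <= 1, t$validation_alpha >= 0,
            t$validation_alpha <= 1)
  cfg$seed <- cfg$seed %||% 1L
  cfg
}

#' Run the full SV-eQTL pipeline
#'
#' Executes filter (depth ratio, inversion support) -> annotate ->
#' LD/recombination span extension -> SV and SNV cis-eQTL scans ->
#' SV-vs-SNV comparison -> variance explained -> methylation validation.
#' Stage outputs are written as TSV under `outdir` and a JSON report
#' embedding the exact configuration and per-stage counts is emitted;
#' a rerun with the same config and inputs is bit-identical.
#'
#' @param cfg a validated config (see [read_run_config()]), or a path to
#'   a YAML config.
#' @return the run report (list), invisibly; also written to
#'   `outdir/report.json`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg)
  t <- cfg$thresholds
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = cfg, stages = list())
  step <- function(name, counts) {
    report$stages[[name]] <<- counts
    message("[svqtl] ", name, ": ",
            paste(names(counts), unlist(counts), sep = "=",
                  collapse = ", "))
  }
  fail <- function(name, e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)

  # ingest ---------------------------------------------------------------
  inp <- tryCatch({
    sv <- read_sv_vcf(cfg$inputs$sv_vcf,
                      depth_ratios = cfg$inputs$depth_ratios)
    snvs <- read_snv_vcf(cfg$inputs$snv_vcf)
    ga <- read_gff3_genes(cfg$inputs$genes_gff3)
    elements <- read_bed(cfg$inputs$elements_bed)
    names(elements)[names(elements) == "name"] <- "class"
    recomb <- read_recomb_bed(cfg$inputs$recomb_bed)
    expr <- read_expression_tsv(cfg$inputs$expression_tsv)
    methyl <- read_methyl_tsv(cfg$inputs$methyl_tsv)
    chroms <- if (!is.null(cfg$chromosomes))
      data.frame(name = names(cfg$chromosomes),
                 length = unlist(cfg$chromosomes))
    else {
      ends <- c(ga$genes$end, sv$events$end, snvs$variants$end)
      chr <- unique(c(ga$genes$chrom, sv$events$chrom))
      data.frame(name = chr, length = vapply(chr, function(cn)
        max(ends[c(ga$genes$chrom, sv$events$chrom,
                   snvs$variants$chrom) == cn]) + 1e6, numeric(1)))
    }
    model <- structure(list(chromosomes = chroms, genes = ga$genes,
                            exons = ga$exons, elements = elements,
                            recomb = recomb),
                       class = "genome_model")
    list(sv = sv, snvs = snvs, model = model, expr = expr,
         methyl = methyl)
  }, error = function(e) fail("ingest", e))
  step("ingest", list(n_sv = nrow(inp$sv$events),
                      n_snv = nrow(inp$snvs$variants),
                      n_genes = nrow(inp$model$genes),
                      n_samples = ncol(inp$sv$dosage)))

  # sv-filter ------------------------------------------------------------
  kept <- tryCatch({
    fd <- filter_by_depth_ratio(inp$sv, del_max = t$depth_ratio_del,
                                dup_min = t$depth_ratio_dup)
    utils::write.table(fd$report, file.path(cfg$outdir,
                                            "filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fi <- filter_inversions(fd$kept)
    fi$kept
  }, error = function(e) fail("sv-filter", e))
  step("sv-filter", list(n_in = nrow(inp$sv$events),
                         n_kept = nrow(kept$events)))
  freq <- allele_frequency(kept, common_cutoff = t$common_carrier_freq)
  utils::write.table(freq, file.path(cfg$outdir, "sv_frequency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # annotate -------------------------------------------------------------
  ann <- tryCatch(annotate_svs(kept, inp$model),
                  error = function(e) fail("annotate", e))
  utils::write.table(ann$class_counts,
                     file.path(cfg$outdir, "element_burden.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ann$gene_impact,
                     file.path(cfg$outdir, "gene_impact.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  step("annotate",
       list(elements_hit = sum(ann$class_counts$genome_wide),
            genes_impacted = sum(ann$gene_impact$impact != "none")))

  # expression preprocessing ---------------------------------------------
  expr <- tryCatch(
    normalize_expression(filter_low_expression(inp$expr)),
    error = function(e) fail("expression", e))
  step("expression", list(n_genes_in = nrow(inp$expr$genes),
                          n_genes_kept = nrow(expr$genes)))

  # extend ---------------------------------------------------------------
  spans <- tryCatch({
    sv_spans <- extend_spans(kept, inp$snvs, inp$model,
                             r2_threshold = t$ld_r2,
                             search_window = t$ld_search_window)
    snv_spans <- extend_spans(inp$snvs, inp$snvs, inp$model,
                              r2_threshold = t$ld_r2,
                              search_window = t$ld_search_window)
    write_spans_bed(sv_spans, file.path(cfg$outdir, "sv_spans.bed"))
    list(sv = sv_spans, snv = snv_spans)
  }, error = function(e) fail("extend", e))
  step("extend",
       list(sv_spans = nrow(spans$sv), snv_spans = nrow(spans$snv),
            sv_ld_extended = sum(spans$sv$ld_start < spans$sv$start |
                                   spans$sv$ld_end > spans$sv$end)))

  # eqtl (SV and SNV runs, corrected separately) -------------------------
  hla <- cfg$hla_region
  eq <- tryCatch({
    sv_pairs <- cis_pairs(spans$sv, expr$genes, window = t$cis_window,
                          hla_region = hla)
    snv_pairs <- cis_pairs(spans$snv, expr$genes,
                           window = t$cis_window, hla_region = hla)
    sv_rec <- run_eqtl(kept, expr, sv_pairs, fdr_alpha = t$fdr_alpha,
                       cis_window = t$cis_window)
    snv_rec <- run_eqtl(inp$snvs, expr, snv_pairs,
                        fdr_alpha = t$fdr_alpha,
                        cis_window = t$cis_window)
    list(sv = sv_rec, snv = snv_rec)
  }, error = function(e) fail("eqtl", e))
  for (run in names(eq))
    utils::write.table(eq[[run]],
                       file.path(cfg$outdir,
                                 paste0(run, "_eqtl.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  step("eqtl", list(sv_pairs_tested = nrow(eq$sv),
                    sv_significant = sum(eq$sv$significant),
                    snv_pairs_tested = nrow(eq$snv),
                    snv_significant = sum(eq$snv$significant)))

  # compare --------------------------------------------------------------
  cmp <- tryCatch(compare_sv_snv(eq$sv, eq$snv, alpha = t$fdr_alpha),
                  error = function(e) fail("compare", e))
  step("compare", list(sv_only_fraction = cmp$sv_only_fraction,
                       shared_genes = nrow(cmp$per_gene)))

  # variance -------------------------------------------------------------
  varrep <- tryCatch(
    global_sv_variance(eq$sv, kept, expr, p_cut = t$variance_p_cut),
    error = function(e) fail("variance", e))
  step("variance", list(r2_universe = varrep$r2_universe,
                        r2_linked_only = varrep$r2_linked_only,
                        n_linked = varrep$n_linked))

  # meth-validate --------------------------------------------------------
  val <- tryCatch(
    validate_svs(kept, inp$methyl, alpha = t$validation_alpha),
    error = function(e) fail("meth-validate", e))
  utils::write.table(val$results,
                     file.path(cfg$outdir, "validation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  step("meth-validate",
       list(n_testable = nrow(val$results),
            n_validated = sum(val$results$validated),
            n_untestable = nrow(val$untestable)))

  report$comparison <- cmp[c("sv_only_fraction", "sign_agreement",
                             "spearman_rho")]
  report$variance <- varrep[c("r2_universe", "r2_linked_only",
                              "n_linked", "n_genes")]
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "columns", pretty = TRUE)
  invisible(report)
}
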