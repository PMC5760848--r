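# File-format boundary. Internally everything is 0-based half-open;
# GFF3/BED conversions go through rtracklayer so the on-disk conventions
# (GFF3 1-based closed, BED 0-based half-open) are handled there.

#' Write the gene/exon models of a genome model as GFF3
#'
#' @param model a `genome_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(model, path) {
  g <- model$genes; e <- model$exons
  gene_gr <- gr_from_intervals(g$chrom, g$start, g$end)
  S4Vectors::mcols(gene_gr) <- S4Vectors::DataFrame(
    type = "gene", ID = g$gene_id)
  GenomicRanges::strand(gene_gr) <- g$strand
  ex_gr <- gr_from_intervals(e$chrom, e$start, e$end)
  S4Vectors::mcols(ex_gr) <- S4Vectors::DataFrame(
    type = "exon", ID = e$exon_id, Parent = e$gene_id)
  rtracklayer::export(c(gene_gr, ex_gr), path, format = "gff3")
  invisible(path)
}

#' Read gene and exon models from GFF3
#'
#' @param path GFF3 file with `gene` and `exon` features (exons carry a
#'   `Parent` gene id).
#' @return list(`genes`, `exons`) data frames in internal coordinates.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", ]
  exons <- df[df$type == "exon", ]
  parent <- vapply(exons$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  list(genes = data.frame(gene_id = genes$ID,
                          chrom = as.character(genes$seqnames),
                          strand = as.character(genes$strand),
                          start = genes$start - 1, end = genes$end,
                          stringsAsFactors = FALSE),
       exons = data.frame(gene_id = parent,
                          exon_id = exons$ID,
                          chrom = as.character(exons$seqnames),
                          start = exons$start - 1, end = exons$end,
                          stringsAsFactors = FALSE))
}

#' Write intervals (elements, recombination sites, spans) as BED
#'
#' @param df data frame with `chrom`, `start`, `end` and optionally a
#'   `name` column (or `class`/`element_id`/`variant_id`, used in that
#'   order).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  name <- df$name %||% df$class %||% df$element_id %||%
    df$variant_id %||% rep(".", nrow(df))
  gr <- gr_from_intervals(df$chrom, df$start, df$end, name = name)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED file into an internal interval data frame
#'
#' @param path BED file.
#' @return data frame (`chrom`, `start`, `end`, `name`).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             name = if ("name" %in% names(S4Vectors::mcols(gr)))
               gr$name else NA_character_,
             stringsAsFactors = FALSE)
}

# Recombination sites as 1-bp BED intervals.
write_recomb_bed <- function(recomb, path) {
  write_bed(data.frame(chrom = recomb$chrom, start = recomb$pos,
                       end = recomb$pos + 1, name = "recomb"), path)
}

read_recomb_bed <- function(path) {
  b <- read_bed(path)
  data.frame(chrom = b$chrom, pos = b$start, stringsAsFactors = FALSE)
}

#' Write / read an expression count matrix as TSV
#'
#' Layout: `gene_id`, `chrom`, `start`, `end`, then one column per
#' sample.
#'
#' @param expr an `expression_matrix`.
#' @param path TSV file.
#' @return `path` (writer) or an `expression_matrix` (reader).
#' @export
write_expression_tsv <- function(expr, path) {
  df <- cbind(expr$genes[c("gene_id", "chrom", "start", "end")],
              as.data.frame(expr$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- c("gene_id", "chrom", "start", "end")
  counts <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  new_expression_matrix(df[meta], counts)
}

#' Write / read methylation probe intensities as long-format TSV
#'
#' Columns: probe_id, chrom, pos, sample, meth, unmeth, tissue.
#'
#' @param methyl a `methyl_set`.
#' @param path TSV file.
#' @return `path` (writer) or a `methyl_set` (reader).
#' @export
write_methyl_tsv <- function(methyl, path) {
  samples <- colnames(methyl$meth)
  long <- do.call(rbind, lapply(samples, function(s)
    data.frame(probe_id = methyl$probes$probe_id,
               chrom = methyl$probes$chrom, pos = methyl$probes$pos,
               sample = s, meth = methyl$meth[, s],
               unmeth = methyl$unmeth[, s],
               tissue = unname(methyl$tissue[s]),
               stringsAsFactors = FALSE)))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_methyl_tsv
#' @export
read_methyl_tsv <- function(path) {
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE,
                            stringsAsFactors = FALSE)
  probes <- unique(long[c("probe_id", "chrom", "pos")])
  rownames(probes) <- NULL
  samples <- unique(long$sample)
  shape <- function(col) {
    m <- matrix(NA_real_, nrow(probes), length(samples),
                dimnames = list(probes$probe_id, samples))
    m[cbind(match(long$probe_id, probes$probe_id),
            match(long$sample, samples))] <- long[[col]]
    m
  }
  tissue <- stats::setNames(
    long$tissue[match(samples, long$sample)], samples)
  structure(list(probes = probes, meth = shape("meth"),
                 unmeth = shape("unmeth"), tissue = tissue),
            class = "methyl_set")
}

#' Write per-sample read-depth ratios as TSV (sv_id x sample)
#'
#' @param sv an `sv_set` with `depth_ratio`.
#' @param path TSV file.
#' @return `path`, invisibly.
#' @export
write_depth_ratio_tsv <- function(sv, path) {
  df <- data.frame(sv_id = sv$events$sv_id,
                   as.data.frame(sv$depth_ratio, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write extended spans as BED with original/LD coordinates as extras
#'
#' @param spans an [extend_spans()] result.
#' @param path output TSV (BED-like: chrom, final span, variant_id,
#'   then original and LD coordinates).
#' @return `path`, invisibly.
#' @export
write_spans_bed <- function(spans, path) {
  df <- data.frame(chrom = spans$chrom, start = spans$final_start,
                   end = spans$final_end, name = spans$variant_id,
                   orig_start = spans$start, orig_end = spans$end,
                   ld_start = spans$ld_start, ld_end = spans$ld_end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize simulation ground truth as JSON
#'
#' @param truth a [sim_truth()].
#' @param path JSON file.
#' @return `path` (writer) or a `sim_truth` (reader).
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  df_or_null <- function(d) if (length(d)) as.data.frame(d) else NULL
  sim_truth(effect_table = df_or_null(x$effect_table),
            dosage_model = x$dosage_model,
            intensity_effect = x$intensity_effect,
            ld_targets = df_or_null(x$ld_targets),
            noise = x$noise, seed = x$seed)
}
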