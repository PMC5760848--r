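# Fixture builders shared across test files.  Everything is constructed
# in code; coordinates follow the package's 0-based half-open convention.

# An sv_set built directly from explicit parts.
make_sv_set <- function(events, dosage, depth_ratio = NULL) {
  samples <- colnames(dosage) %||% sprintf("S%03d", seq_len(ncol(dosage)))
  colnames(dosage) <- samples
  if (!is.null(depth_ratio)) colnames(depth_ratio) <- samples
  svqtl:::new_sv_set(events, dosage, depth_ratio)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-row SV event table with overridable fields.
sv_event_row <- function(sv_id = "SV1", chrom = "chr1", start = 1000,
                         end = 2000, sv_type = "DEL", bp_up = TRUE,
                         bp_down = TRUE) {
  data.frame(sv_id = sv_id, chrom = chrom, start = start, end = end,
             sv_type = sv_type, af = NA_real_, bp_up = bp_up,
             bp_down = bp_down, stringsAsFactors = FALSE)
}

# A hand-built two-gene genome model on one 1 Mb chromosome:
#   G1 [1000, 4000) with exons [1200,1500) and [3000,3500)
#   G2 [10000, 40000) with exons [11000,12000) and [30000,31000)
tiny_model <- function(elements = NULL, recomb_pos = numeric(0),
                       chrom_length = 1e6) {
  genes <- data.frame(
    gene_id = c("G1", "G2"), chrom = "chr1", strand = c("+", "-"),
    start = c(1000, 10000), end = c(4000, 40000),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("G1", "G1", "G2", "G2"),
    exon_id = c("G1.E01", "G1.E02", "G2.E01", "G2.E02"),
    chrom = "chr1",
    start = c(1200, 3000, 11000, 30000),
    end = c(1500, 3500, 12000, 31000), stringsAsFactors = FALSE)
  elements <- elements %||%
    data.frame(element_id = "E1", class = "enhancer", chrom = "chr1",
               start = 500, end = 800, stringsAsFactors = FALSE)
  structure(list(
    chromosomes = data.frame(name = "chr1", length = chrom_length),
    genes = genes, exons = exons, elements = elements,
    recomb = data.frame(chrom = rep("chr1", length(recomb_pos)),
                        pos = recomb_pos)),
    class = "genome_model")
}

# A genotype_matrix of SNVs from parallel vectors.
make_snvs <- function(pos, dosage_rows, chrom = "chr1",
                      ids = sprintf("SNV%03d", seq_along(pos))) {
  variants <- data.frame(variant_id = ids, chrom = chrom, start = pos,
                         end = pos + 1, stringsAsFactors = FALSE)
  dosage <- do.call(rbind, dosage_rows)
  colnames(dosage) <- sprintf("S%03d", seq_len(ncol(dosage)))
  svqtl::as_genotype_matrix(variants, dosage)
}

# An expression_matrix from a plain counts matrix; genes placed at
# arbitrary positions on chr1 unless an interval table is given.
make_expr <- function(counts, genes = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("G%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%03d", seq_len(ncol(counts)))
  genes <- genes %||% data.frame(
    gene_id = rownames(counts), chrom = "chr1",
    start = seq_len(nrow(counts)) * 10000,
    end = seq_len(nrow(counts)) * 10000 + 5000,
    stringsAsFactors = FALSE)
  svqtl:::new_expression_matrix(genes, counts)
}

# Brute-force quadratic interval overlap oracle (half-open).
oracle_overlap <- function(q, e, contained = FALSE) {
  hits <- list()
  for (i in seq_len(nrow(q))) for (j in seq_len(nrow(e))) {
    same <- q$chrom[i] == e$chrom[j]
    if (!same) next
    if (contained) {
      ok <- e$start[j] >= q$start[i] && e$end[j] <= q$end[i]
    } else {
      ok <- q$start[i] < e$end[j] && e$start[j] < q$end[i]
    }
    if (ok) hits[[length(hits) + 1L]] <- c(i, j)
  }
  if (!length(hits))
    return(data.frame(query = integer(), element = integer()))
  m <- do.call(rbind, hits)
  data.frame(query = m[, 1], element = m[, 2])
}

subset_sv <- function(sv, i)
  svqtl:::subset_sv_set(sv, seq_len(nrow(sv$events)) %in% i)

impact_of <- function(rep, gene)
  rep$gene_impact$impact[rep$gene_impact$gene_id == gene]

# rows of a ratio table where the DEL contains every exon of the gene
full_gene_rows <- function(ratios, model, sv) {
  which(vapply(seq_len(nrow(ratios)), function(r) {
    ev <- sv$events[sv$events$sv_id == ratios$sv_id[r], ]
    ex <- model$exons[model$exons$gene_id == ratios$gene_id[r], ]
    all(ex$start >= ev$start & ex$end <= ev$end)
  }, logical(1)))
}

sort_pairs <- function(df) {
  df <- df[order(df$query, df$element), , drop = FALSE]
  rownames(df) <- NULL
  df
}
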