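#' Build a queryable interval index
#'
#' Wraps a set of classed genomic intervals in a \pkg{GenomicRanges}
#' index supporting overlap and containment queries with half-open
#' 0-based semantics: `[10, 20)` does not overlap `[20, 30)`.
#'
#' @param elements data frame with `chrom`, `start`, `end` and any
#'   metadata columns (e.g. `class`, `element_id`).
#' @return an `interval_index`.
#' @export
build_interval_index <- function(elements) {
  check_interval_df(elements, "element")
  gr <- gr_from_intervals(elements$chrom, elements$start, elements$end)
  structure(list(gr = gr, elements = elements), class = "interval_index")
}

#' Query an interval index
#'
#' @param index an [build_interval_index()] result.
#' @param chrom,start,end query intervals (vectors, 0-based half-open).
#' @param type `"any"` for >= 1 bp overlap, `"element_within"` for
#'   elements entirely inside the query, `"query_within"` for queries
#'   entirely inside an element.
#' @return data frame (`query`, `element`) of index pairs.
#' @export
query_index <- function(index, chrom, start, end,
                        type = c("any", "element_within",
                                 "query_within")) {
  type <- match.arg(type)
  q <- gr_from_intervals(chrom, start, end)
  hits <- switch(type,
    any = GenomicRanges::findOverlaps(q, index$gr),
    element_within = GenomicRanges::findOverlaps(index$gr, q,
                                                 type = "within"),
    query_within = GenomicRanges::findOverlaps(q, index$gr,
                                               type = "within"))
  if (type == "element_within")
    data.frame(query = S4Vectors::subjectHits(hits),
               element = S4Vectors::queryHits(hits))
  else
    data.frame(query = S4Vectors::queryHits(hits),
               element = S4Vectors::subjectHits(hits))
}

#' Annotate SV impact on genes and regulatory elements
#'
#' Produces the overlap/burden report: per element class, the number of
#' distinct elements hit (>= 1 bp overlap) genome-wide and per patient
#' (counting only SVs the patient carries, dosage >= 1); per gene, an
#' impact label; per SV type, counts of affected exons, introns and
#' genes.  Labels, in order of severity: `gene_entirely_covered` (gene
#' interval inside an SV), `exon_entirely_deleted` (>= 1 exon inside a
#' DEL/INVDEL), `intronic_only` (an SV entirely inside an intron with no
#' exon overlap), `partial_overlap`, `none`.  An element is counted once
#' per class even when hit by several SVs.
#'
#' @param sv an `sv_set`.
#' @param model a `genome_model`.
#' @return an `overlap_report`: list(`class_counts`, `patient_counts`,
#'   `gene_impact`, `type_counts`).
#' @export
annotate_svs <- function(sv, model) {
  stopifnot(inherits(sv, "sv_set"), inherits(model, "genome_model"))
  bad <- setdiff(unique(sv$events$chrom), model$chromosomes$name)
  if (length(bad))
    stop("unknown chromosome(s) in SV set: ", paste(bad, collapse = ", "))

  ev <- sv$events
  sv_gr <- gr_from_intervals(ev$chrom, ev$start, ev$end)
  samples <- colnames(sv$dosage)
  carried <- !is.na(sv$dosage) & sv$dosage >= 1L   # sv x sample

  # --- element burden (any overlap, deduplicated per element) ----------
  classes <- unique(model$elements$class)
  class_counts <- data.frame(class = classes, genome_wide = 0L)
  patient_counts <- expand.grid(sample = samples, class = classes,
                                stringsAsFactors = FALSE)
  patient_counts$count <- 0L
  if (nrow(model$elements)) {
    el_gr <- gr_from_intervals(model$elements$chrom, model$elements$start,
                               model$elements$end)
    hits <- GenomicRanges::findOverlaps(sv_gr, el_gr)
    hit_sv <- S4Vectors::queryHits(hits)
    hit_el <- S4Vectors::subjectHits(hits)
    for (k in seq_along(classes)) {
      in_cl <- model$elements$class[hit_el] == classes[k]
      class_counts$genome_wide[k] <- length(unique(hit_el[in_cl]))
      for (s in seq_along(samples)) {
        els <- hit_el[in_cl & carried[hit_sv, s]]
        row <- patient_counts$sample == samples[s] &
          patient_counts$class == classes[k]
        patient_counts$count[row] <- length(unique(els))
      }
    }
  }

  # --- gene impact ------------------------------------------------------
  genes <- model$genes
  gene_gr <- gr_from_intervals(genes$chrom, genes$start, genes$end)
  ex_gr <- gr_from_intervals(model$exons$chrom, model$exons$start,
                             model$exons$end)
  del_like <- ev$sv_type %in% c("DEL", "INVDEL")

  gene_any <- GenomicRanges::findOverlaps(gene_gr, sv_gr)
  gene_cov <- GenomicRanges::findOverlaps(gene_gr, sv_gr, type = "within")
  exon_in_sv <- GenomicRanges::findOverlaps(ex_gr, sv_gr, type = "within")
  exon_any <- GenomicRanges::findOverlaps(ex_gr, sv_gr)

  impact <- rep("none", nrow(genes))
  covered_genes <- unique(S4Vectors::queryHits(gene_cov))
  impact[covered_genes] <- "gene_entirely_covered"

  exdel_rows <- S4Vectors::queryHits(exon_in_sv)[
    del_like[S4Vectors::subjectHits(exon_in_sv)]]
  exdel_genes <- match(unique(model$exons$gene_id[exdel_rows]),
                       genes$gene_id)
  impact[setdiff(exdel_genes, covered_genes)] <- "exon_entirely_deleted"

  # intronic_only: SV within the gene body, overlapping no exon of it
  sv_in_gene <- GenomicRanges::findOverlaps(sv_gr, gene_gr,
                                            type = "within")
  exon_hit_by_sv <- split(S4Vectors::queryHits(exon_any),
                          S4Vectors::subjectHits(exon_any))
  for (h in seq_along(sv_in_gene)) {
    si <- S4Vectors::queryHits(sv_in_gene)[h]
    gi <- S4Vectors::subjectHits(sv_in_gene)[h]
    if (!impact[gi] %in% c("none", "partial_overlap")) next
    ex_rows <- exon_hit_by_sv[[as.character(si)]]
    gene_exons_hit <- !is.null(ex_rows) &&
      any(model$exons$gene_id[ex_rows] == genes$gene_id[gi])
    if (!gene_exons_hit) impact[gi] <- "intronic_only"
  }
  rest <- unique(S4Vectors::queryHits(gene_any))
  impact[rest[impact[rest] == "none"]] <- "partial_overlap"

  gene_impact <- data.frame(gene_id = genes$gene_id, impact = impact,
                            stringsAsFactors = FALSE)

  # --- per-SV-type affected feature counts -----------------------------
  type_counts <- do.call(rbind, lapply(unique(ev$sv_type), function(tp) {
    rows <- which(ev$sv_type == tp)
    exs <- unique(S4Vectors::queryHits(exon_in_sv)[
      S4Vectors::subjectHits(exon_in_sv) %in% rows])
    gns <- unique(S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(sv_gr[rows], gene_gr)))
    intronic <- sum(vapply(rows, function(si) {
      gh <- GenomicRanges::findOverlaps(sv_gr[si], gene_gr,
                                        type = "within")
      if (!length(gh)) return(FALSE)
      eh <- GenomicRanges::findOverlaps(sv_gr[si], ex_gr)
      !length(eh)
    }, logical(1)))
    data.frame(sv_type = tp, n_svs = length(rows),
               exons_contained = length(exs),
               intronic_svs = intronic, genes_overlapped = length(gns),
               stringsAsFactors = FALSE)
  }))

  structure(list(class_counts = class_counts,
                 patient_counts = patient_counts,
                 gene_impact = gene_impact,
                 type_counts = type_counts),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap_report\n  element burden (genome-wide):\n")
  print(x$class_counts, row.names = FALSE)
  cat("  gene impact:\n")
  print(table(x$gene_impact$impact))
  invisible(x)
}

#' Carrier/non-carrier expression ratios for CNV-affected genes
#'
#' For every DEL/DUP (incl. complex) event and every gene with at least
#' one exon entirely inside it, computes the ratio of the median
#' size-factor-normalized expression (linear scale, `count / size
#' factor`) over carriers (dosage >= 1) to the median over non-carriers.
#' Ratios with a zero non-carrier median are flagged `undefined` and
#' excluded from the summary.  The summary gives the median, quartiles,
#' the 1.5 x IQR whisker bounds, and a Wilcoxon signed-rank test of the
#' ratios against 1.
#'
#' @param expr an `expression_matrix` (raw counts; size factors are
#'   computed if absent).
#' @param sv an `sv_set`.
#' @param model a `genome_model` (for exon intervals).
#' @param sv_types event types to evaluate.
#' @return list(`ratios` data frame, `summary` list per sv type group).
#' @export
exon_expression_ratio <- function(expr, sv, model,
                                  sv_types = c("DEL", "DUP", "INVDEL",
                                               "INVDUP")) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(sv, "sv_set"))
  sf <- expr$size_factors %||% size_factors_median_ratio(expr$counts)
  norm_lin <- sweep(expr$counts, 2, sf, `/`)

  rows <- which(sv$events$sv_type %in% sv_types)
  ex_gr <- gr_from_intervals(model$exons$chrom, model$exons$start,
                             model$exons$end)
  sv_gr <- gr_from_intervals(sv$events$chrom, sv$events$start,
                             sv$events$end)
  hits <- GenomicRanges::findOverlaps(ex_gr, sv_gr, type = "within")
  keep <- S4Vectors::subjectHits(hits) %in% rows
  pairs <- unique(data.frame(
    sv_row = S4Vectors::subjectHits(hits)[keep],
    gene_id = model$exons$gene_id[S4Vectors::queryHits(hits)[keep]],
    stringsAsFactors = FALSE))

  out <- list()
  for (r in seq_len(nrow(pairs))) {
    si <- pairs$sv_row[r]; gid <- pairs$gene_id[r]
    if (!gid %in% rownames(norm_lin)) next
    d <- sv$dosage[si, ]
    carriers <- which(!is.na(d) & d >= 1L)
    wt <- which(!is.na(d) & d == 0L)
    if (!length(carriers) || !length(wt)) next
    mc <- median_(norm_lin[gid, carriers])
    mw <- median_(norm_lin[gid, wt])
    out[[length(out) + 1L]] <- data.frame(
      sv_id = sv$events$sv_id[si], sv_type = sv$events$sv_type[si],
      gene_id = gid, n_carriers = length(carriers),
      median_carrier = mc, median_wt = mw,
      ratio = if (mw > 0) mc / mw else NA_real_,
      undefined = mw <= 0, stringsAsFactors = FALSE)
  }
  ratios <- if (length(out)) do.call(rbind, out) else
    data.frame(sv_id = character(), sv_type = character(),
               gene_id = character(), n_carriers = integer(),
               median_carrier = numeric(), median_wt = numeric(),
               ratio = numeric(), undefined = logical())

  summarize <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NULL)
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    test <- if (length(x) >= 2 && any(x != 1))
      suppressWarnings(stats::wilcox.test(x, mu = 1)) else NULL
    list(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
         lower_whisker = q[1] - 1.5 * iqr,
         upper_whisker = q[3] + 1.5 * iqr,
         signed_rank_p = if (is.null(test)) NA_real_ else test$p.value)
  }
  del <- ratios$ratio[ratios$sv_type %in% c("DEL", "INVDEL") &
                        !ratios$undefined]
  dup <- ratios$ratio[ratios$sv_type %in% c("DUP", "INVDUP") &
                        !ratios$undefined]
  list(ratios = ratios,
       summary = list(deletion = summarize(del),
                      duplication = summarize(dup),
                      all = summarize(ratios$ratio[!ratios$undefined])))
}
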