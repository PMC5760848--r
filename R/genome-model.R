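#' Generate a synthetic genome annotation model
#'
#' Builds the annotation universe every downstream stage consumes: one or
#' more chromosomes, non-overlapping (per strand) gene models with 2-20
#' exons each, regulatory elements of three classes (enhancer, TFBS,
#' lncRNA), and a strictly increasing set of recombination-site positions
#' per chromosome.  All intervals are 0-based, half-open base-pair spans.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp (>= 1e6); recycled across
#'   chromosomes.
#' @param n_genes total number of genes, distributed evenly over
#'   chromosomes.
#' @param element_densities named integer vector: number of elements to
#'   place per class, per chromosome.  Names must be a subset of
#'   `c("enhancer", "TFBS", "lncRNA")`.
#' @param n_recomb_sites recombination sites per chromosome.
#' @param seed integer seed; the model is a pure function of all arguments.
#' @param gene_length_range allowed gene lengths in bp.
#'
#' @return an object of class `genome_model`: a list with data frames
#'   `chromosomes` (name, length), `genes` (gene_id, chrom, strand, start,
#'   end), `exons` (gene_id, exon_id, chrom, start, end), `elements`
#'   (element_id, class, chrom, start, end) and `recomb` (chrom, pos).
#' @export
generate_genome_model <- function(n_chrom = 1L,
                                  chrom_length = 10e6,
                                  n_genes = 50L,
                                  element_densities = c(enhancer = 40L,
                                                        TFBS = 400L,
                                                        lncRNA = 60L),
                                  n_recomb_sites = 20L,
                                  seed = 1L,
                                  gene_length_range = c(5e3, 6e4)) {
  stopifnot(n_chrom >= 1, n_genes >= 1, n_recomb_sites >= 0,
            all(element_densities >= 0))
  if (chrom_length < 1e6) stop("chrom_length must be >= 1e6 bp")
  if (!all(names(element_densities) %in% c("enhancer", "TFBS", "lncRNA")))
    stop("unknown element class in element_densities")

  with_seed(seed, {
    chroms <- data.frame(name = paste0("chr", seq_len(n_chrom)),
                         length = rep_len(chrom_length, n_chrom),
                         stringsAsFactors = FALSE)

    per_chrom <- diff(round(seq(0, n_genes, length.out = n_chrom + 1)))
    genes <- list(); exons <- list()
    gid <- 0L
    for (ci in seq_len(n_chrom)) {
      placed <- place_nonoverlapping(chroms$length[ci], per_chrom[ci],
                                     gene_length_range, by_strand = TRUE,
                                     what = "genes")
      for (k in seq_len(nrow(placed))) {
        gid <- gid + 1L
        gene_id <- sprintf("G%04d", gid)
        g <- placed[k, ]
        genes[[gid]] <- data.frame(gene_id = gene_id,
                                   chrom = chroms$name[ci],
                                   strand = g$strand,
                                   start = g$start, end = g$end,
                                   stringsAsFactors = FALSE)
        n_ex <- sample(2:20, 1L)
        # 2*n_ex distinct breakpoints inside the gene give non-overlapping
        # exons nested within the gene span
        bp <- sort(sample(seq(g$start, g$end - 1L), 2L * n_ex))
        ex_start <- bp[seq(1L, 2L * n_ex, by = 2L)]
        ex_end <- bp[seq(2L, 2L * n_ex, by = 2L)]
        keep <- ex_end > ex_start
        exons[[gid]] <- data.frame(gene_id = gene_id,
                                   exon_id = sprintf("%s.E%02d", gene_id,
                                                     seq_len(sum(keep))),
                                   chrom = chroms$name[ci],
                                   start = ex_start[keep],
                                   end = ex_end[keep],
                                   stringsAsFactors = FALSE)
      }
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)

    elem_lengths <- c(enhancer = 300, TFBS = 200, lncRNA = 1500)
    elements <- list()
    for (cl in names(element_densities)) {
      n_el <- element_densities[[cl]]
      if (n_el == 0) next
      for (ci in seq_len(n_chrom)) {
        len <- elem_lengths[[cl]]
        start <- sample.int(chroms$length[ci] - len, n_el)
        elements[[paste(cl, ci)]] <-
          data.frame(class = cl, chrom = chroms$name[ci],
                     start = start, end = start + len,
                     stringsAsFactors = FALSE)
      }
    }
    elements <- if (length(elements)) do.call(rbind, elements) else
      data.frame(class = character(), chrom = character(),
                 start = numeric(), end = numeric())
    if (nrow(elements)) {
      elements <- cbind(element_id = sprintf("E%05d", seq_len(nrow(elements))),
                        elements)
      rownames(elements) <- NULL
    }

    recomb <- list()
    for (ci in seq_len(n_chrom)) {
      if (n_recomb_sites > 0) {
        pos <- sort(sample.int(chroms$length[ci], n_recomb_sites))
        recomb[[ci]] <- data.frame(chrom = chroms$name[ci], pos = pos,
                                   stringsAsFactors = FALSE)
      }
    }
    recomb <- if (length(recomb)) do.call(rbind, recomb) else
      data.frame(chrom = character(), pos = numeric())

    structure(list(chromosomes = chroms, genes = genes, exons = exons,
                   elements = elements, recomb = recomb, seed = seed),
              class = "genome_model")
  })
}

# Place n non-overlapping intervals on [0, chrom_length); with
# by_strand = TRUE overlap is only forbidden between same-strand features.
place_nonoverlapping <- function(chrom_length, n, length_range,
                                 by_strand = FALSE, what = "features",
                                 max_tries = 200L) {
  if (n == 0)
    return(data.frame(start = numeric(), end = numeric(),
                      strand = character()))
  lens <- round(stats::runif(n, length_range[1], length_range[2]))
  if (sum(lens) > chrom_length)
    stop("cannot place ", n, " ", what, " of total length ", sum(lens),
         " on a chromosome of length ", chrom_length)
  strand <- if (by_strand) sample(c("+", "-"), n, replace = TRUE) else
    rep("*", n)
  placed_start <- numeric(0); placed_end <- numeric(0)
  placed_strand <- character(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(chrom_length - lens[i], 1L)
      e <- s + lens[i]
      same <- placed_strand == strand[i]
      if (!any(same & placed_start < e & placed_end > s)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("placement error: could not place ", what,
           " without overlap (chromosome too crowded)")
    placed_start <- c(placed_start, s); placed_end <- c(placed_end, e)
    placed_strand <- c(placed_strand, strand[i])
  }
  o <- order(placed_start)
  data.frame(start = placed_start[o], end = placed_end[o],
             strand = placed_strand[o], stringsAsFactors = FALSE)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosome(s),",
      nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      nrow(x$elements), "elements,", nrow(x$recomb),
      "recombination sites\n")
  invisible(x)
}
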