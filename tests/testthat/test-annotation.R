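# Interval queries against a brute-force oracle, SV impact labels, and
# carrier/non-carrier exon expression ratios.

test_that("half-open interval semantics at the boundary", {
  idx <- build_interval_index(data.frame(chrom = "chr1",
                                         start = c(15, 20),
                                         end = c(30, 30)))
  hits <- query_index(idx, "chr1", 10, 20, type = "any")
  expect_equal(hits$element, 1L)   # [15,30) overlaps, [20,30) does not
  expect_error(build_interval_index(data.frame(chrom = "chr1",
                                               start = -5, end = 10)),
               "negative")
})

test_that("index queries equal the quadratic oracle on random fixtures", {
  set.seed(401)
  for (rep in 1:3) {
    e <- data.frame(chrom = sample(c("chr1", "chr2"), 400,
                                   replace = TRUE),
                    start = sample.int(10000, 400, replace = TRUE))
    e$end <- e$start + sample.int(500, 400, replace = TRUE)
    q <- data.frame(chrom = sample(c("chr1", "chr2"), 60,
                                   replace = TRUE),
                    start = sample.int(10000, 60, replace = TRUE))
    q$end <- q$start + sample.int(800, 60, replace = TRUE)
    idx <- build_interval_index(e)
    expect_equal(sort_pairs(query_index(idx, q$chrom, q$start, q$end,
                                        type = "any")),
                 sort_pairs(oracle_overlap(q, e)))
    expect_equal(sort_pairs(query_index(idx, q$chrom, q$start, q$end,
                                        type = "element_within")),
                 sort_pairs(oracle_overlap(q, e, contained = TRUE)))
  }
})

test_that("SV impact labels follow containment rules", {
  model <- tiny_model()
  events <- rbind(
    sv_event_row("SV_cover", start = 0, end = 5000),       # covers G1
    sv_event_row("SV_intron", start = 1600, end = 1700),   # G1 intron
    sv_event_row("SV_exdel", start = 10500, end = 12500),  # G2 exon 1
    sv_event_row("SV_partial", start = 29000, end = 30500))# partial G2
  dosage <- matrix(1L, 4, 3)
  sv <- make_sv_set(events, dosage)

  rep1 <- annotate_svs(subset_sv(sv, 1), model)
  expect_equal(impact_of(rep1, "G1"), "gene_entirely_covered")

  rep2 <- annotate_svs(subset_sv(sv, 2), model)
  expect_equal(impact_of(rep2, "G1"), "intronic_only")

  rep3 <- annotate_svs(subset_sv(sv, 3), model)
  expect_equal(impact_of(rep3, "G2"), "exon_entirely_deleted")

  rep4 <- annotate_svs(subset_sv(sv, 4), model)
  expect_equal(impact_of(rep4, "G2"), "partial_overlap")

  expect_error(annotate_svs(make_sv_set(sv_event_row(chrom = "chrX"),
                                        matrix(1L, 1, 3)), model),
               "chrX")
})

test_that("an element hit by several SVs counts once; per-patient counts use carriers", {
  model <- tiny_model(elements = data.frame(
    element_id = "E1", class = "enhancer", chrom = "chr1",
    start = 500, end = 800, stringsAsFactors = FALSE))
  events <- rbind(sv_event_row("SV_a", start = 400, end = 600),
                  sv_event_row("SV_b", start = 700, end = 900))
  dosage <- rbind(c(1L, 0L, 0L), c(1L, 1L, 0L))
  sv <- make_sv_set(events, dosage)
  rep <- annotate_svs(sv, model)
  expect_equal(rep$class_counts$genome_wide[
    rep$class_counts$class == "enhancer"], 1L)
  pc <- rep$patient_counts[rep$patient_counts$class == "enhancer", ]
  expect_equal(pc$count[order(pc$sample)], c(1L, 1L, 0L))
})

test_that("exon expression ratios reproduce worked medians", {
  model <- tiny_model()
  # DEL containing G1's exons; carriers S1,S2; non-carriers S3,S4
  sv <- make_sv_set(sv_event_row(start = 1000, end = 4000),
                    matrix(c(1L, 1L, 0L, 0L), 1, 4))
  counts <- rbind(G1 = c(4, 4, 5, 5), G2 = c(7, 7, 7, 7))
  colnames(counts) <- colnames(sv$dosage)
  expr <- make_expr(counts, genes = data.frame(
    gene_id = c("G1", "G2"), chrom = "chr1",
    start = c(1000, 10000), end = c(4000, 40000)))
  expr$size_factors <- rep(1, 4)
  rr <- exon_expression_ratio(expr, sv, model)
  expect_equal(rr$ratios$ratio[rr$ratios$gene_id == "G1"], 0.8)

  # identical carrier and non-carrier expression -> ratio exactly 1
  counts2 <- counts; counts2["G1", ] <- 6
  expr2 <- make_expr(counts2, genes = expr$genes)
  expr2$size_factors <- rep(1, 4)
  rr2 <- exon_expression_ratio(expr2, sv, model)
  expect_equal(rr2$ratios$ratio[rr2$ratios$gene_id == "G1"], 1)

  # zero non-carrier median is flagged and excluded from the summary
  counts3 <- counts; counts3["G1", 3:4] <- 0
  expr3 <- make_expr(counts3, genes = expr$genes)
  expr3$size_factors <- rep(1, 4)
  rr3 <- exon_expression_ratio(expr3, sv, model)
  expect_true(rr3$ratios$undefined[rr3$ratios$gene_id == "G1"])
})

test_that("noiseless het-deletion cohorts give exact 0.5 ratios", {
  model <- generate_genome_model(n_genes = 30, seed = 6)
  sv <- simulate_sv_genotypes(model, n_sv = 10,
                              af_spectrum = list(dist = "fixed",
                                                 af = 0.25),
                              type_mix = c(DEL = 1, DUP = 0, INV = 0,
                                           INVDEL = 0, INVDUP = 0),
                              n_samples = 30, depth_noise_sd = 0,
                              seed = 7)
  sv$dosage[sv$dosage == 2L] <- 1L   # het carriers only
  truth <- sim_truth(dosage_model = list(DEL = 0.5, DUP = 1.5),
                     noise = list(expression_sd = 0, dispersion = 0))
  expr <- simulate_expression(model, sv, truth, baseline = 100,
                              family = "deterministic", seed = 8)
  expr$size_factors <- rep(1, ncol(expr$counts))
  rr <- exon_expression_ratio(expr, sv, model)
  full <- full_gene_rows(rr$ratios, model, sv)
  expect_gt(length(full), 0)
  expect_equal(rr$ratios$ratio[full], rep(0.5, length(full)))
})

test_that("null cohorts keep the ratio distribution centred at 1", {
  model <- generate_genome_model(n_genes = 30, seed = 10)
  ok <- vapply(1:20, function(s) {
    sv <- simulate_sv_genotypes(model, n_sv = 12,
                                af_spectrum = list(dist = "fixed",
                                                   af = 0.3),
                                type_mix = c(DEL = 1, DUP = 0, INV = 0,
                                             INVDEL = 0, INVDUP = 0),
                                n_samples = 40, seed = s)
    truth <- sim_truth(dosage_model = list(DEL = 1, DUP = 1),
                       noise = list(expression_sd = 0.3,
                                    dispersion = 0.02))
    expr <- simulate_expression(model, sv, truth, baseline = 200,
                                seed = s + 500)
    rr <- exon_expression_ratio(expr, sv, model)
    x <- rr$ratios$ratio[!rr$ratios$undefined]
    if (length(x) < 5) return(TRUE)
    b <- stats::binom.test(sum(x > 1), sum(x != 1))$p.value
    b > 0.01
  }, logical(1))
  expect_gte(sum(ok), 18)
})
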