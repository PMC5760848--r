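# Generators: determinism, Hardy-Weinberg behaviour, planted-truth
# contracts for genotypes, LD tags, expression and intensities.

test_that("genome model echoes requested feature counts and is seed-deterministic", {
  m <- generate_genome_model(n_chrom = 1, chrom_length = 10e6,
                             n_genes = 50, n_recomb_sites = 20, seed = 1)
  expect_equal(nrow(m$genes), 50)
  expect_equal(nrow(m$recomb), 20)
  expect_identical(m, generate_genome_model(n_chrom = 1,
                                            chrom_length = 10e6,
                                            n_genes = 50,
                                            n_recomb_sites = 20,
                                            seed = 1))
  m2 <- generate_genome_model(n_chrom = 1, chrom_length = 10e6,
                              n_genes = 50, n_recomb_sites = 20,
                              seed = 2)
  expect_false(identical(m$genes$start, m2$genes$start))
})

test_that("genome model satisfies its structural invariants", {
  m <- generate_genome_model(n_genes = 80, seed = 42)
  # exons nested in their gene span
  for (g in seq_len(nrow(m$genes))) {
    ex <- m$exons[m$exons$gene_id == m$genes$gene_id[g], ]
    expect_true(all(ex$start >= m$genes$start[g]))
    expect_true(all(ex$end <= m$genes$end[g]))
    expect_true(nrow(ex) >= 1 && nrow(ex) <= 20)
  }
  # genes non-overlapping per strand
  for (s in c("+", "-")) {
    g <- m$genes[m$genes$strand == s, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1)
      expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # recombination sites strictly increasing, in bounds
  expect_true(all(diff(m$recomb$pos) > 0))
  expect_true(all(m$recomb$pos <= m$chromosomes$length[1]))
  expect_true(all(m$elements$end <= m$chromosomes$length[1]))
})

test_that("infeasible gene placement raises a placement error", {
  expect_error(generate_genome_model(chrom_length = 1e6, n_genes = 100,
                                     gene_length_range = c(4e4, 6e4),
                                     seed = 1),
               "place")
})

test_that("SV genotypes follow Hardy-Weinberg at fixed allele frequency", {
  m <- generate_genome_model(seed = 1)
  sv <- simulate_sv_genotypes(m, n_sv = 1,
                              af_spectrum = list(dist = "fixed",
                                                 af = 0.5),
                              n_samples = 10000, seed = 7)
  d <- sv$dosage[1, ]
  freqs <- tabulate(d + 1L, 3L) / length(d)
  se <- sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / length(d))
  expect_true(all(abs(freqs - c(0.25, 0.5, 0.25)) < 3 * se))
})

test_that("Hardy-Weinberg chi-square holds across seeds", {
  m <- generate_genome_model(seed = 1)
  pass <- vapply(1:50, function(s) {
    sv <- simulate_sv_genotypes(m, n_sv = 1,
                                af_spectrum = list(dist = "fixed",
                                                   af = 0.3),
                                n_samples = 2000, seed = s,
                                depth_noise_sd = 0)
    obs <- tabulate(sv$dosage[1, ] + 1L, 3L)
    exp_p <- c(0.49, 0.42, 0.09)
    suppressWarnings(
      stats::chisq.test(obs, p = exp_p)$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(pass), 48)
})

test_that("zero allele frequency gives all-reference dosages", {
  m <- generate_genome_model(seed = 1)
  sv <- simulate_sv_genotypes(m, n_sv = 5,
                              af_spectrum = list(dist = "fixed", af = 0),
                              n_samples = 30, seed = 2)
  expect_true(all(sv$dosage == 0L))
})

test_that("noiseless read-depth ratios follow the per-copy dosage model", {
  m <- generate_genome_model(seed = 1)
  sv <- simulate_sv_genotypes(m, n_sv = 200,
                              af_spectrum = list(dist = "fixed",
                                                 af = 0.4),
                              n_samples = 40, depth_noise_sd = 0,
                              seed = 3)
  del <- sv$events$sv_type %in% c("DEL", "INVDEL")
  dup <- sv$events$sv_type %in% c("DUP", "INVDUP")
  inv <- sv$events$sv_type == "INV"
  expect_equal(sv$depth_ratio[del, ][sv$dosage[del, ] == 1L],
               rep(0.5, sum(sv$dosage[del, ] == 1L)))
  expect_equal(sv$depth_ratio[del, ][sv$dosage[del, ] == 2L],
               rep(0, sum(sv$dosage[del, ] == 2L)))
  expect_equal(sv$depth_ratio[dup, ][sv$dosage[dup, ] == 1L],
               rep(1.5, sum(sv$dosage[dup, ] == 1L)))
  if (any(inv))
    expect_true(all(sv$depth_ratio[inv, ] == 1))
  expect_identical(sv, simulate_sv_genotypes(
    m, n_sv = 200, af_spectrum = list(dist = "fixed", af = 0.4),
    n_samples = 40, depth_noise_sd = 0, seed = 3))
})

test_that("tagging SNVs realize their target LD R2", {
  m <- generate_genome_model(seed = 1)
  sv <- simulate_sv_genotypes(m, n_sv = 3,
                              af_spectrum = list(dist = "fixed",
                                                 af = 0.3),
                              n_samples = 1000, seed = 11)
  tags <- data.frame(sv_id = sv$events$sv_id,
                     snv_id = c("T1", "T2", "T3"),
                     r2 = c(1, 0, 0.8))
  snvs <- simulate_snv_genotypes_with_ld(m, sv, tags,
                                         n_background_snvs = 0,
                                         seed = 5)
  r2 <- vapply(tags$snv_id, function(id) {
    i <- match(tags$sv_id[match(id, tags$snv_id)], sv$events$sv_id)
    compute_ld_r2(sv$dosage[i, ], snvs$dosage[id, ])
  }, numeric(1))
  expect_equal(unname(r2[["T1"]]), 1)
  expect_lt(r2[["T2"]], (3 / sqrt(1000))^2)   # 3 SE of a null correlation
  expect_lt(abs(r2[["T3"]] - 0.8), 0.1)
  expect_identical(snvs, simulate_snv_genotypes_with_ld(
    m, sv, tags, n_background_snvs = 0, seed = 5))
})

test_that("unreachable LD target on a monomorphic SV is logged, not fatal", {
  m <- generate_genome_model(seed = 1)
  sv <- simulate_sv_genotypes(m, n_sv = 1,
                              af_spectrum = list(dist = "fixed", af = 0),
                              n_samples = 50, seed = 1)
  tags <- data.frame(sv_id = sv$events$sv_id[1], snv_id = "T1", r2 = 0.9)
  expect_warning(
    snvs <- simulate_snv_genotypes_with_ld(m, sv, tags,
                                           n_background_snvs = 0,
                                           seed = 1),
    "unreachable")
  expect_false(attr(snvs, "ld_log")$achievable[1])
})

test_that("homozygous deletion of all exons silences the gene", {
  model <- tiny_model()
  # DEL spanning all of G1's exons; sample 1 hom, sample 2 het, rest wt
  dosage <- matrix(0L, 1, 10)
  dosage[1, 1] <- 2L; dosage[1, 2] <- 1L
  sv <- make_sv_set(sv_event_row(start = 1000, end = 4000), dosage)
  truth <- sim_truth(noise = list(expression_sd = 1, dispersion = 0.1))
  expr <- simulate_expression(model, sv, truth, seed = 9)
  expect_equal(unname(expr$counts["G1", 1]), 0)
  expect_gt(expr$counts["G1", 3], 0)
})

test_that("planted eQTL beta is recovered by OLS within 3 SE", {
  # enough null genes that size factors are untouched by the one effect
  model <- generate_genome_model(n_genes = 50, seed = 2)
  gene <- model$genes$gene_id[25]
  hits <- vapply(1:200, function(s) {
    sv <- simulate_sv_genotypes(model, n_sv = 1,
                                af_spectrum = list(dist = "fixed",
                                                   af = 0.5),
                                n_samples = 42, seed = s,
                                size_range = c(1000, 2000),
                                type_mix = c(DEL = 0, DUP = 0, INV = 1,
                                             INVDEL = 0, INVDUP = 0))
    truth <- sim_truth(effect_table = data.frame(
      variant_id = sv$events$sv_id[1], gene_id = gene, beta = 1),
      noise = list(expression_sd = 1, dispersion = 0))
    expr <- simulate_expression(model, sv, truth, baseline = 500,
                                seed = s + 1000)
    nm <- normalize_expression(expr)
    f <- tryCatch(fit_additive_model(sv$dosage[1, ], nm$values[gene, ]),
                  error = function(e) NULL)
    !is.null(f) && abs(f$beta - 1) < 3 * f$se
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("null generator yields genotype-independent expression", {
  model <- generate_genome_model(n_genes = 50, seed = 2)
  sv <- simulate_sv_genotypes(model, n_sv = 40,
                              af_spectrum = list(dist = "uniform",
                                                 min = 0.1, max = 0.5),
                              n_samples = 42, seed = 3)
  truth <- sim_truth(dosage_model = list(DEL = 1, DUP = 1),
                     noise = list(expression_sd = 0.5,
                                  dispersion = 0.05))
  expr <- simulate_expression(model, sv, truth, seed = 4)
  rec <- run_eqtl(sv, normalize_expression(filter_low_expression(expr)),
                  pairs = NULL)
  frac <- mean(rec$p <= 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(rec))
  expect_lt(abs(frac - 0.05), 4 * se)
})

test_that("methylation intensities track copy number exactly when noiseless", {
  model <- tiny_model()
  dosage <- matrix(c(1L, 2L, 0L, 0L), 1, 4)
  sv <- make_sv_set(sv_event_row(start = 0, end = 500000), dosage)
  truth <- sim_truth(intensity_effect = 0.5,
                     noise = list(intensity_sd = 0))
  my <- simulate_methylation_intensities(model, sv, probe_density = 0.05,
                                         truth = truth,
                                         tissue_labels = "heart",
                                         baseline = 1000, seed = 13)
  tot <- my$meth + my$unmeth
  inside <- my$probes$pos >= 0 & my$probes$pos < 500000
  expect_true(any(inside) && any(!inside))
  expect_equal(unname(tot[inside, 1]),
               rep(750, sum(inside)))                 # het DEL carrier
  expect_equal(unname(tot[inside, 2]), rep(500, sum(inside)))  # hom
  expect_equal(unname(tot[inside, 3]), rep(1000, sum(inside))) # wt
  expect_equal(unname(tot[!inside, ]),
               matrix(1000, sum(!inside), 4))         # copy-neutral
  expect_identical(my, simulate_methylation_intensities(
    model, sv, probe_density = 0.05, truth = truth,
    tissue_labels = "heart", baseline = 1000, seed = 13))
})
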