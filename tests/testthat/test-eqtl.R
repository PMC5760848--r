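# Expression preprocessing, cis pairing, the OLS engine, BH-FDR and the
# SV-vs-SNV comparison.

test_that("low-expression filter applies the mean and detection rules", {
  counts <- rbind(low_mean = c(0, 0, 0, 3),     # mean 0.75 <= 1
                  low_det = c(5, 0, 0, 0),      # detected in 25% < 50%
                  kept = c(2, 2, 2, 2))
  expr <- make_expr(counts)
  out <- filter_low_expression(expr)
  expect_equal(out$genes$gene_id, "kept")
})

test_that("median-of-ratios normalization matches its contracts and DESeq2", {
  counts <- matrix(rpois(200, 50) + 1, 20, 10)
  expr <- make_expr(counts)

  same <- make_expr(matrix(rep(counts[, 1], 10), 20, 10))
  expect_equal(normalize_expression(same)$size_factors,
               setNames(rep(1, 10), colnames(same$counts)))

  # size factors are defined up to a common scale: doubling a column
  # doubles its factor relative to every other sample
  doubled <- counts; doubled[, 3] <- counts[, 3] * 2
  nrm <- normalize_expression(make_expr(doubled))
  base <- normalize_expression(expr)
  expect_equal(unname((nrm$size_factors[3] / nrm$size_factors[1]) /
                        (base$size_factors[3] / base$size_factors[1])),
               2)

  # cross-check against the reference implementation in DESeq2
  expect_equal(unname(base$size_factors),
               unname(DESeq2::estimateSizeFactorsForMatrix(counts)),
               tolerance = 1e-10)

  # zero count maps to zero normalized value
  with_zero <- counts; with_zero[1, 1] <- 0
  expect_equal(unname(normalize_expression(
    make_expr(with_zero))$values[1, 1]), 0)

  zero_sample <- counts; zero_sample[, 2] <- 0
  expect_error(normalize_expression(make_expr(zero_sample)), "S002")
})

test_that("cis pairing uses span-gene gaps, overlap classes and HLA exclusion", {
  spans <- data.frame(variant_id = "SV1", chrom = "chr1",
                      start = 450000, end = 460000,
                      ld_start = 430000, ld_end = 500000,
                      final_start = 400000, final_end = 600000)
  genes <- data.frame(
    gene_id = c("G_far", "G_direct", "G_ld", "G_window", "G_out"),
    chrom = "chr1",
    start = c(1.50e6, 455000, 470000, 700000, 1.75e6),
    end = c(1.52e6, 458000, 480000, 710000, 1.80e6))
  pr <- cis_pairs(spans, genes, window = 1e6)
  expect_setequal(pr$gene_id, c("G_far", "G_direct", "G_ld",
                                "G_window"))
  expect_equal(pr$distance[pr$gene_id == "G_far"], 900000)
  expect_equal(pr$overlap_class[pr$gene_id == "G_direct"],
               "direct_overlap")
  expect_equal(pr$overlap_class[pr$gene_id == "G_ld"], "ld_overlap")
  expect_equal(pr$overlap_class[pr$gene_id == "G_window"],
               "within_1Mb")

  # genes inside the excluded region produce no pair
  pr2 <- cis_pairs(spans, genes, window = 1e6,
                   hla_region = list(chrom = "chr1", start = 1.4e6,
                                     end = 1.6e6))
  expect_false("G_far" %in% pr2$gene_id)
  expect_true("G_direct" %in% pr2$gene_id)
})

test_that("the additive model fits an exact line and matches the normal equations", {
  f <- fit_additive_model(c(0, 1, 2), c(1, 3, 5))
  expect_equal(f$beta, 2)
  expect_equal(f$se, 0)

  set.seed(77)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    d <- stats::rbinom(n, 2, runif(1, 0.2, 0.8))
    if (stats::var(d) == 0) next
    y <- stats::rnorm(n, d * runif(1, -1, 1))
    f <- fit_additive_model(d, y)
    X <- cbind(1, d)
    bh <- solve(crossprod(X), crossprod(X, y))
    r <- y - X %*% bh
    s2 <- sum(r^2) / (n - 2)
    seo <- sqrt(s2 * solve(crossprod(X))[2, 2])
    expect_equal(f$beta, bh[2], tolerance = 1e-10)
    expect_equal(f$se, seo, tolerance = 1e-10)
    expect_equal(f$p, 2 * stats::pt(-abs(bh[2] / seo), n - 2),
                 tolerance = 1e-10)

    # with a covariate, against lm() as an independent reference
    z <- stats::rnorm(n)
    fc <- fit_additive_model(d, y, covariates = cbind(z = z))
    lmf <- summary(stats::lm(y ~ d + z))$coefficients
    expect_equal(fc$beta, lmf["d", "Estimate"], tolerance = 1e-10)
    expect_equal(fc$se, lmf["d", "Std. Error"], tolerance = 1e-10)
    expect_equal(fc$p, lmf["d", "Pr(>|t|)"], tolerance = 1e-10)
  }

  expect_error(fit_additive_model(c(1, 1, 1, 1), rnorm(4)),
               "monomorphic")
  expect_error(fit_additive_model(c(0, 1), c(1, 2)), "too few")
})

test_that("the vectorized scan equals the per-pair fit, incl. missing dosages", {
  set.seed(88)
  n <- 30
  D <- matrix(stats::rbinom(20 * n, 2, 0.4), 20, n)
  D[sample(length(D), 25)] <- NA
  E <- matrix(stats::rnorm(15 * n), 15, n)
  rownames(D) <- sprintf("V%02d", 1:20)
  rownames(E) <- sprintf("G%02d", 1:15)
  colnames(D) <- colnames(E) <- sprintf("S%03d", 1:n)
  vi <- rep(1:20, each = 15); gi <- rep(1:15, 20)
  scan <- svqtl:::ols_scan(D, E, vi, gi, chunk = 37L)
  for (k in sample(length(vi), 60)) {
    ref <- tryCatch(fit_additive_model(D[vi[k], ], E[gi[k], ]),
                    error = function(e) NULL)
    if (is.null(ref)) {
      expect_true(is.na(scan$p[k]))
    } else {
      expect_equal(scan$beta[k], ref$beta, tolerance = 1e-10)
      expect_equal(scan$se[k], ref$se, tolerance = 1e-10)
      expect_equal(scan$p[k], ref$p, tolerance = 1e-10)
      expect_equal(scan$n[k], ref$n)
    }
  }
})

test_that("BH q-values reproduce the step-up arithmetic and oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(1), 1)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      js <- which(p[o] >= p[o][i])
      q[o[i]] <- min(1, min((m / js) * p[o][js]))
    }
    q
  }
  set.seed(99)
  for (i in 1:200) {
    p <- stats::runif(sample(1:25, 1))^sample(1:3, 1)
    expect_identical(bh_fdr(p), bh_oracle(p))
  }
})

test_that("run_eqtl wires pairs, q-values and flags; m=1 keeps q=p", {
  d <- c(0, 0, 1, 1, 2, 2, 0, 1)
  y <- d + stats::rnorm(8, sd = 0.4)
  gm <- make_snvs(pos = 100, dosage_rows = list(d), ids = "V1")
  E <- matrix(y, 1, 8,
              dimnames = list("G1", colnames(gm$dosage)))
  expr <- make_expr(E)
  expr$values <- E
  pairs <- data.frame(variant_id = "V1", gene_id = "G1",
                      distance = 0, overlap_class = "direct_overlap")
  rec <- run_eqtl(gm, expr, pairs)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$q, rec$p)
  expect_true(rec$cis)

  # monomorphic variants are skipped and logged
  gm2 <- make_snvs(pos = c(100, 200),
                   dosage_rows = list(d, rep(1, 8)),
                   ids = c("V1", "V2"))
  pairs2 <- rbind(pairs,
                  data.frame(variant_id = "V2", gene_id = "G1",
                             distance = 0,
                             overlap_class = "direct_overlap"))
  rec2 <- run_eqtl(gm2, expr, pairs2)
  expect_equal(nrow(rec2), 1)
  expect_equal(attr(rec2, "skipped")$variant_id, "V2")
})

test_that("sample-order permutation leaves eQTL records unchanged", {
  co <- simulate_cohort(n_samples = 24, n_genes = 40, n_sv = 20,
                        n_snv = 30, seed = 23)
  expr <- normalize_expression(filter_low_expression(co$expr))
  rec <- run_eqtl(co$sv, expr, pairs = NULL)
  perm <- sample(colnames(co$sv$dosage))
  sv2 <- co$sv; sv2$dosage <- sv2$dosage[, perm]
  expr2 <- expr
  expr2$counts <- expr2$counts[, perm]
  expr2$values <- expr2$values[, perm]
  rec2 <- run_eqtl(sv2, expr2, pairs = NULL)
  expect_equal(rec$beta, rec2$beta)
  expect_equal(rec$p, rec2$p)
  expect_equal(rec$q, rec2$q)
})

test_that("SV-vs-SNV comparison handles empty and perfectly tagged runs", {
  sv_rec <- data.frame(variant_id = "SV1", gene_id = "G1", beta = 1,
                       se = 0.1, t = 10, p = 1e-6, q = 1e-5, n = 40,
                       distance = 0, cis = TRUE,
                       overlap_class = "direct_overlap",
                       significant = TRUE)
  empty <- svqtl:::empty_eqtl_result()
  cmp <- compare_sv_snv(sv_rec, empty, alpha = 0.05)
  expect_equal(cmp$sv_only_fraction, 1)

  snv_rec <- sv_rec; snv_rec$variant_id <- "SNV1"
  cmp2 <- compare_sv_snv(sv_rec, snv_rec, alpha = 0.05)
  expect_equal(cmp2$sv_only_fraction, 0)
  expect_equal(cmp2$sign_agreement, 1)

  # perfect tagging: an R2 = 1 SNV reproduces the SV association
  co <- simulate_cohort(n_samples = 40, n_genes = 60, n_sv = 25,
                        n_snv = 50, n_eqtl = 8, beta = 1.5,
                        n_ld_tags = 25, tag_r2 = 1, seed = 31)
  expr <- normalize_expression(filter_low_expression(co$expr))
  sv_run <- run_eqtl(co$sv, expr, pairs = NULL)
  snv_run <- run_eqtl(co$snvs, expr, pairs = NULL)
  cmp3 <- compare_sv_snv(sv_run, snv_run, alpha = 0.05)
  if (cmp3$n_sv_eqtls > 0) {
    expect_lte(cmp3$sv_only_fraction, 0.3)
    shared <- cmp3$per_gene
    if (nrow(shared) >= 2)
      expect_gt(cmp3$sign_agreement, 0.9)
  }
})
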