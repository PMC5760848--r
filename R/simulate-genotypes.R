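#' Simulate structural-variant genotypes for a diploid cohort
#'
#' Places `n_sv` structural variants on the genome model, samples an
#' allele frequency per variant from `af_spectrum`, draws genotype dosages
#' under Hardy-Weinberg equilibrium, and attaches per-sample normalized
#' read-depth ratios: the expected ratio is 1 minus 0.5 per deleted copy
#' and 1 plus 0.5 per duplicated copy (so a heterozygous deletion carrier
#' sits at 0.5, a heterozygous duplication at 1.5), perturbed by normal
#' noise truncated at zero.  Inversions are copy-neutral (ratio 1).
#' Breakpoint-support flags default to `TRUE` on both ends.
#'
#' @param model a [generate_genome_model()] result.
#' @param n_sv number of variants.
#' @param af_spectrum list describing the allele-frequency distribution:
#'   `list(dist = "beta", shape1, shape2)` (default, skewed toward rare),
#'   `list(dist = "uniform", min, max)` or `list(dist = "fixed", af)`.
#' @param size_range SV length range in bp.
#' @param type_mix named proportions over DEL, DUP, INV, INVDEL, INVDUP
#'   (must sum to 1).
#' @param n_samples cohort size.
#' @param depth_noise_sd SD of the read-depth-ratio noise (0 = noiseless).
#' @param seed integer seed.
#'
#' @return an object of class `sv_set`: list with `events` (data frame:
#'   sv_id, chrom, start, end, sv_type, af, bp_up, bp_down), `dosage`
#'   (variants x samples integer matrix, NA = missing) and `depth_ratio`
#'   (same shape, numeric).
#' @export
simulate_sv_genotypes <- function(model, n_sv = 100L,
                                  af_spectrum = list(dist = "beta",
                                                     shape1 = 0.4,
                                                     shape2 = 2),
                                  size_range = c(1e3, 1e5),
                                  type_mix = c(DEL = 0.76, DUP = 0.20,
                                               INV = 0.03, INVDEL = 0.005,
                                               INVDUP = 0.005),
                                  n_samples = 50L,
                                  depth_noise_sd = 0.05,
                                  seed = 1L) {
  stopifnot(inherits(model, "genome_model"), n_sv >= 1, n_samples >= 1)
  if (abs(sum(type_mix) - 1) > 1e-8) stop("type_mix must sum to 1")
  if (size_range[2] > min(model$chromosomes$length))
    stop("size_range exceeds chromosome length")
  capacity <- sum(model$chromosomes$length) %/% max(1, size_range[1])
  if (n_sv > capacity)
    stop("placement error: n_sv exceeds placeable capacity (", capacity, ")")

  with_seed(seed, {
    samples <- sprintf("S%03d", seq_len(n_samples))
    ci <- sample.int(nrow(model$chromosomes), n_sv, replace = TRUE,
                     prob = model$chromosomes$length)
    len <- round(stats::runif(n_sv, size_range[1], size_range[2]))
    start <- vapply(seq_len(n_sv), function(i)
      sample.int(model$chromosomes$length[ci[i]] - len[i], 1L), numeric(1))
    sv_type <- sample(names(type_mix), n_sv, replace = TRUE,
                      prob = type_mix)
    af <- switch(af_spectrum$dist,
                 beta = stats::rbeta(n_sv, af_spectrum$shape1,
                                     af_spectrum$shape2),
                 uniform = stats::runif(n_sv, af_spectrum$min,
                                        af_spectrum$max),
                 fixed = rep(af_spectrum$af, n_sv),
                 stop("unknown af_spectrum dist: ", af_spectrum$dist))

    dosage <- matrix(stats::rbinom(n_sv * n_samples, 2L,
                                   rep(af, each = n_samples)),
                     nrow = n_sv, ncol = n_samples, byrow = TRUE)

    # signed copy change per dosage unit: -1 deleted, +1 duplicated, 0 INV
    shift <- c(DEL = -1, DUP = 1, INV = 0, INVDEL = -1, INVDUP = 1)[sv_type]
    expected <- 1 + 0.5 * shift * dosage
    noise <- if (depth_noise_sd > 0)
      matrix(stats::rnorm(n_sv * n_samples, 0, depth_noise_sd),
             nrow = n_sv) else 0
    depth_ratio <- pmax(expected + noise, 0)  # matrix first: keep dims

    events <- data.frame(sv_id = sprintf("SV%04d", seq_len(n_sv)),
                         chrom = model$chromosomes$name[ci],
                         start = start, end = start + len,
                         sv_type = sv_type, af = af,
                         bp_up = TRUE, bp_down = TRUE,
                         stringsAsFactors = FALSE)
    o <- order(match(events$chrom, model$chromosomes$name), events$start)
    events <- events[o, ]; rownames(events) <- NULL
    dosage <- dosage[o, , drop = FALSE]
    depth_ratio <- depth_ratio[o, , drop = FALSE]
    dimnames(dosage) <- list(events$sv_id, samples)
    dimnames(depth_ratio) <- list(events$sv_id, samples)
    new_sv_set(events, dosage, depth_ratio)
  })
}

new_sv_set <- function(events, dosage, depth_ratio = NULL) {
  check_interval_df(events, "SV")
  stopifnot(nrow(events) == nrow(dosage))
  structure(list(events = events, dosage = dosage,
                 depth_ratio = depth_ratio),
            class = "sv_set")
}

#' @export
print.sv_set <- function(x, ...) {
  cat("sv_set:", nrow(x$events), "SVs x", ncol(x$dosage), "samples (",
      paste(names(table(x$events$sv_type)),
            table(x$events$sv_type), collapse = ", "), ")\n")
  invisible(x)
}

#' View an sv_set (or build from parts) as a plain genotype matrix
#'
#' @param x an `sv_set`, or a variant data frame (`variant_id`, `chrom`,
#'   `start`, `end`).
#' @param dosage dosage matrix when `x` is a data frame.
#' @return a `genotype_matrix`: list(variants, dosage).
#' @export
as_genotype_matrix <- function(x, dosage = NULL) {
  if (inherits(x, "sv_set")) {
    variants <- data.frame(variant_id = x$events$sv_id,
                           chrom = x$events$chrom,
                           start = x$events$start, end = x$events$end,
                           stringsAsFactors = FALSE)
    return(new_genotype_matrix(variants, x$dosage))
  }
  new_genotype_matrix(x, dosage)
}

new_genotype_matrix <- function(variants, dosage) {
  stopifnot(all(c("variant_id", "chrom", "start", "end") %in%
                  names(variants)),
            nrow(variants) == nrow(dosage))
  rownames(dosage) <- variants$variant_id
  structure(list(variants = variants, dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$variants), "variants x",
      ncol(x$dosage), "samples\n")
  invisible(x)
}

#' Simulate SNV genotypes, with tagging SNVs in controlled LD with SVs
#'
#' For each row of `ld_targets` a SNV is synthesized whose dosage has
#' expected squared correlation `r2` with the named SV: the SV's dosage is
#' split into two haplotypes, copied, and haplotype alleles are flipped
#' with frequency-balanced probabilities (carrier to non-carrier with
#' probability `(1 - sqrt(r2)) * (1 - p)`, the reverse with
#' `(1 - sqrt(r2)) * p`), which leaves the allele frequency `p` unchanged
#' and gives correlation `sqrt(r2)` exactly in expectation.  `r2 = 1`
#' therefore copies the dosage vector; `r2 = 0` gives an independent SNV.
#' Background SNVs are drawn independently of all SVs under
#' Hardy-Weinberg.
#'
#' A target on a monomorphic SV is unreachable; a warning is recorded in
#' the returned `ld_log` attribute and an independent SNV is emitted.
#'
#' @param model a `genome_model`.
#' @param sv an `sv_set` (provides dosages, positions, sample ids).
#' @param ld_targets data frame `sv_id`, `snv_id`, `r2`, optional `pos`
#'   (0-based; defaults to a uniform draw within `placement_window` of the
#'   SV midpoint).
#' @param n_background_snvs independent SNVs to scatter over the genome.
#' @param background_af_range allele-frequency range for background SNVs.
#' @param placement_window bp window around the SV for unplaced targets.
#' @param seed integer seed.
#'
#' @return a `genotype_matrix` sorted by position, with attribute
#'   `ld_log`: data frame (sv_id, snv_id, target_r2, achievable, note).
#' @export
simulate_snv_genotypes_with_ld <- function(model, sv,
                                           ld_targets = NULL,
                                           n_background_snvs = 200L,
                                           background_af_range = c(0.05, 0.5),
                                           placement_window = 2.5e5,
                                           seed = 1L) {
  stopifnot(inherits(model, "genome_model"), inherits(sv, "sv_set"))
  ld_targets <- ld_targets %||%
    data.frame(sv_id = character(), snv_id = character(), r2 = numeric())
  missing_sv <- setdiff(ld_targets$sv_id, sv$events$sv_id)
  if (length(missing_sv))
    stop("ld_targets reference unknown SVs: ",
         paste(missing_sv, collapse = ", "))

  with_seed(seed, {
    samples <- colnames(sv$dosage)
    n <- length(samples)
    rows <- list(); dmat <- list(); log <- list()

    for (k in seq_len(nrow(ld_targets))) {
      tg <- ld_targets[k, ]
      ev <- sv$events[sv$events$sv_id == tg$sv_id, ]
      d <- sv$dosage[tg$sv_id, ]
      p <- mean(d, na.rm = TRUE) / 2
      note <- ""; achievable <- TRUE
      if (is.na(p) || p <= 0 || p >= 1) {
        achievable <- FALSE
        note <- "monomorphic SV; target R2 unreachable, independent SNV used"
        warning("ld target ", tg$snv_id, ": ", note)
        g <- stats::rbinom(n, 2L, 0.2)
      } else {
        h1 <- as.integer(d == 2) + as.integer(d == 1) *
          stats::rbinom(n, 1L, 0.5)
        h2 <- d - h1
        c_ <- 1 - sqrt(tg$r2)
        flip_hap <- function(h) {
          u <- stats::runif(n)
          ifelse(h == 1L, ifelse(u < c_ * (1 - p), 0L, 1L),
                 ifelse(u < c_ * p, 1L, 0L))
        }
        g <- flip_hap(h1) + flip_hap(h2)
      }
      pos <- if (!is.null(tg$pos) && !is.na(tg$pos)) tg$pos else {
        mid <- floor((ev$start + ev$end) / 2)
        cl <- model$chromosomes$length[model$chromosomes$name == ev$chrom]
        max(0, min(cl - 1, mid + round(stats::runif(1, -placement_window,
                                                    placement_window))))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(variant_id = tg$snv_id, chrom = ev$chrom,
                   start = pos, end = pos + 1, stringsAsFactors = FALSE)
      dmat[[length(dmat) + 1L]] <- g
      log[[length(log) + 1L]] <-
        data.frame(sv_id = tg$sv_id, snv_id = tg$snv_id, target_r2 = tg$r2,
                   achievable = achievable, note = note,
                   stringsAsFactors = FALSE)
    }

    if (n_background_snvs > 0) {
      ci <- sample.int(nrow(model$chromosomes), n_background_snvs,
                       replace = TRUE, prob = model$chromosomes$length)
      pos <- vapply(ci, function(i)
        sample.int(model$chromosomes$length[i], 1L) - 1, numeric(1))
      af <- stats::runif(n_background_snvs, background_af_range[1],
                         background_af_range[2])
      for (k in seq_len(n_background_snvs)) {
        rows[[length(rows) + 1L]] <-
          data.frame(variant_id = sprintf("SNVbg%05d", k),
                     chrom = model$chromosomes$name[ci[k]],
                     start = pos[k], end = pos[k] + 1,
                     stringsAsFactors = FALSE)
        dmat[[length(dmat) + 1L]] <- stats::rbinom(n, 2L, af[k])
      }
    }

    variants <- do.call(rbind, rows)
    dosage <- do.call(rbind, dmat)
    colnames(dosage) <- samples
    o <- order(match(variants$chrom, model$chromosomes$name),
               variants$start)
    gm <- new_genotype_matrix(variants[o, , drop = FALSE],
                              dosage[o, , drop = FALSE])
    attr(gm, "ld_log") <- if (length(log)) do.call(rbind, log) else
      data.frame(sv_id = character(), snv_id = character(),
                 target_r2 = numeric(), achievable = logical(),
                 note = character())
    gm
  })
}
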