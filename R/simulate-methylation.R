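#' Simulate methylation-array raw intensities tracking copy number
#'
#' Probes are scattered over the genome at `probe_density` probes per kb.
#' The total (methylated + unmethylated) intensity of a probe in a sample
#' is proportional to the local copy number: for a probe inside a
#' copy-altering SV carried at dosage `d`, the mean is
#' `baseline * (2 + s * d * intensity_effect) / 2` with `s = -1` for
#' deletions and `+1` for duplications, so with `intensity_effect = 0.5`
#' a heterozygous deletion carrier averages 75% of the diploid mean.
#' Noise is multiplicative log-normal (`sdlog = truth$noise$intensity_sd`)
#' and tissue enters as an additive offset on the log scale.  The total is
#' split into the two channels at a probe-specific methylation fraction.
#'
#' @param model a `genome_model`.
#' @param sv an `sv_set`.
#' @param probe_density probes per kb (> 0).
#' @param truth a [sim_truth()]; uses `intensity_effect` and
#'   `noise$intensity_sd`.
#' @param tissue_labels character vector, one label per sample (recycled).
#' @param tissue_offsets named numeric log-scale offsets per label
#'   (default 0 for the first label, 0.2 for the others).
#' @param baseline diploid mean total intensity in fluorescence units.
#' @param seed integer seed.
#'
#' @return a `methyl_set`: list(`probes` data frame (probe_id, chrom,
#'   pos), `meth` and `unmeth` probe x sample matrices, `tissue` vector).
#' @export
simulate_methylation_intensities <- function(model, sv,
                                             probe_density = 0.02,
                                             truth = sim_truth(),
                                             tissue_labels = "heart",
                                             tissue_offsets = NULL,
                                             baseline = 1000,
                                             seed = 1L) {
  stopifnot(inherits(model, "genome_model"), inherits(sv, "sv_set"),
            probe_density > 0)
  samples <- colnames(sv$dosage)
  n_s <- length(samples)
  tissue <- rep_len(tissue_labels, n_s)
  labs <- unique(tissue)
  if (is.null(tissue_offsets))
    tissue_offsets <- stats::setNames(c(0, rep(0.2, length(labs) - 1)),
                                      labs)

  with_seed(seed, {
    probes <- list()
    for (ci in seq_len(nrow(model$chromosomes))) {
      n_p <- max(1L, round(probe_density *
                             model$chromosomes$length[ci] / 1000))
      pos <- sort(sample.int(model$chromosomes$length[ci], n_p)) - 1
      probes[[ci]] <- data.frame(chrom = model$chromosomes$name[ci],
                                 pos = pos, stringsAsFactors = FALSE)
    }
    probes <- do.call(rbind, probes)
    probes <- cbind(probe_id = sprintf("cg%06d", seq_len(nrow(probes))),
                    probes)
    n_p <- nrow(probes)

    # signed copy shift per probe x sample from containing SVs
    shift_of <- c(DEL = -1, DUP = 1, INV = 0, INVDEL = -1, INVDUP = 1)
    copy_shift <- matrix(0, n_p, n_s,
                         dimnames = list(probes$probe_id, samples))
    p_gr <- gr_from_points(probes$chrom, probes$pos)
    sv_gr <- gr_from_intervals(sv$events$chrom, sv$events$start,
                               sv$events$end)
    hits <- GenomicRanges::findOverlaps(p_gr, sv_gr)
    for (h in seq_along(hits)) {
      pi <- S4Vectors::queryHits(hits)[h]
      si <- S4Vectors::subjectHits(hits)[h]
      s_ <- shift_of[[sv$events$sv_type[si]]]
      if (s_ == 0) next
      d <- sv$dosage[si, ]; d[is.na(d)] <- 0
      copy_shift[pi, ] <- copy_shift[pi, ] + s_ * d
    }

    cn <- pmax(2 + copy_shift * truth$intensity_effect, 0)
    toff <- tissue_offsets[tissue]
    mean_total <- baseline * (cn / 2) *
      matrix(exp(toff), n_p, n_s, byrow = TRUE)
    sdl <- truth$noise$intensity_sd
    noise <- if (sdl > 0)
      matrix(stats::rlnorm(n_p * n_s, -sdl^2 / 2, sdl), n_p, n_s) else 1
    total <- mean_total * noise
    mfrac <- stats::runif(n_p, 0.2, 0.8)
    meth <- total * mfrac
    unmeth <- total - meth
    dimnames(meth) <- dimnames(unmeth) <- list(probes$probe_id, samples)
    structure(list(probes = probes, meth = meth, unmeth = unmeth,
                   tissue = stats::setNames(tissue, samples)),
              class = "methyl_set")
  })
}

#' @export
print.methyl_set <- function(x, ...) {
  cat("methyl_set:", nrow(x$probes), "probes x", ncol(x$meth),
      "samples; tissues:",
      paste(names(table(x$tissue)), table(x$tissue), collapse = ", "),
      "\n")
  invisible(x)
}
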