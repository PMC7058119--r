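## Baseline (copy-neutral) segment detection ---------------------------------
##
## Copy-neutral segments anchor the ratio scale: the tumor/normal ratio of a
## segment is proportional to cbar/2 only up to the overall sequencing-depth
## ratio of the two libraries, which the baseline scale theta absorbs.
## Detection uses the BAF and depth signatures of cbar = 2 with a diploid
## heterozygous genotype: folded BAF 1/2 and SNP depth equal to the expected
## copy-neutral coverage.  Balanced aberrations (e.g. a PPMM gain, or a
## homozygous deletion diluted by normal cells) also show folded BAF 1/2 but
## fail the depth test.

#' Detect copy-neutral baseline segments
#'
#' Two-step filter.  Step 1 keeps segments whose average BAF is consistent
#' with 1/2.  Because folding the observed BAF biases any naive distance
#' from 0.5, the test uses the unbiased per-locus estimator of
#' `(mu - 1/2)^2`, namely `1/4 - b*(d - b) / (d*(d - 1))`, averaged over
#' the segment's loci; a segment passes when this average is at most
#' `baf_tol^2` plus twice its standard error (the sampling allowance keeps
#' truly balanced segments from failing by noise).  Step 2 keeps, among
#' those, segments whose mean SNP depth is within `depth_tol` (relative) of
#' `coverage`, the expected copy-neutral per-locus tumor depth — this
#' removes balanced aberrations (e.g. homozygous deletions diluted by
#' normal cells, or PPMM-like gains) that also show BAF 1/2.
#'
#' @param segset a [segment_set] with SNPs attached.
#' @param coverage expected per-locus tumor read depth at `cbar = 2`.
#' @param baf_tol tolerance on the absolute deviation of the average BAF
#'   from 1/2 (default 0.03).
#' @param depth_tol relative tolerance on mean SNP depth (default 0.1).
#' @return character vector of baseline segment ids.
#' @export
detect_baseline <- function(segset, coverage, baf_tol = 0.03,
                            depth_tol = 0.1) {
  stopifnot(coverage > 0, baf_tol > 0, depth_tol > 0)
  seg <- segset$segments
  snps <- segset$snps
  keep <- character()
  for (id in seg$id) {
    sn <- snps[snps$segment_id == id, , drop = FALSE]
    sn2 <- sn[sn$depth >= 2, , drop = FALSE]
    if (nrow(sn) == 0) next
    if (nrow(sn2) >= 2) {
      est <- 0.25 - sn2$b_count * (sn2$depth - sn2$b_count) /
        (sn2$depth * (sn2$depth - 1))
      delta2 <- mean(est)
      se <- stats::sd(est) / sqrt(length(est))
      if (delta2 > baf_tol^2 + 2 * se) next
    }
    mean_depth <- mean(sn$depth)
    if (abs(mean_depth - coverage) / coverage > depth_tol) next
    keep <- c(keep, id)
  }
  if (length(keep) == 0) {
    stop("no baseline segment detected; designate baseline segments manually")
  }
  keep
}

#' Baseline ratio scale theta
#'
#' The geometric mean of the corrected tumor/normal ratios of the baseline
#' segments.  Invariant to their order; scales linearly with a common factor
#' applied to all ratios.
#'
#' @param segset a [segment_set] with `corrected_ratio` set.
#' @param baseline_ids ids of the baseline segments (non-empty).
#' @return positive scalar theta.
#' @export
compute_theta <- function(segset, baseline_ids) {
  if (length(baseline_ids) == 0) stop("empty baseline")
  r <- segset$segments$corrected_ratio[match(baseline_ids, segset$segments$id)]
  if (anyNA(r)) stop("corrected_ratio unset for a baseline segment")
  exp(mean(log(r)))
}

#' Mark the baseline of a segment set
#'
#' Runs [detect_baseline()] and [compute_theta()] and stores the results in
#' the set's `baseline_ids` and `theta` fields.
#'
#' @inheritParams detect_baseline
#' @return the updated [segment_set].
#' @export
set_baseline <- function(segset, coverage, baf_tol = 0.03, depth_tol = 0.1) {
  ids <- detect_baseline(segset, coverage, baf_tol, depth_tol)
  segset$baseline_ids <- ids
  segset$theta <- compute_theta(segset, ids)
  segset
}
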