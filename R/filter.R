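## False-breakpoint filter ----------------------------------------------------
##
## Over-sensitive segmentation splits true SCNAs into fragments.  Fragments
## of one SCNA share the same average copy number and the same folded BAF, so
## the filter (i) clusters segments on log corrected ratio (aggregation),
## (ii) splits each ratio cluster by the BAF modes of its pooled SNPs
## (decomposition), and (iii) merges adjacent fragments that landed in the
## same (ratio, BAF) cell.  Fragments of different SCNAs differ in at least
## one of the two observables and are never merged.

#' Breakpoint-filter configuration
#'
#' @param c_max maximum absolute copy number (default 15).
#' @param tau assumed number of subclonal populations (>= 1); the aggregation
#'   step opens at most `c_max * tau` ratio clusters.
#' @param rho maximum gap in bp between two adjacent fragments for merging
#'   (default 1: only book-ended fragments merge).
#' @param bandwidth mean-shift kernel bandwidth on folded BAF, or `NULL` for
#'   the Silverman rule on the pooled values, floored at half the median
#'   per-locus binomial noise (a narrower kernel would resolve sampling
#'   noise, not genotype structure).
#' @param z_cut aggregation cut in noise units: two segments join a ratio
#'   cluster while their log-ratio difference is below `z_cut` pooled
#'   standard errors (default 4).
#' @param min_baf_snps segments with fewer SNPs than this are treated as
#'   BAF-untyped in the decomposition step (default 3).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(c_max = 15, tau = 6, rho = 1, bandwidth = NULL,
                          z_cut = 4, min_baf_snps = 3) {
  stopifnot(c_max >= 1, tau >= 1, rho >= 0,
            is.null(bandwidth) || bandwidth > 0, z_cut > 0, min_baf_snps >= 1)
  structure(list(c_max = c_max, tau = tau, rho = rho, bandwidth = bandwidth,
                 z_cut = z_cut, min_baf_snps = min_baf_snps),
            class = "filter_config")
}

#' Cluster segments on log corrected read-count ratio
#'
#' Agglomerative (average-linkage) clustering of the scalar
#' `log(corrected_ratio)`, measured in noise units: the distance between
#' segments `i` and `j` is their log-ratio difference divided by the pooled
#' counting standard error `sqrt(1/D_i^S + 1/D_i^N + 1/D_j^S + 1/D_j^N)`.
#' The dendrogram is cut at `z_cut` (default 4), so fragments whose ratios
#' differ by no more than noise stay together regardless of their size,
#' while states separated beyond noise split apart.  The cluster count is
#' capped at `c_max * tau`; degenerate inputs (all ratios equal) give one
#' cluster.
#'
#' @param segset a [segment_set] with `corrected_ratio` set on all segments.
#' @param config a [filter_config].
#' @return integer vector of cluster labels, one per segment (in
#'   `segset$segments` order).
#' @export
aggregate_segments <- function(segset, config = filter_config()) {
  seg <- segset$segments
  if (anyNA(seg$corrected_ratio)) {
    stop("corrected_ratio unset; run apply_bias_correction() first")
  }
  x <- log(seg$corrected_ratio)
  n <- length(x)
  if (n == 1) return(1L)
  k_max <- min(config$c_max * config$tau, n)
  var_i <- 1 / pmax(seg$tumor_reads, 1) + 1 / seg$normal_reads
  z <- abs(outer(x, x, "-")) / sqrt(outer(var_i, var_i, "+"))
  hc <- stats::hclust(stats::as.dist(z), method = "average")
  if (max(hc$height) < 1e-12) return(rep(1L, n))
  labels <- stats::cutree(hc, h = config$z_cut)
  if (max(labels) > k_max) labels <- stats::cutree(hc, k = k_max)
  labels
}

#' One-dimensional mean-shift clustering
#'
#' Gaussian-kernel mean shift: every point hill-climbs to a mode of the
#' kernel density estimate and points reaching the same mode (within
#' `bandwidth / 10`) share a label.  Labels are ordered by mode position.
#'
#' @param x numeric vector.
#' @param bandwidth kernel bandwidth; `NULL` for `stats::bw.nrd0(x)`.
#' @param max_iter,tol iteration controls.
#' @return list with `labels` (integer per point) and `modes` (numeric per
#'   cluster).
#' @export
mean_shift_1d <- function(x, bandwidth = NULL, max_iter = 200, tol = 1e-7) {
  n <- length(x)
  if (n == 0) return(list(labels = integer(), modes = numeric()))
  if (is.null(bandwidth)) {
    bandwidth <- tryCatch(stats::bw.nrd0(x), error = function(e) 0)
  }
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    return(list(labels = rep(1L, n), modes = mean(x)))
  }
  y <- x
  for (iter in seq_len(max_iter)) {
    w <- exp(-outer(y, x, "-")^2 / (2 * bandwidth^2))
    y_new <- drop(w %*% x) / rowSums(w)
    if (max(abs(y_new - y)) < tol) { y <- y_new; break }
    y <- y_new
  }
  ord <- order(y)
  labels <- integer(n)
  modes <- numeric()
  current <- -Inf
  for (i in ord) {
    if (y[i] - current > bandwidth / 10) {
      modes <- c(modes, y[i])
    } else {
      modes[length(modes)] <- y[i]
    }
    labels[i] <- length(modes)
    current <- y[i]
  }
  list(labels = labels, modes = modes)
}

#' Split a ratio cluster by the BAF modes of its SNPs
#'
#' Mean-shift on the pooled folded BAFs of all SNPs of the cluster's
#' segments; each segment takes the label occurring most often among its own
#' SNPs (ties toward the lowest label).  Segments with fewer than
#' `min_baf_snps` loci cannot be BAF-typed reliably and are collected in a
#' shared untyped subcluster (label 0).
#'
#' @param segset a [segment_set].
#' @param ids ids of the segments forming one ratio cluster.
#' @param config a [filter_config].
#' @return named integer vector: BAF subcluster label per segment id.
#' @export
decompose_cluster <- function(segset, ids, config = filter_config()) {
  snps <- segset$snps[segset$snps$segment_id %in% ids, , drop = FALSE]
  out <- stats::setNames(rep(0L, length(ids)), ids)
  if (nrow(snps) == 0) return(out)
  baf <- folded_baf(snps$b_count, snps$depth)
  bw <- config$bandwidth
  if (is.null(bw)) {
    noise_floor <- 0.5 * stats::median(sqrt(0.25 / snps$depth))
    bw <- max(stats::bw.nrd0(baf), noise_floor, 1e-6)
  }
  ms <- mean_shift_1d(baf, bandwidth = bw)
  n_snp <- table(snps$segment_id)
  for (id in unique(snps$segment_id)) {
    if (n_snp[[id]] < config$min_baf_snps) next
    lab <- ms$labels[snps$segment_id == id]
    counts <- tabulate(lab)
    out[id] <- which.max(counts)  # first max: lowest label wins ties
  }
  out
}

#' Merge adjacent fragments of one (ratio, BAF) cell
#'
#' Transitively merges same-chromosome neighbors whose gap
#' (`next start - previous end`) is smaller than `rho`.  A merged segment
#' spans the union interval, sums the read counts, concatenates the SNPs and
#' takes the length-weighted mean GC; its corrected ratio is recomputed from
#' the summed counts through the bias model.
#'
#' @param segset a [segment_set].
#' @param ids ids of the segments in one subcluster.
#' @param rho maximum merge gap in bp.
#' @param bias a [bias_model] used to recompute corrected ratios.
#' @return list with `segments` (merged rows), `snps`, and `provenance`
#'   (data.frame `child`, `merged`).
#' @keywords internal
merge_adjacent_ids <- function(segset, ids, rho, bias = bias_model()) {
  seg <- segset$segments[match(ids, segset$segments$id), , drop = FALSE]
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  n <- nrow(seg)
  group <- integer(n); g <- 1L; group[1] <- g
  if (n > 1) {
    for (i in 2:n) {
      same <- seg$chrom[i] == seg$chrom[i - 1]
      if (same && seg$start[i] < seg$end[i - 1]) stop("overlapping segments")
      if (same && (seg$start[i] - seg$end[i - 1]) < rho) group[i] <- g
      else { g <- g + 1L; group[i] <- g }
    }
  }
  merged <- lapply(split(seq_len(n), group), function(idx) {
    s <- seg[idx, , drop = FALSE]
    len <- s$end - s$start
    data.frame(id = s$id[1], chrom = s$chrom[1],
               start = min(s$start), end = max(s$end),
               tumor_reads = sum(s$tumor_reads),
               normal_reads = sum(s$normal_reads),
               gc = sum(s$gc * len) / sum(len),
               stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, merged)
  ratio <- pmax(merged$tumor_reads, 1) / merged$normal_reads
  merged$corrected_ratio <- bias_correct(bias, ratio, merged$gc)
  merged$baf_cluster <- NA_integer_
  prov <- data.frame(child = seg$id,
                     merged = vapply(group, function(gi) {
                       seg$id[which(group == gi)[1]]
                     }, ""),
                     stringsAsFactors = FALSE)
  snps <- segset$snps[segset$snps$segment_id %in% ids, , drop = FALSE]
  if (nrow(snps) > 0) {
    snps$segment_id <- prov$merged[match(snps$segment_id, prov$child)]
  }
  list(segments = merged, snps = snps, provenance = prov)
}

#' Merge adjacent segments of a subcluster
#'
#' Convenience wrapper over the internal merge used by [run_filter()]:
#' merges the given segments (assumed to belong to one cluster cell) and
#' returns them as a [segment_set].
#'
#' @inheritParams merge_adjacent_ids
#' @return a [segment_set] of the merged segments.
#' @export
merge_adjacent <- function(segset, ids, rho = 1, bias = bias_model()) {
  m <- merge_adjacent_ids(segset, ids, rho, bias)
  out <- segment_set(m$segments, m$snps)
  attr(out, "provenance") <- m$provenance
  out
}

#' Run the false-breakpoint filter
#'
#' Aggregation (ratio clustering), decomposition (BAF subclustering) and
#' adjacent merging, in that order.  Merging never crosses chromosomes,
#' never bridges a gap of `rho` or more, and never joins segments from
#' different ratio clusters or with conflicting BAF labels; a BAF-untyped
#' segment (label 0, too few SNPs to vote) is compatible with either
#' neighbor of its ratio cluster.  Total read counts and SNP loci are
#' conserved.
#'
#' @param segset a bias-corrected [segment_set].
#' @param config a [filter_config].
#' @param bias the [bias_model] used to recompute merged corrected ratios.
#' @return the filtered [segment_set]; attribute `provenance` maps each
#'   input id to the id of the merged segment containing it, and attribute
#'   `clusters` records the (ratio, BAF) cell per input id.
#' @export
run_filter <- function(segset, config = filter_config(), bias = bias_model()) {
  seg <- segset$segments
  ratio_lab <- stats::setNames(aggregate_segments(segset, config), seg$id)
  baf_lab <- stats::setNames(rep(NA_integer_, nrow(seg)), seg$id)
  for (cl in unique(ratio_lab)) {
    ids <- seg$id[ratio_lab[seg$id] == cl]
    baf_lab[ids] <- decompose_cluster(segset, ids, config)
  }
  ord <- order(seg$chrom, seg$start)
  sseg <- seg[ord, , drop = FALSE]
  group <- integer(nrow(sseg))
  g <- 0L
  group_label <- 0L
  for (i in seq_len(nrow(sseg))) {
    id <- sseg$id[i]
    lab <- baf_lab[[id]]
    chain <- i > 1 &&
      sseg$chrom[i] == sseg$chrom[i - 1] &&
      (sseg$start[i] - sseg$end[i - 1]) < config$rho &&
      ratio_lab[[id]] == ratio_lab[[sseg$id[i - 1]]] &&
      (lab == 0L || group_label == 0L || lab == group_label)
    if (!chain) {
      g <- g + 1L
      group_label <- lab
    } else if (group_label == 0L) {
      group_label <- lab
    }
    group[i] <- g
  }
  pieces <- lapply(split(sseg$id, group), function(ids) {
    merge_adjacent_ids(segset, ids, config$rho, bias)
  })
  new_seg <- do.call(rbind, lapply(pieces, `[[`, "segments"))
  new_snp <- do.call(rbind, lapply(pieces, `[[`, "snps"))
  prov <- do.call(rbind, lapply(pieces, `[[`, "provenance"))
  rownames(new_seg) <- rownames(prov) <- NULL
  new_seg <- new_seg[order(new_seg$chrom, new_seg$start), , drop = FALSE]
  if (is.null(new_snp)) new_snp <- empty_snp_table()
  out <- segment_set(new_seg, new_snp)
  attr(out, "provenance") <- prov
  attr(out, "clusters") <- data.frame(id = seg$id,
                                      ratio_cluster = unname(ratio_lab[seg$id]),
                                      baf_cluster = unname(baf_lab[seg$id]),
                                      stringsAsFactors = FALSE)
  out
}
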