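#' @keywords internal
"_PACKAGE"

## Segment container ---------------------------------------------------------

#' Construct a segment set
#'
#' A `segment_set` is the central container of the package: a table of genomic
#' segments (as produced downstream of a read-count segmenter) together with
#' the heterozygous-SNP allele counts that fall inside them.  Segments use
#' 0-based half-open coordinates (BED-like); SNP positions are 1-based (VCF
#' convention), so a SNP at position `pos` belongs to a segment when
#' `start < pos <= end`.
#'
#' @param segments data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `tumor_reads`, `normal_reads`, `gc`.  Optional columns `corrected_ratio`
#'   (tumor/normal read-count ratio after GC-bias correction) and
#'   `baf_cluster` are added as `NA` when absent.
#' @param snps data.frame with columns `segment_id`, `chrom`, `pos`,
#'   `b_count`, `depth`, or `NULL` for none.
#' @param baseline_ids character vector of ids of copy-neutral (baseline)
#'   segments, normally filled in by [detect_baseline()].
#' @param theta baseline read-count-ratio scale (geometric mean of baseline
#'   corrected ratios), normally filled in by [compute_theta()].
#'
#' @return An object of class `segment_set`.
#' @seealso [read_segment_table()], [attach_snps()], [detect_baseline()]
#' @export
segment_set <- function(segments, snps = NULL, baseline_ids = character(),
                        theta = NA_real_) {
  stopifnot(is.data.frame(segments))
  required <- c("id", "chrom", "start", "end", "tumor_reads", "normal_reads", "gc")
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols) > 0) {
    stop("segment table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  segments$id <- as.character(segments$id)
  segments$chrom <- as.character(segments$chrom)
  if (!("corrected_ratio" %in% names(segments))) {
    segments$corrected_ratio <- rep(NA_real_, nrow(segments))
  }
  if (!("baf_cluster" %in% names(segments))) {
    segments$baf_cluster <- rep(NA_integer_, nrow(segments))
  }
  if (is.null(snps)) snps <- empty_snp_table()
  snps$segment_id <- as.character(snps$segment_id)
  obj <- structure(
    list(segments = segments, snps = snps,
         baseline_ids = as.character(baseline_ids), theta = theta),
    class = "segment_set")
  validate_segment_set(obj)
  obj
}

empty_snp_table <- function() {
  data.frame(segment_id = character(), chrom = character(),
             pos = integer(), b_count = integer(), depth = integer(),
             stringsAsFactors = FALSE)
}

#' Validate a segment set
#'
#' Checks the structural invariants: unique ids, `start < end`, non-negative
#' counts, `normal_reads >= 1`, GC in \[0,1\], SNP counts with
#' `0 <= b_count <= depth`, every SNP inside its segment under the
#' half-open convention, and `baseline_ids` a subset of the segment ids.
#'
#' @param x a `segment_set`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_segment_set <- function(x) {
  seg <- x$segments
  if (anyDuplicated(seg$id)) stop("segment ids are not unique")
  bad <- which(!(seg$start < seg$end))
  if (length(bad) > 0) stop("segment row ", bad[1], " (id ", seg$id[bad[1]],
                            ") has start >= end")
  if (any(seg$tumor_reads < 0)) stop("negative tumor read count")
  if (any(seg$normal_reads < 1)) stop("normal read count below 1")
  if (any(seg$gc < 0 | seg$gc > 1)) stop("gc fraction outside [0, 1]")
  if (any(!is.na(seg$corrected_ratio) & seg$corrected_ratio <= 0)) {
    stop("corrected_ratio must be positive when set")
  }
  snp <- x$snps
  if (nrow(snp) > 0) {
    if (any(snp$depth < 1)) stop("SNP locus with depth < 1")
    if (any(snp$b_count < 0 | snp$b_count > snp$depth)) {
      stop("SNP locus with b_count outside [0, depth]")
    }
    idx <- match(snp$segment_id, seg$id)
    if (anyNA(idx)) stop("SNP references unknown segment id ",
                         snp$segment_id[which(is.na(idx))[1]])
    inside <- seg$start[idx] < snp$pos & snp$pos <= seg$end[idx]
    if (any(!inside)) stop("SNP at ", snp$chrom[!inside][1], ":",
                           snp$pos[!inside][1], " lies outside its segment")
  }
  if (!all(x$baseline_ids %in% seg$id)) stop("baseline_ids not a subset of segment ids")
  invisible(x)
}

#' @export
print.segment_set <- function(x, ...) {
  cat("<segment_set> ", nrow(x$segments), " segments, ",
      nrow(x$snps), " SNP loci\n", sep = "")
  if (length(x$baseline_ids) > 0) {
    cat("  baseline: ", length(x$baseline_ids), " segments, theta = ",
        format(x$theta, digits = 6), "\n", sep = "")
  }
  invisible(x)
}

#' Folded B-allele frequency
#'
#' `min(baf, 1 - baf)`: the BAF with the haplotype assignment of the B allele
#' removed, always in \[0, 0.5\].
#'
#' @param b_count reads carrying the B allele.
#' @param depth total reads at the locus.
#' @return numeric vector of folded BAFs.
#' @export
folded_baf <- function(b_count, depth) {
  baf <- b_count / depth
  pmin(baf, 1 - baf)
}

## Readers -------------------------------------------------------------------

#' Read a tab-separated segment table
#'
#' Expects a header with columns `chrom`, `start`, `end`, `tumor_reads`,
#' `normal_reads`, `gc` (extra columns are kept).  Coordinates are taken as
#' 0-based half-open.  Row order is preserved; ids are taken from an `id`
#' column when present, otherwise generated as `chrom:start-end`.
#'
#' @param path path to the TSV file.
#' @return a [segment_set] with no SNPs attached.
#' @export
read_segment_table <- function(path) {
  seg <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("chrom", "start", "end", "tumor_reads", "normal_reads", "gc")
  missing_cols <- setdiff(required, names(seg))
  if (length(missing_cols) > 0) {
    stop("segment table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("start", "end", "tumor_reads", "normal_reads", "gc")) {
    v <- suppressWarnings(as.numeric(seg[[col]]))
    if (nrow(seg) > 0 && anyNA(v)) {
      stop("non-numeric value in column '", col, "' at row ",
           which(is.na(v))[1], " of ", path)
    }
    seg[[col]] <- v
  }
  bad <- which(seg$start >= seg$end)
  if (length(bad) > 0) stop("start >= end at row ", bad[1], " of ", path)
  if (!("id" %in% names(seg))) {
    seg$id <- if (nrow(seg) > 0) {
      paste0(seg$chrom, ":", format(seg$start, scientific = FALSE, trim = TRUE),
             "-", format(seg$end, scientific = FALSE, trim = TRUE))
    } else character()
  }
  segment_set(seg)
}

#' Read tumor allele counts at germline-heterozygous SNPs
#'
#' Two dialects are supported.  `format = "tsv"` expects a header with
#' columns `chrom`, `pos`, `b_count`, `depth`.  `format = "vcf"` reads a VCF
#' 4.x file whose FORMAT carries per-sample allele depths (`AD`); the B
#' allele is the alternate allele, `b_count` the alternate-allele depth and
#' `depth` the sum of the allele depths.  Loci with zero total depth are
#' dropped.
#'
#' @param path input file path.
#' @param format `"tsv"` or `"vcf"`.
#' @param sample for VCF input, the sample name (or index) holding the tumor
#'   allele depths; defaults to the first sample.
#' @return data.frame with columns `chrom`, `pos`, `b_count`, `depth`.
#' @export
read_snp_counts <- function(path, format = c("tsv", "vcf"), sample = 1L) {
  format <- match.arg(format)
  if (format == "tsv") {
    snp <- utils::read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    required <- c("chrom", "pos", "b_count", "depth")
    missing_cols <- setdiff(required, names(snp))
    if (length(missing_cols) > 0) {
      stop("SNP table ", path, " is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    snp <- snp[, required]
  } else {
    snp <- read_snp_vcf(path, sample)
  }
  snp$chrom <- as.character(snp$chrom)
  for (col in c("pos", "b_count", "depth")) {
    v <- suppressWarnings(as.numeric(snp[[col]]))
    if (nrow(snp) > 0 && anyNA(v)) {
      stop("non-numeric value in column '", col, "' of ", path)
    }
    snp[[col]] <- v
  }
  snp <- snp[snp$depth > 0, , drop = FALSE]
  if (any(snp$b_count > snp$depth)) {
    stop("b_count > depth at ", snp$chrom[snp$b_count > snp$depth][1], ":",
         snp$pos[snp$b_count > snp$depth][1])
  }
  rownames(snp) <- NULL
  snp
}

read_snp_vcf <- function(path, sample = 1L) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF input requires the 'vcfR' package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                 error = function(e) NULL)
  if (is.null(ad)) stop("VCF ", path, " has no FORMAT/AD field")
  ad <- ad[, sample, drop = TRUE]
  if (anyNA(ad)) {
    keep <- !is.na(ad)
  } else keep <- rep(TRUE, length(ad))
  split_ad <- strsplit(ad[keep], ",", fixed = TRUE)
  ref_d <- vapply(split_ad, function(x) suppressWarnings(as.numeric(x[1])), 0)
  alt_d <- vapply(split_ad, function(x) {
    suppressWarnings(sum(as.numeric(x[-1])))
  }, 0)
  if (anyNA(ref_d) || anyNA(alt_d)) stop("malformed AD field in ", path)
  data.frame(chrom = vcf@fix[keep, "CHROM"],
             pos = as.numeric(vcf@fix[keep, "POS"]),
             b_count = alt_d, depth = ref_d + alt_d,
             stringsAsFactors = FALSE)
}

#' Attach SNP loci to the segments that contain them
#'
#' Each locus is assigned to the unique segment whose half-open interval
#' contains it (`start < pos <= end`).  Loci falling outside every segment
#' are dropped with a message.  Overlapping segments on the same chromosome
#' are a structural error.
#'
#' @param segset a [segment_set].
#' @param loci data.frame as returned by [read_snp_counts()].
#' @return the segment set with its `snps` table replaced.
#' @export
attach_snps <- function(segset, loci) {
  seg <- segset$segments
  for (chr in unique(seg$chrom)) {
    s <- seg[seg$chrom == chr, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      stop("overlapping segments on ", chr)
    }
  }
  n <- nrow(loci)
  seg_id <- rep(NA_character_, n)
  for (chr in unique(loci$chrom)) {
    li <- which(loci$chrom == chr)
    s <- seg[seg$chrom == chr, , drop = FALSE]
    if (nrow(s) == 0) next
    ord <- order(s$start)
    s <- s[ord, , drop = FALSE]
    # pos in segment i iff start_i < pos <= end_i; intervals are disjoint
    idx <- findInterval(loci$pos[li] - 1, s$start)  # last start <= pos-1
    ok <- idx >= 1
    ok[ok] <- loci$pos[li][ok] <= s$end[idx[ok]]
    seg_id[li[ok]] <- s$id[idx[ok]]
  }
  assigned <- !is.na(seg_id)
  if (any(!assigned)) {
    message(sum(!assigned), " of ", n,
            " SNP loci fall outside every segment and were dropped")
  }
  snps <- data.frame(segment_id = seg_id[assigned],
                     chrom = loci$chrom[assigned],
                     pos = loci$pos[assigned],
                     b_count = loci$b_count[assigned],
                     depth = loci$depth[assigned],
                     stringsAsFactors = FALSE)
  segset$snps <- snps
  validate_segment_set(segset)
  segset
}

## Writers -------------------------------------------------------------------

#' Write inference results
#'
#' Writes three files under `prefix`:
#' * `<prefix>.segments.tsv` — per-segment table with `chrom`, `start`,
#'   `end`, `c_map` (MAP absolute copy number), `phi_map` (MAP subclonal
#'   frequency) and `node`;
#' * `<prefix>.tree.yaml` — the clone tree as a nested mapping with node
#'   subpopulation frequencies;
#' * `<prefix>.edges.tsv` — partial-order edge probabilities
#'   (`node_a`, `node_b`, `probability`).
#'
#' @param segset a [segment_set] (its coordinates are used).
#' @param assignments data.frame with columns `id`, `c_map`, `phi_map`,
#'   `node` (one row per inferred segment).
#' @param tree nested list describing the clone tree (see [tree_to_list()]),
#'   or `NULL` to skip the tree file.
#' @param edges data.frame with columns `node_a`, `node_b`, `probability`,
#'   or `NULL` for an empty edge file.
#' @param prefix output path prefix.
#' @return invisibly, the character vector of files written.
#' @export
write_results <- function(segset, assignments, tree = NULL, edges = NULL,
                          prefix = "scnapop") {
  old <- options(scipen = 15)  # coordinates in plain notation
  on.exit(options(old))
  seg <- segset$segments
  idx <- match(assignments$id, seg$id)
  if (anyNA(idx)) stop("assignment references unknown segment id")
  out <- data.frame(id = assignments$id,
                    chrom = seg$chrom[idx],
                    start = seg$start[idx], end = seg$end[idx],
                    c_map = assignments$c_map,
                    phi_map = assignments$phi_map,
                    node = assignments$node,
                    stringsAsFactors = FALSE)
  files <- character()
  f_seg <- paste0(prefix, ".segments.tsv")
  utils::write.table(out, f_seg, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f_seg)
  if (!is.null(tree)) {
    f_tree <- paste0(prefix, ".tree.yaml")
    yaml::write_yaml(tree, f_tree)
    files <- c(files, f_tree)
  }
  if (is.null(edges)) {
    edges <- data.frame(node_a = character(), node_b = character(),
                        probability = numeric())
  }
  f_edge <- paste0(prefix, ".edges.tsv")
  utils::write.table(edges, f_edge, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f_edge)
  invisible(files)
}

#' Write a segment set to the TSV dialects this package reads
#'
#' Writes `<prefix>.segments.tsv` and, when SNPs are attached,
#' `<prefix>.snps.tsv`.  `read_segment_table()` of the written segment table
#' is the identity on all serialized fields.
#'
#' @param segset a [segment_set].
#' @param prefix output path prefix.
#' @return invisibly, the files written.
#' @export
write_segment_set <- function(segset, prefix) {
  old <- options(scipen = 15)  # coordinates in plain notation
  on.exit(options(old))
  seg <- segset$segments
  f_seg <- paste0(prefix, ".segments.tsv")
  utils::write.table(
    seg[, c("id", "chrom", "start", "end", "tumor_reads", "normal_reads", "gc")],
    f_seg, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- f_seg
  if (nrow(segset$snps) > 0) {
    f_snp <- paste0(prefix, ".snps.tsv")
    utils::write.table(segset$snps[, c("chrom", "pos", "b_count", "depth")],
                       f_snp, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f_snp)
  }
  invisible(files)
}
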