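## Count-level tumor/normal simulator ----------------------------------------
##
## Generates segment read counts and SNP allele counts under a known clone
## tree, so that every downstream stage (bias correction, breakpoint filter,
## baseline detection, MCMC inference) can be validated against ground truth
## without external data.  The simulation is at count level: read counts are
## Poisson around their copy-number expectation and B-allele counts binomial
## around the population-averaged BAF; no reads or alignments are produced.

#' Construct a simulation configuration
#'
#' @param clone_nodes data.frame with columns `node`, `parent` (`NA` for the
#'   root) and `freq` (subpopulation frequency of exactly that clone).
#'   Frequencies must be positive and sum to at most 1; the remainder is the
#'   normal-cell fraction.
#' @param scnas data.frame with columns `chrom`, `pos` (1-based start),
#'   `length` (bp), `C` (integer tumor copy number >= 0), `genotype` (string
#'   over \{P, M\}, `"-"` for the empty genotype of `C = 0`) and `node`.
#' @param normal_segments data.frame with columns `chrom`, `pos` (1-based
#'   start) and `length`: copy-neutral segments carried by no clone.
#' @param coverage expected normal reads per base (default 0.03, i.e. about
#'   15000 reads on a 500-kb segment).
#' @param snp_rate heterozygous SNPs per base (default 1e-4).
#' @param snp_depth expected tumor read depth per SNP locus at copy-neutral
#'   state (default 30).
#' @param gc_bias numeric `(slope, intercept)` of the injected log-linear GC
#'   effect on the tumor/normal ratio.
#' @param false_breakpoint_rate expected extra splits per segment passed to
#'   [inject_false_breakpoints()] by pipelines that request it.
#' @param seed integer RNG seed used by [simulate_scna()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(clone_nodes, scnas, normal_segments,
                       coverage = 0.03, snp_rate = 1e-4, snp_depth = 30,
                       gc_bias = c(0, 0), false_breakpoint_rate = 0,
                       seed = 1L) {
  stopifnot(is.data.frame(clone_nodes), is.data.frame(scnas),
            is.data.frame(normal_segments),
            coverage > 0, snp_rate > 0, snp_depth > 0,
            length(gc_bias) == 2, false_breakpoint_rate >= 0)
  if (any(clone_nodes$freq <= 0)) stop("subpopulation frequencies must be positive")
  if (sum(clone_nodes$freq) > 1 + 1e-9) {
    stop("subpopulation frequencies sum to more than 1")
  }
  glen <- nchar(gsub("-", "", scnas$genotype))
  if (any(glen != scnas$C)) {
    stop("genotype length does not match copy number for SCNA ",
         which(glen != scnas$C)[1])
  }
  if (!all(scnas$node %in% clone_nodes$node)) stop("SCNA assigned to unknown node")
  structure(list(clone_nodes = clone_nodes, scnas = scnas,
                 normal_segments = normal_segments, coverage = coverage,
                 snp_rate = snp_rate, snp_depth = snp_depth,
                 gc_bias = as.numeric(gc_bias),
                 false_breakpoint_rate = false_breakpoint_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Subclonal frequency of each clone node
#'
#' The subclonal frequency of a node is its own subpopulation frequency plus
#' that of all its descendants (cells carrying the node's SCNAs).
#'
#' @param clone_nodes data.frame as in [sim_config()].
#' @return named numeric vector of phi per node.
#' @export
node_phi <- function(clone_nodes) {
  phi <- stats::setNames(clone_nodes$freq, clone_nodes$node)
  children <- split(clone_nodes$node, clone_nodes$parent)
  subtree <- function(node) {
    kids <- children[[node]]
    phi[[node]] + sum(vapply(kids, subtree, 0))
  }
  stats::setNames(vapply(clone_nodes$node, subtree, 0), clone_nodes$node)
}

#' Simulate a segment set from a clone-tree configuration
#'
#' For each segment the average copy number is `cbar = phi*C + (1 - phi)*2`
#' (`phi = 0` for copy-neutral segments).  Normal reads are Poisson with
#' mean `coverage * length`; tumor reads are Poisson with mean
#' `exp(slope*gc + intercept) * (cbar/2) * normal_reads`, conditioning on
#' the realized normal count; GC is uniform on \[0.3, 0.6\] per segment.
#' SNP loci are placed at rate `snp_rate` per base, with depth Poisson
#' around `snp_depth * cbar/2` (floored at 1) and B-allele count binomial
#' with success probability `(phi*C*mu_t + (1 - phi)) / cbar`.
#'
#' @param config a [sim_config].
#' @param seed RNG seed; defaults to `config$seed`.  The output is
#'   deterministic given the seed.
#' @return list with `segset` (a [segment_set]) and `truth`, a data.frame
#'   `(id, phi, C, genotype, node, cbar)` per segment.
#' @export
simulate_scna <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  phi_map <- node_phi(config$clone_nodes)
  sc <- config$scnas
  nm <- config$normal_segments
  tab <- rbind(
    if (nrow(sc) > 0) data.frame(
      name = if ("name" %in% names(sc)) sc$name else NA_character_,
      chrom = sc$chrom, start = sc$pos - 1, end = sc$pos - 1 + sc$length,
      C = sc$C, genotype = sc$genotype, node = sc$node,
      phi = unname(phi_map[sc$node]), stringsAsFactors = FALSE),
    if (nrow(nm) > 0) data.frame(
      name = NA_character_,
      chrom = nm$chrom, start = nm$pos - 1, end = nm$pos - 1 + nm$length,
      C = 2L, genotype = "PM", node = NA_character_, phi = 0,
      stringsAsFactors = FALSE))
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  n <- nrow(tab)
  id <- sprintf("seg%03d", seq_len(n))
  len <- tab$end - tab$start
  cbar <- expected_avg_copy(tab$phi, tab$C)
  gc <- stats::runif(n, 0.3, 0.6)
  normal_reads <- stats::rpois(n, config$coverage * len)
  normal_reads <- pmax(normal_reads, 1)
  slope <- config$gc_bias[1]; intercept <- config$gc_bias[2]
  tumor_mean <- exp(slope * gc + intercept) * (cbar / 2) * normal_reads
  tumor_reads <- stats::rpois(n, tumor_mean)
  segments <- data.frame(id = id, chrom = tab$chrom, start = tab$start,
                         end = tab$end, tumor_reads = tumor_reads,
                         normal_reads = normal_reads, gc = gc,
                         stringsAsFactors = FALSE)
  # SNP loci
  mu_t <- vapply(seq_len(n), function(i) {
    if (tab$C[i] == 0) 0 else {
      nchar(gsub("[^M]", "", tab$genotype[i])) / tab$C[i]
    }
  }, 0)
  mu_bar <- ifelse(cbar > 0,
                   (tab$phi * tab$C * mu_t + (1 - tab$phi)) / cbar, 0.5)
  snp_list <- lapply(seq_len(n), function(i) {
    k <- stats::rpois(1, config$snp_rate * len[i])
    if (k == 0) return(NULL)
    pos <- sort(sample.int(len[i], min(k, len[i]))) + tab$start[i]  # 1-based in (start, end]
    depth <- pmax(stats::rpois(k, config$snp_depth * cbar[i] / 2), 1)
    b <- stats::rbinom(k, depth, mu_bar[i])
    data.frame(segment_id = id[i], chrom = tab$chrom[i], pos = pos,
               b_count = b, depth = depth, stringsAsFactors = FALSE)
  })
  snps <- do.call(rbind, snp_list)
  if (is.null(snps)) snps <- empty_snp_table()
  truth <- data.frame(id = id, name = tab$name, chrom = tab$chrom,
                      start = tab$start, end = tab$end,
                      phi = tab$phi, C = tab$C,
                      genotype = tab$genotype, node = tab$node,
                      cbar = cbar, stringsAsFactors = FALSE)
  list(segset = segment_set(segments, snps), truth = truth,
       config = config)
}

#' The six-SCNA chromosome 21 demonstration scenario
#'
#' A clone tree of six subpopulations, each carrying one SCNA on
#' chromosome 21 (a homozygous deletion at subclonal frequency 0.95, a
#' three-copy gain at 0.30, a four-copy gain at 0.10, a five-copy gain with
#' genotype PMMMM at 0.50, a single-copy loss at 0.30, and a seven-copy
#' amplification MPPPPPP at 0.10), plus `n_normal` copy-neutral 500-kb
#' segments for baseline detection.  This is the package's standard
#' validation scenario; the tree places the deletion clone at the root with
#' the 0.50 and one 0.30 clone as its children.
#'
#' @param n_normal number of copy-neutral segments (>= 20 recommended).
#' @param gc_slope injected log-linear GC slope (default 0.5).
#' @param seed RNG seed stored in the configuration.
#' @return a [sim_config].
#' @export
six_scna_scenario <- function(n_normal = 24, gc_slope = 0.5, seed = 1L) {
  clone_nodes <- data.frame(
    node   = c("n1", "n2", "n3", "n4", "n5", "n6"),
    parent = c(NA, "n1", "n1", "n2", "n4", "n3"),
    freq   = c(0.15, 0.20, 0.20, 0.20, 0.10, 0.10),
    stringsAsFactors = FALSE)
  scnas <- data.frame(
    name = c("a", "b", "c", "d", "e", "f"),
    chrom = "chr21",
    pos = c(17478172, 27485802, 30959067, 35841868, 43277023, 25056314),
    length = 500000,
    C = c(0L, 3L, 4L, 5L, 1L, 7L),
    genotype = c("-", "PPM", "PPPM", "PMMMM", "M", "MPPPPPP"),
    node = c("n1", "n4", "n5", "n2", "n3", "n6"),
    stringsAsFactors = FALSE)
  # copy-neutral segments in the gaps between the SCNAs, 100 kb apart
  occupied <- cbind(scnas$pos - 1, scnas$pos - 1 + scnas$length)
  starts <- seq(5e6, 46e6, by = 6e5)
  free <- vapply(starts, function(s) {
    all(s + 5e5 + 1e3 <= occupied[, 1] | s - 1e3 >= occupied[, 2])
  }, TRUE)
  starts <- utils::head(starts[free], n_normal)
  if (length(starts) < n_normal) stop("not enough room for normal segments")
  normal_segments <- data.frame(chrom = "chr21", pos = starts + 1,
                                length = 5e5)
  sim_config(clone_nodes, scnas, normal_segments,
             gc_bias = c(gc_slope, 0), seed = seed)
}

#' Split segments at spurious breakpoints
#'
#' Emulates the false-positive breakpoints of an over-sensitive segmenter:
#' each segment is independently split at `k ~ Poisson(rate)` uniformly
#' drawn interior positions; the children partition the parent's interval,
#' read counts are apportioned multinomially by length fraction, and SNPs
#' are reassigned by position.  Lengths, read counts and SNP loci are
#' conserved exactly.
#'
#' @param segset a [segment_set] with simulated counts.
#' @param rate expected number of extra splits per segment (>= 0).
#' @param seed integer RNG seed.
#' @return the split [segment_set], with attribute `provenance`: a
#'   data.frame `(child, parent)` mapping child ids to original ids.
#' @export
inject_false_breakpoints <- function(segset, rate, seed = 1L) {
  stopifnot(rate >= 0)
  if (rate == 0) return(segset)
  set.seed(seed)
  seg <- segset$segments
  snps <- segset$snps
  out_seg <- list(); out_snp <- list(); prov <- list()
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    len <- s$end - s$start
    k <- stats::rpois(1, rate)
    k <- min(k, len - 1)
    cuts <- if (k > 0) sort(sample.int(len - 1, k)) + s$start else numeric()
    bounds <- c(s$start, cuts, s$end)
    nparts <- length(bounds) - 1
    part_len <- diff(bounds)
    tum <- if (nparts > 1) {
      drop(stats::rmultinom(1, s$tumor_reads, part_len))
    } else s$tumor_reads
    nor <- if (nparts > 1) {
      pmax(drop(stats::rmultinom(1, s$normal_reads, part_len)), 1)
    } else s$normal_reads
    child_id <- if (nparts > 1) paste0(s$id, ".", seq_len(nparts)) else s$id
    out_seg[[i]] <- data.frame(
      id = child_id, chrom = s$chrom, start = bounds[-length(bounds)],
      end = bounds[-1], tumor_reads = tum, normal_reads = nor, gc = s$gc,
      stringsAsFactors = FALSE)
    prov[[i]] <- data.frame(child = child_id, parent = s$id,
                            stringsAsFactors = FALSE)
    sn <- snps[snps$segment_id == s$id, , drop = FALSE]
    if (nrow(sn) > 0) {
      part <- findInterval(sn$pos - 1, bounds[-length(bounds)])
      sn$segment_id <- child_id[part]
      out_snp[[i]] <- sn
    }
  }
  new_seg <- do.call(rbind, out_seg)
  new_snp <- do.call(rbind, out_snp)
  if (is.null(new_snp)) new_snp <- empty_snp_table()
  out <- segment_set(new_seg, new_snp)
  attr(out, "provenance") <- do.call(rbind, prov)
  out
}

#' Read / write a simulation configuration
#'
#' YAML serialization of a [sim_config] (tables as lists of records).
#'
#' @param config a [sim_config].
#' @param path YAML file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a [sim_config].
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  for (f in c("clone_nodes", "scnas", "normal_segments")) {
    x[[f]] <- lapply(seq_len(nrow(config[[f]])), function(i) {
      as.list(config[[f]][i, , drop = FALSE])
    })
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  records <- function(recs) {
    do.call(rbind, lapply(recs, function(r) {
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)
    }))
  }
  sim_config(records(x$clone_nodes), records(x$scnas),
             records(x$normal_segments), coverage = x$coverage,
             snp_rate = x$snp_rate, snp_depth = x$snp_depth,
             gc_bias = unlist(x$gc_bias),
             false_breakpoint_rate = x$false_breakpoint_rate,
             seed = x$seed)
}
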