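## End-to-end pipeline --------------------------------------------------------
##
## Stage order: segment/SNP input -> GC-bias correction -> false-breakpoint
## filter -> baseline detection and theta -> subclonal inference (TSSB MCMC
## or flat grid) -> result files.

#' Pipeline configuration
#'
#' @param segments path to the segment TSV ([read_segment_table()]); may be
#'   `NULL` when a [segment_set] is passed to [run_pipeline()] directly.
#' @param snps path to the SNP input, or `NULL`.
#' @param snp_format `"tsv"` or `"vcf"`.
#' @param out_prefix output path prefix, or `NULL` to skip writing.
#' @param bias_correction fit and apply the GC-bias model (`FALSE` uses the
#'   identity model).
#' @param filter run the false-breakpoint filter.
#' @param filter_config a [filter_config].
#' @param mcmc an [mcmc_config] (its `mode` selects tree or flat inference).
#' @param coverage expected copy-neutral per-SNP tumor depth, required for
#'   baseline detection.
#' @param baf_tol,depth_tol baseline-detection tolerances
#'   (see [detect_baseline()]).
#' @param c_max maximum absolute copy number.
#' @param grid_step flat-mode grid resolution.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(segments = NULL, snps = NULL,
                            snp_format = c("tsv", "vcf"), out_prefix = NULL,
                            bias_correction = TRUE, filter = TRUE,
                            filter_config = scnapop::filter_config(),
                            mcmc = mcmc_config(), coverage = NULL,
                            baf_tol = 0.03, depth_tol = 0.1, c_max = 15,
                            grid_step = 0.01) {
  snp_format <- match.arg(snp_format)
  structure(list(segments = segments, snps = snps, snp_format = snp_format,
                 out_prefix = out_prefix, bias_correction = bias_correction,
                 filter = filter, filter_config = filter_config, mcmc = mcmc,
                 coverage = coverage, baf_tol = baf_tol,
                 depth_tol = depth_tol, c_max = c_max,
                 grid_step = grid_step),
            class = "pipeline_config")
}

stage_msg <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the full subclonal-reconstruction pipeline
#'
#' Executes bias correction, breakpoint filtering, baseline detection and
#' subclonal inference in order, logging input/output cardinalities per
#' stage, and optionally writes the result files via [write_results()].
#'
#' @param config a [pipeline_config].
#' @param segset optionally, an in-memory [segment_set] (with SNPs attached)
#'   used instead of reading `config$segments` / `config$snps`.
#' @return list with `segset` (post-filter, baseline marked), `bias` (the
#'   fitted [bias_model]), `theta`, `assignments` (data.frame `id`, `c_map`,
#'   `phi_map`, `node`), `edges`, `map` (tree mode: the MAP recorded state),
#'   `chain` (tree mode), `flat` (flat mode) and `files` (paths written).
#' @export
run_pipeline <- function(config, segset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(segset)) {
    if (is.null(config$segments)) stop("[input] no segment table configured")
    segset <- read_segment_table(config$segments)
    stage_msg("input", nrow(segset$segments), " segments from ", config$segments)
    if (!is.null(config$snps)) {
      loci <- read_snp_counts(config$snps, config$snp_format)
      segset <- attach_snps(segset, loci)
      stage_msg("input", nrow(segset$snps), " SNP loci attached")
    }
  }
  if (config$filter && nrow(segset$snps) == 0) {
    stop("[decompose] the breakpoint filter needs SNP input for BAF decomposition")
  }
  bias <- if (config$bias_correction) fit_bias(segset) else bias_model()
  segset <- apply_bias_correction(segset, bias)
  stage_msg("bias", "slope ", format(bias$slope, digits = 4),
            ", reference gc ", format(bias$reference_gc, digits = 4))
  if (config$filter) {
    n_in <- nrow(segset$segments)
    segset <- run_filter(segset, config$filter_config, bias)
    stage_msg("filter", n_in, " segments in, ", nrow(segset$segments), " out")
  }
  if (is.null(config$coverage)) {
    stop("[baseline] coverage (expected copy-neutral SNP depth) is required")
  }
  segset <- set_baseline(segset, config$coverage, config$baf_tol,
                         config$depth_tol)
  stage_msg("baseline", length(segset$baseline_ids), " baseline segments, theta ",
            format(segset$theta, digits = 6))
  ctx <- likelihood_context(theta = segset$theta, c_max = config$c_max,
                            bias = bias)
  out <- list(segset = segset, bias = bias, theta = segset$theta)
  if (config$mcmc$mode == "tree") {
    stage_msg("infer", "tree-mode MCMC: ", config$mcmc$burnin, " burn-in + ",
              config$mcmc$samples, " recorded cycles, seed ", config$mcmc$seed)
    chain <- run_mcmc(segset, ctx, config$mcmc)
    mp <- map_state(chain)
    out$chain <- chain
    out$map <- mp
    out$assignments <- data.frame(id = mp$assignments$id,
                                  c_map = mp$assignments$C,
                                  phi_map = mp$assignments$phi,
                                  node = mp$assignments$node,
                                  stringsAsFactors = FALSE)
    out$edges <- edge_probabilities(chain)
    out$tree <- tree_to_list(mp)
  } else {
    stage_msg("infer", "flat-mode grid inference, step ", config$grid_step)
    fl <- flat_infer(segset, ctx, config$grid_step)
    out$flat <- fl
    out$assignments <- data.frame(id = fl$assignments$id,
                                  c_map = fl$assignments$c_map,
                                  phi_map = fl$assignments$phi_map,
                                  node = NA_character_,
                                  stringsAsFactors = FALSE)
    out$edges <- NULL
    out$tree <- NULL
  }
  if (!is.null(config$out_prefix)) {
    out$files <- write_results(segset, out$assignments, out$tree, out$edges,
                               config$out_prefix)
    stage_msg("output", paste(out$files, collapse = ", "))
  }
  out
}

#' Group flat-mode segments into population-level frequency clusters
#'
#' Flat-mode inference is per segment; to report population frequencies the
#' segments are clustered on their inferred phi with the same aggregation
#' rule used by the breakpoint filter, and each cluster reports its
#' read-count-weighted mean phi.
#'
#' @param assignments the `assignments` data.frame of a flat [run_pipeline()]
#'   result.
#' @param segset the matching [segment_set].
#' @param tol cluster width on phi (default 0.05).
#' @return data.frame `cluster`, `phi`, `n_segments`.
#' @export
flat_population_clusters <- function(assignments, segset, tol = 0.05) {
  phi <- assignments$phi_map
  if (length(phi) == 1) {
    return(data.frame(cluster = 1L, phi = phi, n_segments = 1L))
  }
  hc <- stats::hclust(stats::dist(phi), method = "average")
  lab <- stats::cutree(hc, h = tol)
  seg <- segset$segments
  w <- seg$tumor_reads[match(assignments$id, seg$id)]
  out <- do.call(rbind, lapply(sort(unique(lab)), function(l) {
    i <- lab == l
    data.frame(cluster = l, phi = sum(phi[i] * w[i]) / sum(w[i]),
               n_segments = sum(i))
  }))
  out[order(-out$phi), ]
}
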