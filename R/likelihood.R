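## Per-segment likelihood ----------------------------------------------------
##
## A segment with subclonal frequency phi and tumor copy number C has
## population-averaged copy number Cbar = phi*C + (1 - phi)*2.  Two data
## channels inform (phi, C):
##   * the tumor read count, Poisson with mean
##     invert_bias((Cbar/2) * theta) * normal_reads, where theta is the
##     baseline ratio scale;
##   * the B-allele counts of the segment's heterozygous SNPs, binomial
##     around the expected folded BAF of the genotype.
## The marginal segment likelihood sums the (C, genotype) lattice in
## log-sum-exp form.

#' Enumerate tumor genotypes of a copy number
#'
#' All allele multisets over \{P, M\} of size `C`: pairs `(n_p, n_m)` with
#' `n_p + n_m = C`.  `C = 0` yields the single empty genotype.  Mirrored
#' genotypes (swapping P and M) are both retained; they are exactly
#' equivalent under the folded-BAF likelihood.
#'
#' @param C integer copy number >= 0.
#' @return data.frame with columns `n_p`, `n_m`, `mu_t` (`n_m / C`, `NA` for
#'   `C = 0`) and `label` (e.g. `"PPM"`; `"-"` for the empty genotype).
#' @export
genotype_set <- function(C) {
  stopifnot(C >= 0)
  if (C == 0) {
    return(data.frame(n_p = 0L, n_m = 0L, mu_t = NA_real_, label = "-",
                      stringsAsFactors = FALSE))
  }
  n_m <- 0:C
  data.frame(n_p = C - n_m, n_m = n_m, mu_t = n_m / C,
             label = paste0(strrep("P", C - n_m), strrep("M", n_m)),
             stringsAsFactors = FALSE)
}

#' Population-averaged copy number
#'
#' @param phi subclonal frequency in \[0, 1\].
#' @param C integer tumor copy number.
#' @return `phi * C + (1 - phi) * 2`.
#' @export
expected_avg_copy <- function(phi, C) {
  phi * C + (1 - phi) * 2
}

#' Expected folded BAF of a genotype at a subclonal frequency
#'
#' The average BAF mixes the tumor genotype's BAF `mu_t` (weight `phi * C`)
#' with the diploid normal contribution (weight `(1 - phi) * 2`, BAF 1/2),
#' normalized by the average copy number; the folded value
#' `min(mu, 1 - mu)` is returned.  For `C = 0` the tumor term vanishes and
#' the result is exactly 0.5.  The degenerate case `phi = 1, C = 0` (no DNA
#' at all) also returns 0.5, with attribute `degenerate = TRUE`.
#'
#' @param phi subclonal frequency in \[0, 1\].
#' @param C integer tumor copy number.
#' @param mu_t tumor-genotype BAF (`n_m / C`); ignored when `C = 0`.
#' @return folded expected BAF in \[0, 0.5\].
#' @export
expected_folded_baf <- function(phi, C, mu_t) {
  cbar <- expected_avg_copy(phi, C)
  if (cbar == 0) {
    out <- 0.5
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  tumor_term <- if (C == 0) 0 else phi * C * mu_t
  mu <- (tumor_term + (1 - phi)) / cbar
  min(mu, 1 - mu)
}

#' Likelihood context
#'
#' Bundles the quantities every segment likelihood needs: the baseline ratio
#' scale `theta`, the maximum absolute copy number `c_max` and the GC-bias
#' model used to map expected corrected ratios back to raw read scale.
#' Genotype tables per copy number are cached.
#'
#' @param theta positive baseline ratio scale (see [compute_theta()]).
#' @param c_max maximum absolute copy number (>= 3, default 15).
#' @param bias a [bias_model] (default identity).
#' @return an object of class `likelihood_context`.
#' @export
likelihood_context <- function(theta = 1, c_max = 15, bias = bias_model()) {
  stopifnot(theta > 0, c_max >= 3)
  structure(list(theta = theta, c_max = c_max, bias = bias,
                 genotypes = lapply(0:c_max, genotype_set)),
            class = "likelihood_context")
}

ctx_genotypes <- function(ctx, C) ctx$genotypes[[C + 1]]

## log(0.5*exp(a) + 0.5*exp(b)), elementwise, stable
log_mean_exp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m)) - log(2)
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' SNP B-allele-count log likelihood
#'
#' The B allele of a heterozygous germline SNP sits on either haplotype with
#' equal probability, so the count is modelled as the symmetric binomial
#' mixture `0.5 * Binom(depth, mu_hat) + 0.5 * Binom(depth, 1 - mu_hat)`
#' where `mu_hat` is the expected folded BAF of the genotype at `phi`.  At
#' `mu_hat = 0.5` this is exactly `Binom(depth, 0.5)`, and the pmf sums to
#' one over `b_count` for any `mu_hat`.
#'
#' @param b_count B-allele read count(s).
#' @param depth total read depth(s).
#' @param phi subclonal frequency.
#' @param C tumor copy number.
#' @param g one row of [genotype_set()] (or a list with `mu_t`).
#' @return log likelihood, vectorized over loci.
#' @export
snp_loglik <- function(b_count, depth, phi, C, g) {
  p <- as.numeric(expected_folded_baf(phi, C, g$mu_t))
  log_mean_exp2(stats::dbinom(b_count, depth, p, log = TRUE),
                stats::dbinom(b_count, depth, 1 - p, log = TRUE))
}

#' Tumor read-count log likelihood
#'
#' Poisson log pmf of the tumor read count with mean
#' `bias_invert(bias, (cbar / 2) * theta, gc) * normal_reads`.
#'
#' @param tumor_reads observed tumor read count.
#' @param normal_reads matched normal read count (>= 1).
#' @param gc segment GC fraction.
#' @param phi subclonal frequency.
#' @param C tumor copy number.
#' @param ctx a [likelihood_context].
#' @return log likelihood (scalar).
#' @export
readcount_loglik <- function(tumor_reads, normal_reads, gc, phi, C, ctx) {
  cbar <- expected_avg_copy(phi, C)
  if (cbar <= 0) return(if (tumor_reads == 0) 0 else -Inf)
  lambda <- bias_invert(ctx$bias, (cbar / 2) * ctx$theta, gc) * normal_reads
  stats::dpois(tumor_reads, lambda, log = TRUE)
}

#' Copy-number support of a segment
#'
#' Deletions and amplifications are separated by the baseline scale: a
#' corrected ratio below `theta` supports `C` in \{0, 1, 2\}, a ratio above
#' supports \{2, ..., c_max\}.  Equality is assigned to the amplification
#' branch; both branches contain the neutral `C = 2`.
#'
#' @param corrected_ratio the segment's GC-corrected tumor/normal ratio.
#' @param ctx a [likelihood_context].
#' @return integer vector of admissible copy numbers.
#' @export
cn_support <- function(corrected_ratio, ctx) {
  if (is.na(corrected_ratio)) stop("corrected_ratio is unset")
  if (corrected_ratio < ctx$theta) 0:2 else 2:ctx$c_max
}

## Per-segment cached data for repeated likelihood evaluation ---------------
segment_cache <- function(seg_row, snps, ctx) {
  support <- cn_support(seg_row$corrected_ratio, ctx)
  if (nrow(snps) == 0) {
    # no BAF information: the genotype sum would only replicate the
    # read-count term |genotypes(C)| times, so the lattice collapses to C
    combos <- data.frame(C = support, n_m = NA_integer_, mu_t = NA_real_)
  } else {
    combos <- do.call(rbind, lapply(support, function(C) {
      g <- ctx_genotypes(ctx, C)
      data.frame(C = C, n_m = g$n_m, mu_t = g$mu_t)
    }))
    combos <- combos[order(combos$C, combos$n_m), , drop = FALSE]
  }
  list(id = seg_row$id,
       tumor_reads = seg_row$tumor_reads,
       normal_reads = seg_row$normal_reads,
       gc = seg_row$gc,
       ratio = seg_row$corrected_ratio,
       support = support,
       combos = combos,
       b = snps$b_count, d = snps$depth,
       n_snp = nrow(snps))
}

## log-likelihood of every (C, genotype) combo of a cached segment at phi
segment_ll_terms <- function(cache, phi, ctx) {
  combos <- cache$combos
  cbar <- expected_avg_copy(phi, combos$C)
  # read-count term, one per combo (depends on C only, cheap to vectorize)
  lam <- bias_invert(ctx$bias, pmax(cbar, 1e-12) / 2 * ctx$theta, cache$gc) *
    cache$normal_reads
  rc <- stats::dpois(cache$tumor_reads, lam, log = TRUE)
  rc[cbar <= 0] <- if (cache$tumor_reads == 0) 0 else -Inf
  if (cache$n_snp == 0) return(rc)
  # folded expected BAF per combo
  tumor_term <- ifelse(combos$C == 0, 0, phi * combos$C * combos$mu_t)
  mu <- ifelse(cbar > 0, (tumor_term + (1 - phi)) / cbar, 0.5)
  p <- pmin(mu, 1 - mu)
  nc <- nrow(combos)
  bb <- rep(cache$b, times = nc)
  dd <- rep(cache$d, times = nc)
  pp <- rep(p, each = cache$n_snp)
  ll <- log_mean_exp2(stats::dbinom(bb, dd, pp, log = TRUE),
                      stats::dbinom(bb, dd, 1 - pp, log = TRUE))
  rc + colSums(matrix(ll, nrow = cache$n_snp, ncol = nc))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Marginal log likelihood of a segment at a subclonal frequency
#'
#' Sums, in log-sum-exp form, `exp(readcount_loglik + sum_k snp_loglik)`
#' over the copy numbers in the segment's support and the genotypes of each
#' copy number (unweighted genotype sum; no per-genotype prior).  A segment
#' without SNPs contributes its read-count term only.
#'
#' @param seg_row one row of a segment table (with `corrected_ratio` set).
#' @param snps data.frame of the segment's SNP loci (`b_count`, `depth`).
#' @param phi subclonal frequency.
#' @param ctx a [likelihood_context].
#' @return scalar log likelihood.
#' @export
segment_loglik <- function(seg_row, snps, phi, ctx) {
  cache <- segment_cache(seg_row, snps, ctx)
  log_sum_exp(segment_ll_terms(cache, phi, ctx))
}

#' MAP copy number and genotype of a segment at a subclonal frequency
#'
#' The `(C, genotype)` pair maximizing the joint read-count and SNP log
#' likelihood at the given `phi`.  Exact ties are broken toward the smaller
#' copy number, then the smaller maternal count.
#'
#' @inheritParams segment_loglik
#' @return list with `C`, `n_m`, `n_p`, `mu_t`, `loglik`.
#' @export
map_copy_number <- function(seg_row, snps, phi, ctx) {
  cache <- segment_cache(seg_row, snps, ctx)
  ll <- segment_ll_terms(cache, phi, ctx)
  i <- which.max(ll)  # combos pre-sorted by (C, n_m): first max wins ties
  combos <- cache$combos
  list(C = combos$C[i], n_m = combos$n_m[i],
       n_p = combos$C[i] - combos$n_m[i],
       mu_t = combos$mu_t[i], loglik = ll[i])
}
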