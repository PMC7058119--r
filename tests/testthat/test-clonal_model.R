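test_that("genotype enumeration covers all allele multisets", {
  g2 <- genotype_set(2)
  expect_equal(g2$label, c("PP", "PM", "MM"))
  g0 <- genotype_set(0)
  expect_equal(nrow(g0), 1)
  expect_equal(g0$label, "-")
  for (C in 0:9) expect_equal(nrow(genotype_set(C)), C + 1)
})

test_that("expected average copy number and folded BAF follow the model", {
  expect_equal(expected_avg_copy(0, 7), 2)
  expect_equal(expected_avg_copy(1, 7), 7)
  expect_equal(expected_avg_copy(0.5, 5), 3.5)
  # pure normal: folded BAF 1/2 for every genotype
  for (C in c(0, 1, 3, 4)) {
    g <- genotype_set(C)
    for (i in seq_len(nrow(g))) {
      expect_equal(as.numeric(expected_folded_baf(0, C, g$mu_t[i])), 0.5)
    }
  }
  # pure tumor PPPM
  expect_equal(as.numeric(expected_folded_baf(1, 4, 0.25)), 0.25)
  # half tumor PPPM: (0.5*4*0.25 + 0.5)/3 = 1/3
  expect_equal(as.numeric(expected_folded_baf(0.5, 4, 0.25)), 1 / 3)
  # five-copy PMMMM at phi 0.5: cbar 3.5, mu_t 4/5
  expect_equal(expected_avg_copy(0.5, 5), 3.5)
  expect_equal(as.numeric(expected_folded_baf(0.5, 5, 4 / 5)),
               min(2.5 / 3.5, 1 - 2.5 / 3.5))
  # C = 0 always gives 1/2; the degenerate no-DNA case carries a flag
  expect_equal(as.numeric(expected_folded_baf(0.6, 0, NA)), 0.5)
  deg <- expected_folded_baf(1, 0, NA)
  expect_equal(as.numeric(deg), 0.5)
  expect_true(isTRUE(attr(deg, "degenerate")))
  # bounds hold over random draws
  set.seed(5)
  for (i in 1:200) {
    C <- sample(0:15, 1); phi <- runif(1)
    mu_t <- if (C > 0) sample(0:C, 1) / C else NA
    fb <- as.numeric(expected_folded_baf(phi, C, mu_t))
    expect_gte(fb, 0); expect_lte(fb, 0.5)
    expect_gte(expected_avg_copy(phi, C), 0)
  }
})

test_that("snp_loglik is the symmetric binomial mixture and normalizes", {
  g <- list(mu_t = 0.5)
  expect_equal(snp_loglik(30, 60, 0, 2, g), dbinom(30, 60, 0.5, log = TRUE))
  # normalization over b for an asymmetric genotype
  g2 <- genotype_set(4)[2, ]  # PPPM
  ll <- snp_loglik(0:40, 40, 0.7, 4, g2)
  expect_equal(sum(exp(ll)), 1, tolerance = 1e-12)
  # agreement with a directly computed mixture pmf (lchoose arithmetic)
  set.seed(9)
  for (i in 1:20) {
    d <- sample(5:60, 1); b <- sample(0:d, 1)
    phi <- runif(1); C <- sample(c(0, 1, 3:8), 1)
    mu_t <- if (C > 0) sample(0:C, 1) / C else NA
    p <- as.numeric(expected_folded_baf(phi, C, mu_t))
    ref <- log(0.5 * exp(lchoose(d, b) + b * log(p) + (d - b) * log1p(-p)) +
               0.5 * exp(lchoose(d, b) + b * log1p(-p) + (d - b) * log(p)))
    expect_equal(snp_loglik(b, d, phi, C, list(mu_t = mu_t)), ref,
                 tolerance = 1e-10)
  }
})

test_that("readcount_loglik uses the corrected Poisson mean", {
  ctx <- likelihood_context(theta = 1, c_max = 15)
  # copy neutral: mean equals the normal read count
  expect_equal(readcount_loglik(1000, 1000, 0.5, 0, 2, ctx),
               dpois(1000, 1000, log = TRUE))
  # pure tumor at C 4: mean doubles
  expect_equal(readcount_loglik(2000, 1000, 0.5, 1, 4, ctx),
               dpois(2000, 2000, log = TRUE))
  # pmf sums to ~1 over a truncated support at small mean
  ctx2 <- likelihood_context(theta = 1)
  ll <- vapply(0:100, function(k) readcount_loglik(k, 5, 0.5, 1, 2, ctx2), 0)
  expect_equal(sum(exp(ll)), 1, tolerance = 1e-10)
})

test_that("cn_support splits on theta and always contains 2", {
  ctx <- likelihood_context(theta = 1, c_max = 15)
  expect_equal(cn_support(0.8, ctx), 0:2)
  expect_equal(cn_support(1.5, ctx), 2:15)
  expect_true(2 %in% cn_support(0.8, ctx))
  expect_true(2 %in% cn_support(1.0, ctx))  # equality: amplification branch
  expect_equal(cn_support(1.0, ctx), 2:15)
})

test_that("segment_loglik equals a linear-space brute force on a tiny fixture", {
  ctx <- likelihood_context(theta = 1, c_max = 5)
  seg <- data.frame(id = "t", chrom = "chr1", start = 0, end = 100,
                    tumor_reads = 8, normal_reads = 10, gc = 0.5,
                    corrected_ratio = 0.8, baf_cluster = NA_integer_)
  snps <- data.frame(segment_id = "t", chrom = "chr1", pos = c(10, 20),
                     b_count = c(3, 5), depth = c(8, 9))
  phi <- 0.37
  total <- 0
  for (C in 0:2) {  # ratio < theta: support {0,1,2}
    g <- genotype_set(C)
    for (i in seq_len(nrow(g))) {
      p <- as.numeric(expected_folded_baf(phi, C, g$mu_t[i]))
      lik <- exp(dpois(8, expected_avg_copy(phi, C) / 2 * 10, log = TRUE))
      for (k in 1:2) {
        lik <- lik * (0.5 * dbinom(snps$b_count[k], snps$depth[k], p) +
                      0.5 * dbinom(snps$b_count[k], snps$depth[k], 1 - p))
      }
      total <- total + lik
    }
  }
  expect_equal(segment_loglik(seg, snps, phi, ctx), log(total),
               tolerance = 1e-9)
  # empty SNP table: read-count term only
  no_snp <- snps[0, ]
  ref <- log(sum(vapply(0:2, function(C) {
    dpois(8, expected_avg_copy(phi, C) / 2 * 10)
  }, 0)))
  expect_equal(segment_loglik(seg, no_snp, phi, ctx), ref, tolerance = 1e-12)
})

test_that("map_copy_number recovers exact-mean fixtures and matches a scan", {
  ctx <- likelihood_context(theta = 1, c_max = 15)
  fx <- exact_segment("m1", phi = 1, C = 4, n_m = 1)
  mp <- map_copy_number(fx$seg, fx$snps, 1, ctx)
  expect_equal(mp$C, 4)
  expect_equal(mp$n_m, 1)  # mirrored tie broken toward smaller n_m
  # homozygous deletion at phi 0.95
  fx2 <- exact_segment("m2", phi = 0.95, C = 0, n_m = 0)
  mp2 <- map_copy_number(fx2$seg, fx2$snps, 0.95, ctx)
  expect_equal(mp2$C, 0)
  # agreement with an explicit scan over the same lattice
  phi <- 0.6
  scan_best <- -Inf; scan_C <- NA
  for (C in cn_support(fx$seg$corrected_ratio, ctx)) {
    g <- genotype_set(C)
    for (i in seq_len(nrow(g))) {
      ll <- readcount_loglik(fx$seg$tumor_reads, fx$seg$normal_reads,
                             fx$seg$gc, phi, C, ctx) +
        sum(snp_loglik(fx$snps$b_count, fx$snps$depth, phi, C, g[i, ]))
      if (ll > scan_best) { scan_best <- ll; scan_C <- C }
    }
  }
  mp3 <- map_copy_number(fx$seg, fx$snps, phi, ctx)
  expect_equal(mp3$C, scan_C)
  expect_equal(mp3$loglik, scan_best, tolerance = 1e-9)
})
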