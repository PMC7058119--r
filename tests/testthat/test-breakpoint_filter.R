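test_that("aggregation recovers well-separated ratio groups", {
  set.seed(31)
  n <- 50
  seg <- data.frame(
    id = sprintf("s%03d", 1:(2 * n)), chrom = "chr1",
    start = seq(0, by = 2e5, length.out = 2 * n),
    end = seq(0, by = 2e5, length.out = 2 * n) + 1e5,
    tumor_reads = 20000, normal_reads = 20000, gc = 0.5,
    corrected_ratio = exp(c(rnorm(n, 0, 0.01), rnorm(n, log(1.5), 0.01))),
    baf_cluster = NA_integer_)
  ss <- segment_set(seg)
  lab <- aggregate_segments(ss, filter_config())
  tab <- table(lab[1:n] == lab[(n + 1):(2 * n)])
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:n])), 1)
  expect_equal(length(unique(lab[(n + 1):(2 * n)])), 1)
  # degenerate: identical ratios collapse to one cluster
  seg$corrected_ratio <- 1
  expect_equal(unique(aggregate_segments(segment_set(seg), filter_config())),
               1L)
  # the cluster count respects the c_max * tau cap
  seg$corrected_ratio <- exp(seq(0, 3, length.out = 2 * n))
  lab2 <- aggregate_segments(segment_set(seg), filter_config(c_max = 2, tau = 2))
  expect_lte(length(unique(lab2)), 4)
  # unset corrected ratio is a state error
  seg$corrected_ratio <- NA_real_
  expect_error(aggregate_segments(segment_set(seg), filter_config()),
               "corrected_ratio unset")
})

test_that("mean-shift decomposition separates BAF modes and uses majority rule", {
  # all SNPs at one mode: a single subcluster
  ss <- tiny_segset()
  ss$snps$b_count <- ss$snps$depth / 2
  lab <- decompose_cluster(ss, c("s1", "s2", "s3"), filter_config())
  expect_equal(length(unique(lab)), 1)
  # two modes far apart, pure segments per mode
  set.seed(41)
  mk <- function(id, p, off, n = 60) data.frame(
    segment_id = id, chrom = "chr1", pos = off + seq_len(n),
    b_count = rbinom(n, 100, p), depth = 100)
  seg <- data.frame(id = c("lo", "hi"), chrom = "chr1",
                    start = c(0, 2e5), end = c(1e5, 3e5),
                    tumor_reads = 100, normal_reads = 100, gc = 0.5)
  ss2 <- segment_set(seg, rbind(mk("lo", 0.2, 0), mk("hi", 0.5, 2e5)))
  lab2 <- decompose_cluster(ss2, c("lo", "hi"), filter_config())
  expect_equal(length(unique(lab2)), 2)
  expect_true(lab2[["lo"]] != lab2[["hi"]])
  # majority rule with tie toward the lowest label
  labs <- mean_shift_1d(c(0.1, 0.1, 0.1, 0.48, 0.52, 0.5), bandwidth = 0.05)
  expect_equal(length(labs$modes), 2)
  # segments without SNPs are isolated in subcluster 0
  lab3 <- decompose_cluster(ss2, c("lo", "hi", "bare"), filter_config())
  expect_equal(unname(lab3["bare"]), 0L)
})

test_that("adjacent merging respects rho, chromosome and conservation", {
  seg <- data.frame(
    id = c("a", "b", "c", "d"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(0, 150, 400, 0), end = c(100, 250, 500, 100),
    tumor_reads = c(10, 20, 30, 40), normal_reads = c(10, 10, 10, 10),
    gc = c(0.4, 0.6, 0.5, 0.5))
  ss <- segment_set(seg)
  # gap 50 < rho 100: a and b merge; c (gap 150) and d (chr2) stay
  m <- merge_adjacent(ss, c("a", "b", "c", "d"), rho = 100)
  expect_equal(nrow(m$segments), 3)
  ab <- m$segments[m$segments$start == 0 & m$segments$chrom == "chr1", ]
  expect_equal(ab$end, 250)
  expect_equal(ab$tumor_reads, 30)
  expect_equal(ab$gc, (0.4 * 100 + 0.6 * 100) / 200)
  expect_equal(sum(m$segments$tumor_reads), sum(seg$tumor_reads))
  # rho 1: nothing merges
  m2 <- merge_adjacent(ss, c("a", "b", "c", "d"), rho = 1)
  expect_equal(nrow(m2$segments), 4)
  # overlap is a structural error
  seg$start[2] <- 50
  expect_error(merge_adjacent(segment_set(seg), seg$id, rho = 10),
               "overlapping")
})

test_that("run_filter restores split segments and preserves true boundaries", {
  sim <- simulate_scna(six_scna_scenario(seed = 11))
  bias <- fit_bias(sim$segset)
  truth_n <- nrow(sim$segset$segments)
  split <- inject_false_breakpoints(sim$segset, rate = 2, seed = 12)
  split <- apply_bias_correction(split, bias)
  filtered <- run_filter(split, filter_config(), bias)
  n_out <- nrow(filtered$segments)
  expect_lte(abs(n_out - truth_n) / truth_n, 0.10)
  # every true SCNA boundary must survive in the filtered breakpoint set
  tr <- sim$truth[!is.na(sim$truth$name), ]
  bounds <- c(filtered$segments$start, filtered$segments$end)
  expect_true(all(tr$start %in% bounds))
  expect_true(all(tr$end %in% bounds))
  # read counts conserved overall
  expect_equal(sum(filtered$segments$tumor_reads),
               sum(sim$segset$segments$tumor_reads))
  expect_equal(nrow(filtered$snps), nrow(split$snps))
})

test_that("unsplit input passes through without losing boundaries", {
  sim <- simulate_scna(six_scna_scenario(seed = 13))
  bias <- fit_bias(sim$segset)
  ss <- apply_bias_correction(sim$segset, bias)
  out <- run_filter(ss, filter_config(), bias)
  expect_lte(nrow(out$segments), nrow(ss$segments))
  expect_true(all(ss$segments$start %in% out$segments$start))
})

test_that("adjacent segments with different copy number never merge", {
  # two book-ended segments whose ratios differ by a full copy step
  seg <- data.frame(
    id = c("left", "right"), chrom = "chr1", start = c(0, 5e5),
    end = c(5e5, 1e6), tumor_reads = c(15000, 22500),
    normal_reads = c(15000, 15000), gc = 0.45)
  snps <- rbind(
    data.frame(segment_id = "left", chrom = "chr1",
               pos = seq(1000, 4e5, by = 1e4), b_count = 15, depth = 30),
    data.frame(segment_id = "right", chrom = "chr1",
               pos = seq(5e5 + 1000, 9e5, by = 1e4), b_count = 10, depth = 30))
  ss <- apply_bias_correction(segment_set(seg, snps))
  out <- run_filter(ss, filter_config(rho = 10), bias_model())
  expect_equal(nrow(out$segments), 2)
})

test_that("the filter is idempotent under fixed clustering", {
  sim <- simulate_scna(six_scna_scenario(seed = 14))
  bias <- fit_bias(sim$segset)
  split <- apply_bias_correction(
    inject_false_breakpoints(sim$segset, 1.5, seed = 15), bias)
  once <- run_filter(split, filter_config(), bias)
  twice <- run_filter(once, filter_config(), bias)
  expect_equal(nrow(twice$segments), nrow(once$segments))
  expect_equal(sort(twice$segments$start), sort(once$segments$start))
})
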