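# Shared fixtures, built in code at test time.

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# a tiny two-chromosome segment set with SNPs attached
tiny_segset <- function() {
  segments <- data.frame(
    id = c("s1", "s2", "s3"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(0, 10, 0),
    end = c(10, 20, 50),
    tumor_reads = c(100, 150, 400),
    normal_reads = c(100, 100, 400),
    gc = c(0.4, 0.5, 0.45),
    stringsAsFactors = FALSE)
  snps <- data.frame(
    segment_id = c("s1", "s1", "s2", "s3"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(1, 10, 20, 25),
    b_count = c(3, 5, 10, 30),
    depth = c(10, 10, 20, 60),
    stringsAsFactors = FALSE)
  segment_set(segments, snps)
}

# a minimal VCF 4.2 file with FORMAT/AD for one tumor sample
tiny_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR",
    "chr21\t100\t.\tA\tC\t50\tPASS\t.\tGT:AD\t0/1:30,30",
    "chr21\t200\t.\tG\tT\t50\tPASS\t.\tGT:AD\t0/1:40,20",
    "chr21\t300\t.\tG\tA\t50\tPASS\t.\tGT:AD\t0/1:0,0"),
    path)
  path
}

# segments whose counts realize an exact expected ratio (no noise), with
# matching exact-mean SNPs; used for noiseless likelihood fixtures
exact_segment <- function(id = "x1", phi, C, n_m, normal_reads = 20000,
                          n_snp = 40, snp_depth = 50, theta = 1, gc = 0.5) {
  cbar <- phi * C + (1 - phi) * 2
  mu_t <- if (C > 0) n_m / C else 0
  mu <- if (cbar > 0) (phi * C * mu_t + (1 - phi)) / cbar else 0.5
  seg <- data.frame(
    id = id, chrom = "chr1", start = 0, end = 1e6,
    tumor_reads = round(cbar / 2 * theta * normal_reads),
    normal_reads = normal_reads, gc = gc,
    corrected_ratio = cbar / 2 * theta,
    baf_cluster = NA_integer_, stringsAsFactors = FALSE)
  snps <- data.frame(
    segment_id = id, chrom = "chr1", pos = seq_len(n_snp) * 100,
    b_count = round(mu * snp_depth), depth = snp_depth,
    stringsAsFactors = FALSE)
  list(seg = seg, snps = snps)
}
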