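# Independent brute-force oracle for the Weir-Cockerham (1984) variance
# components: classical one-way-nested ANOVA on per-allele indicator
# variables (alleles within individuals within populations), algebraically
# independent of the closed-form moment expressions in the package.
oracle_wc_site <- function(dosA, dosB) {
  alleles <- list()
  pops <- integer(0)
  for (d in dosA[!is.na(dosA)]) {
    alleles[[length(alleles) + 1]] <- switch(as.character(d),
      `0` = c(0, 0), `1` = c(0, 1), `2` = c(1, 1))
    pops <- c(pops, 1L)
  }
  for (d in dosB[!is.na(dosB)]) {
    alleles[[length(alleles) + 1]] <- switch(as.character(d),
      `0` = c(0, 0), `1` = c(0, 1), `2` = c(1, 1))
    pops <- c(pops, 2L)
  }
  n1 <- sum(pops == 1); n2 <- sum(pops == 2)
  if (n1 < 2 || n2 < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  n_ind <- length(alleles)
  ind_means <- vapply(alleles, mean, numeric(1))
  pop_means <- c(mean(unlist(alleles[pops == 1])),
                 mean(unlist(alleles[pops == 2])))
  grand <- mean(unlist(alleles))
  # sums of squares: within individuals / individuals within pops / pops
  ssg <- sum(vapply(seq_len(n_ind), function(i)
    sum((alleles[[i]] - ind_means[i])^2), numeric(1)))
  ssi <- sum(2 * (ind_means - pop_means[pops])^2)
  ssp <- 2 * n1 * (pop_means[1] - grand)^2 + 2 * n2 * (pop_means[2] - grand)^2
  msg <- ssg / n_ind
  msi <- ssi / (n_ind - 2)
  msp <- ssp / 1
  nc <- (n_ind - (n1^2 + n2^2) / n_ind) / 1
  a <- (msp - msi) / (2 * nc)
  b <- (msi - msg) / 2
  c(a = a, b = b, c = msg)
}

oracle_wc_fst <- function(dosA, dosB) {
  comps <- vapply(seq_len(ncol(dosA)), function(j)
    oracle_wc_site(dosA[, j], dosB[, j]), numeric(3))
  a <- comps[1, ]; b <- comps[2, ]; cc <- comps[3, ]
  ok <- !is.na(a) & (a + b + cc) != 0
  if (!any(ok)) return(NA_real_)
  sum(a[ok]) / sum(a[ok] + b[ok] + cc[ok])
}

# random small genotype-matrix instance for property sweeps
random_gm_instance <- function(seed) {
  set.seed(seed)
  n_a <- sample(2:5, 1)
  n_b <- sample(2:5, 1)
  n_sites <- sample(1:20, 1)
  dos <- matrix(sample(c(0L, 1L, 2L, NA), (n_a + n_b) * n_sites,
                       replace = TRUE, prob = c(0.4, 0.3, 0.25, 0.05)),
                n_a + n_b, n_sites)
  samples <- sprintf("s%02d", seq_len(n_a + n_b))
  variants <- data.frame(chrom = "chr1", pos = seq_len(n_sites) * 10L,
                         ref = "A", alt = "T", stringsAsFactors = FALSE)
  gm <- genotype_matrix(dos, samples, variants,
                        chrom_lengths = c(chr1 = n_sites * 10 + 10))
  list(gm = gm, group_a = samples[seq_len(n_a)], group_b = samples[-seq_len(n_a)])
}

# small handwritten VCF used by the I/O tests
write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=5000>",
    "##contig=<ID=chrZ,length=2000>",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="x">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="x">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t100\t.\tA\tT\t50\tPASS\tQD=20;FS=1\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tG\t50\tPASS\tQD=15;FS=2\tGT\t0/1\t0/1\t./.",
    "chr1\t300\t.\tG\tA\t50\tPASS\tQD=10;FS=3\tGT\t1/1\t0/0\t0/1",
    "chr1\t400\t.\tT\tC,G\t50\tPASS\tQD=9;FS=1\tGT\t0/1\t0/2\t1/1",
    "chr1\t500\t.\tA\tACG\t50\tPASS\tQD=9;FS=1\tGT\t0/1\t0/0\t0/0",
    "chr1\t600\t.\tT\tA\t50\tPASS\tQD=30;FS=0\tGT\t0|1\t0/0\t0/0",
    "chrZ\t150\t.\tG\tC\t50\tPASS\tQD=25;FS=5\tGT\t0/0\t1/1\t0/1"
  ), path)
  path
}

# structured fixture split into its truth groups
fixture_groups <- function(fx) {
  list(a = fx$labels$sample_id[fx$labels$population == "pop1"],
       b = fx$labels$sample_id[fx$labels$population == "pop2"])
}
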