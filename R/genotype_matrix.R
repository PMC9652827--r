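#' Construct a genotype matrix
#'
#' The central container for diploid biallelic SNV genotypes: a samples x
#' variants matrix of alternate-allele dosages (0, 1, 2 or `NA` for missing),
#' together with variant coordinates, chromosome lengths and the set of
#' chromosomes treated as Z-linked.
#'
#' @param dosage integer/numeric matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param samples character vector of unique sample identifiers (row names).
#' @param variants data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; one row per dosage column. Positions must be strictly increasing
#'   within each chromosome.
#' @param chrom_lengths named numeric vector mapping chromosome name to its
#'   length in bp. Defaults to the maximum observed position per chromosome.
#' @param z_chroms character vector of chromosome names treated as Z-linked.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, samples, variants,
                            chrom_lengths = NULL, z_chroms = character()) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(samples))
    stop("dosage must have one row per sample")
  if (ncol(dosage) != nrow(variants))
    stop("dosage must have one column per variant")
  if (anyDuplicated(samples))
    stop("sample identifiers must be unique")
  bad <- !(dosage %in% c(0, 1, 2)) & !is.na(dosage)
  if (any(bad))
    stop("dosage entries must be 0, 1, 2 or NA")
  variants <- as.data.frame(variants)
  needed <- c("chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(variants)))
    stop("variants must have columns chrom, pos, ref, alt")
  variants$chrom <- as.character(variants$chrom)
  nt <- c("A", "C", "G", "T")
  if (nrow(variants) &&
      (!all(variants$ref %in% nt) || !all(variants$alt %in% nt)))
    stop("only biallelic SNVs allowed: ref/alt must be single nucleotides")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(variants$pos, variants$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  rownames(dosage) <- samples
  structure(list(
    dosage = dosage,
    samples = as.character(samples),
    variants = variants,
    chrom_lengths = chrom_lengths,
    z_chroms = as.character(z_chroms)
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d biallelic SNVs on %d chromosome(s)\n",
              length(x$samples), nrow(x$variants),
              length(unique(x$variants$chrom))))
  if (length(x$z_chroms))
    cat("  Z-linked:", paste(x$z_chroms, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by variants and/or samples
#'
#' @param gm a [genotype_matrix()].
#' @param variants logical or integer index over variant columns.
#' @param samples logical/integer/character index over samples.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_gm <- function(gm, variants = NULL, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  dos <- gm$dosage
  var <- gm$variants
  smp <- gm$samples
  if (!is.null(variants)) {
    dos <- dos[, variants, drop = FALSE]
    var <- var[variants, , drop = FALSE]
    rownames(var) <- NULL
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, smp)
    dos <- dos[samples, , drop = FALSE]
    smp <- smp[samples]
  }
  genotype_matrix(dos, smp, var, gm$chrom_lengths, gm$z_chroms)
}

#' Split variants into Z-linked and autosomal subsets
#'
#' Produces a disjoint, exhaustive partition of the variants according to the
#' `z_chroms` attribute of the genotype matrix.
#'
#' @param gm a [genotype_matrix()] with `z_chroms` configured.
#' @return A list with elements `z` and `autosome`, both `genotype_matrix`.
#' @export
partition_z_autosome <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  is_z <- gm$variants$chrom %in% gm$z_chroms
  if (length(gm$z_chroms) && !any(gm$variants$chrom %in% gm$z_chroms) &&
      !any(names(gm$chrom_lengths) %in% gm$z_chroms))
    warning("z_chroms name no chromosome present in the data; Z subset empty")
  list(z = subset_gm(gm, variants = is_z),
       autosome = subset_gm(gm, variants = !is_z))
}

#' Observed alternate-allele frequencies
#'
#' Allele counts are taken over observed (non-missing) alleles only.
#'
#' @param gm a [genotype_matrix()].
#' @param samples optional sample subset (names or indices).
#' @return Numeric vector of per-variant alternate-allele frequencies (`NaN`
#'   where no genotype is observed).
#' @export
allele_freq <- function(gm, samples = NULL) {
  dos <- gm$dosage
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, gm$samples)
    dos <- dos[samples, , drop = FALSE]
  }
  colSums(dos, na.rm = TRUE) / (2 * colSums(!is.na(dos)))
}

#' Mean pairwise nucleotide diversity per site
#'
#' Unbiased per-site heterozygosity `2 p (1-p) * n/(n-1)` summed over variants
#' and divided by the sequence length (unlisted positions are invariant).
#'
#' @param gm a [genotype_matrix()].
#' @param samples optional sample subset.
#' @param seq_len total sequence length in bp; defaults to the sum of
#'   `chrom_lengths`.
#' @return Diversity per site (substitutions/site).
#' @export
nucleotide_diversity <- function(gm, samples = NULL, seq_len = NULL) {
  dos <- gm$dosage
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, gm$samples)
    dos <- dos[samples, , drop = FALSE]
  }
  if (is.null(seq_len)) seq_len <- sum(gm$chrom_lengths)
  n <- 2 * colSums(!is.na(dos))
  p <- colSums(dos, na.rm = TRUE) / n
  ok <- n >= 2
  sum(2 * p[ok] * (1 - p[ok]) * n[ok] / (n[ok] - 1)) / seq_len
}
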