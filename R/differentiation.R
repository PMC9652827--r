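#' Per-site Weir-Cockerham variance components
#'
#' Computes the Weir & Cockerham (1984) among-population (a), among-individual
#' (b) and within-individual (c) variance components per site for two groups
#' of diploid genotypes, from allele frequencies and observed heterozygosity.
#' Sites where either group has fewer than two genotyped individuals are not
#' counted.
#'
#' @param gm a [genotype_matrix()].
#' @param group_a,group_b character vectors of sample IDs (or indices) for the
#'   two populations.
#' @return Data frame with one row per variant: `a`, `b`, `c` and `counted`
#'   (logical; `FALSE` rows have `NA` components).
#' @export
wc_components <- function(gm, group_a, group_b) {
  dosA <- group_dosage(gm, group_a)
  dosB <- group_dosage(gm, group_b)
  wc_components_dosage(dosA, dosB)
}

group_dosage <- function(gm, group) {
  if (is.character(group)) {
    idx <- match(group, gm$samples)
    if (anyNA(idx)) stop("unknown sample(s): ",
                         paste(group[is.na(idx)], collapse = ", "))
  } else idx <- group
  gm$dosage[idx, , drop = FALSE]
}

wc_components_dosage <- function(dosA, dosB) {
  nA <- colSums(!is.na(dosA)); nB <- colSums(!is.na(dosB))
  counted <- nA >= 2 & nB >= 2
  pA <- colSums(dosA, na.rm = TRUE) / (2 * nA)
  pB <- colSums(dosB, na.rm = TRUE) / (2 * nB)
  hA <- colSums(dosA == 1, na.rm = TRUE) / nA
  hB <- colSums(dosB == 1, na.rm = TRUE) / nB
  nbar <- (nA + nB) / 2
  nc <- 2 * nbar - (nA^2 + nB^2) / (2 * nbar)
  pbar <- (nA * pA + nB * pB) / (2 * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / nbar
  hbar <- (nA * hA + nB * hB) / (2 * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!counted] <- NA_real_; b[!counted] <- NA_real_; cc[!counted] <- NA_real_
  data.frame(a = a, b = b, c = cc, counted = counted)
}

# ratio-of-sums estimate from component table (rows already selected)
wc_ratio <- function(comp) {
  ok <- comp$counted & (comp$a + comp$b + comp$c) != 0
  if (!any(ok, na.rm = TRUE)) return(NA_real_)
  sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
}

#' Weir-Cockerham F_ST, genome-wide or per window
#'
#' Multi-site estimates use the ratio-of-sums ("weighted") convention
#' `sum(a) / sum(a + b + c)`; sites with zero total variance contribute
#' nothing. Values are reported unclamped (the estimator can be negative).
#'
#' @inheritParams wc_components
#' @param windows optional window table from [make_windows()]; if supplied a
#'   per-window table is returned, otherwise a genome-wide scalar.
#' @return Scalar estimate, or a data frame of window statistics with columns
#'   `chrom`, `start`, `end`, `untruncated`, `n_snps`, `fst` (windows with no
#'   informative site report `NA`).
#' @export
wc_fst <- function(gm, group_a, group_b, windows = NULL) {
  comp <- wc_components(gm, group_a, group_b)
  if (!any(comp$counted))
    stop("no site with >= 2 genotyped samples in both groups")
  if (is.null(windows)) return(wc_ratio(comp))
  idx <- window_variant_index(gm, windows)
  fst <- vapply(idx, function(i) wc_ratio(comp[i, , drop = FALSE]), numeric(1))
  n_snps <- vapply(idx, function(i) sum(comp$counted[i]), numeric(1))
  cbind(windows, n_snps = n_snps, fst = fst)
}

#' Windowed absolute divergence D_XY
#'
#' Per window, `D_XY = sum_sites [pA (1-pB) + (1-pA) pB] / window length`,
#' with `pA`, `pB` the observed alternate-allele frequencies. Positions not
#' listed as variants are taken as invariant: they contribute 0 to the
#' numerator but the full window length forms the denominator.
#'
#' @inheritParams wc_components
#' @param windows window table from [make_windows()] (conventionally 500 kb
#'   windows with 100 kb step).
#' @return Window table with `n_snps` and `dxy` columns appended.
#' @export
window_dxy <- function(gm, group_a, group_b, windows) {
  if (!length(group_a) || !length(group_b)) stop("empty group")
  dosA <- group_dosage(gm, group_a)
  dosB <- group_dosage(gm, group_b)
  nA <- colSums(!is.na(dosA)); nB <- colSums(!is.na(dosB))
  pA <- colSums(dosA, na.rm = TRUE) / (2 * nA)
  pB <- colSums(dosB, na.rm = TRUE) / (2 * nB)
  per_site <- pA * (1 - pB) + (1 - pA) * pB
  ok <- nA >= 1 & nB >= 1
  idx <- window_variant_index(gm, windows)
  dxy <- vapply(seq_along(idx), function(i) {
    j <- idx[[i]][ok[idx[[i]]]]
    sum(per_site[j]) / (windows$end[i] - windows$start[i])
  }, numeric(1))
  n_snps <- vapply(idx, function(i) sum(ok[i]), numeric(1))
  cbind(windows, n_snps = n_snps, dxy = dxy)
}

#' Genome-wide random-grouping permutation test for F_ST
#'
#' Recomputes the genome-wide Weir-Cockerham F_ST under `B` random
#' relabelings of the samples preserving the two group sizes, and reports the
#' empirical p-value `(1 + #\{null >= observed\}) / (1 + B)` (never zero, so
#' an observed value exceeding all `B = 100` permutations yields
#' `p = 1/101 < 0.01`).
#'
#' @inheritParams wc_components
#' @param B number of random groupings (default 100).
#' @param seed optional RNG seed.
#' @return An object of class `permutation_result`: list with `observed`,
#'   `null_values`, `B` and `p_empirical`.
#' @export
permutation_test <- function(gm, group_a, group_b, B = 100, seed = NULL) {
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  idxA <- sample_index(gm, group_a); idxB <- sample_index(gm, group_b)
  pool <- sort(c(idxA, idxB)) # canonical order: p-values invariant to input order
  nA <- length(idxA)
  if (B > choose(length(pool), nA))
    warning("B exceeds the number of distinct relabelings; ",
            "sampling with replacement retained")
  observed <- wc_ratio(wc_components_dosage(
    gm$dosage[idxA, , drop = FALSE], gm$dosage[idxB, , drop = FALSE]))
  null_values <- vapply(seq_len(B), function(b) {
    perm <- sample(pool)
    wc_ratio(wc_components_dosage(
      gm$dosage[perm[seq_len(nA)], , drop = FALSE],
      gm$dosage[perm[-seq_len(nA)], , drop = FALSE]))
  }, numeric(1))
  structure(list(observed = observed, null_values = null_values, B = B,
                 p_empirical = (1 + sum(null_values >= observed)) / (1 + B)),
            class = "permutation_result")
}

sample_index <- function(gm, group) {
  if (is.character(group)) {
    idx <- match(group, gm$samples)
    if (anyNA(idx)) stop("unknown sample(s): ",
                         paste(group[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(group)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: observed F_ST = %.4f, B = %d, p = %.4g\n",
              x$observed, x$B, x$p_empirical))
  invisible(x)
}

#' Per-window permutation significance with FDR correction
#'
#' For every window with at least one informative SNP, the window F_ST is
#' recomputed under `B_window` within-window random relabelings; the
#' empirical p-value uses the `(k + 1)/(B + 1)` convention. p-values are
#' Benjamini-Hochberg corrected across the untruncated windows that carry
#' data (zero-SNP windows are excluded from the FDR family).
#'
#' @inheritParams wc_components
#' @param windows window table from [make_windows()].
#' @param B_window permutations per window (>= 19; default 199).
#' @param alpha FDR level for the `significant` flag (default 0.05).
#' @param seed optional RNG seed.
#' @return Window table with `n_snps`, `fst`, `p_value`, `q_value` and
#'   `significant` columns.
#' @export
window_significance <- function(gm, group_a, group_b, windows,
                                B_window = 199, alpha = 0.05, seed = NULL) {
  stopifnot(B_window >= 19)
  if (!is.null(seed)) set.seed(seed)
  idxA <- sample_index(gm, group_a); idxB <- sample_index(gm, group_b)
  pool <- sort(c(idxA, idxB)); nA <- length(idxA)
  widx <- window_variant_index(gm, windows)
  comp <- wc_components_dosage(gm$dosage[idxA, , drop = FALSE],
                               gm$dosage[idxB, , drop = FALSE])
  fst <- vapply(widx, function(i) wc_ratio(comp[i, , drop = FALSE]), numeric(1))
  n_snps <- vapply(widx, function(i) sum(comp$counted[i]), numeric(1))
  p <- rep(NA_real_, nrow(windows))
  for (w in which(!is.na(fst))) {
    cols <- widx[[w]]
    dos <- gm$dosage[pool, cols, drop = FALSE]
    null_w <- vapply(seq_len(B_window), function(b) {
      perm <- sample(nrow(dos))
      wc_ratio(wc_components_dosage(dos[perm[seq_len(nA)], , drop = FALSE],
                                    dos[perm[-seq_len(nA)], , drop = FALSE]))
    }, numeric(1))
    p[w] <- (1 + sum(null_w >= fst[w], na.rm = TRUE)) / (1 + B_window)
  }
  n_empty <- sum(windows$untruncated & is.na(fst))
  if (n_empty)
    message(n_empty, " untruncated window(s) without informative SNPs ",
            "excluded from the FDR family")
  fam <- windows$untruncated & !is.na(p)
  q <- rep(NA_real_, nrow(windows))
  q[fam] <- p.adjust(p[fam], method = "BH")
  out <- cbind(windows, n_snps = n_snps, fst = fst,
               p_value = p, q_value = q)
  out$significant <- !is.na(out$q_value) & out$q_value < alpha
  out
}

#' Classify genomic differentiation (GD)
#'
#' GD is the status where genetic differentiation occurs in a vast majority
#' of genomic windows: the flag is raised iff strictly more than 90% of
#' untruncated data-carrying windows are significant at the chosen FDR level.
#'
#' @param windowstats output of [window_significance()].
#' @param alpha FDR level (default 0.05).
#' @param threshold fraction of significant windows that must be exceeded
#'   (strictly) to declare GD (default 0.90).
#' @return An object of class `gd_report`: list with `frac_positive`
#'   (fraction of windows with F_ST > 0), `frac_significant`, `gd_flag`,
#'   `n_windows`.
#' @export
gd_classify <- function(windowstats, alpha = 0.05, threshold = 0.90) {
  use <- windowstats$untruncated & !is.na(windowstats$fst)
  if (!any(use)) stop("no untruncated window with data")
  ws <- windowstats[use, , drop = FALSE]
  frac_positive <- mean(ws$fst > 0)
  frac_significant <- mean(!is.na(ws$q_value) & ws$q_value < alpha)
  structure(list(frac_positive = frac_positive,
                 frac_significant = frac_significant,
                 gd_flag = frac_significant > threshold,
                 n_windows = nrow(ws), alpha = alpha, threshold = threshold),
            class = "gd_report")
}

#' @export
print.gd_report <- function(x, ...) {
  cat(sprintf(
    "GD report over %d windows: %.1f%% with F_ST > 0, %.1f%% significant (FDR %.2g) -> GD %s\n",
    x$n_windows, 100 * x$frac_positive, 100 * x$frac_significant, x$alpha,
    if (x$gd_flag) "YES" else "no"))
  invisible(x)
}

#' Rank a genomic region within its chromosome's F_ST distribution
#'
#' Used to ask whether a candidate locus (e.g. a clock gene such as vrille)
#' sits in the upper tail of its chromosome's windowed differentiation.
#'
#' @param windowstats window table carrying an `fst` column.
#' @param chrom chromosome name of the region.
#' @param start,end region interval (0-based half-open, bp).
#' @return List with `region_fst` (mean F_ST of overlapping windows),
#'   `percentile` (share, in percent, of the chromosome's data windows with
#'   F_ST <= region mean), `n_overlap` and a `chrom_summary` of the
#'   chromosome's window distribution.
#' @export
region_report <- function(windowstats, chrom, start, end) {
  on_chr <- windowstats[windowstats$chrom == chrom & !is.na(windowstats$fst), ,
                        drop = FALSE]
  if (!nrow(on_chr)) stop("region chromosome not present in window stats")
  ov <- on_chr$start < end & on_chr$end > start
  if (!any(ov)) stop("region overlaps no window with data")
  region_fst <- mean(on_chr$fst[ov])
  w <- on_chr$fst
  list(region_fst = region_fst,
       percentile = 100 * sum(w <= region_fst) / length(w),
       n_overlap = sum(ov),
       chrom_summary = summary(w))
}
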