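#' Quick two-population genotype fixture with known structure
#'
#' Draws per-population allele frequencies from a Balding-Nichols divergence
#' model calibrated so the realized Weir-Cockerham F_ST approximates
#' `fst_target`, then samples binomial genotypes. Optional F1 hybrids draw
#' one allele from each population's frequency pool at every locus. Truth
#' labels are returned alongside the genotypes.
#'
#' @param n_per_group diploid samples per population (>= 2).
#' @param n_variants number of biallelic SNVs.
#' @param fst_target target differentiation in `[0, 0.95]`; larger values are
#'   rejected as unreachable.
#' @param n_hybrids number of planted F1 hybrids (default 0).
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @param chrom_len chromosome length in bp (default: variants spaced 1 kb).
#' @param anc_range range of ancestral allele frequencies.
#' @return List with `gm` (a [genotype_matrix()]) and `labels` (data frame
#'   `sample_id`, `population`, `is_hybrid`).
#' @export
make_structured_fixture <- function(n_per_group = 20, n_variants = 500,
                                    fst_target = 0.1, n_hybrids = 0,
                                    seed = 1, chrom = "chr1",
                                    chrom_len = NULL,
                                    anc_range = c(0.1, 0.9)) {
  stopifnot(n_per_group >= 2, n_variants >= 1, n_hybrids >= 0)
  if (fst_target < 0 || fst_target > 0.95)
    stop("fst_target must lie in [0, 0.95]")
  set.seed(seed)
  p_anc <- runif(n_variants, anc_range[1], anc_range[2])
  if (fst_target == 0) {
    p1 <- p_anc
    p2 <- p_anc
  } else {
    # Balding-Nichols parameter adjusted so the *pairwise* two-population
    # Weir-Cockerham estimate lands near the target
    f <- 2 * fst_target / (2 + fst_target)
    shape <- (1 - f) / f
    p1 <- rbeta(n_variants, p_anc * shape, (1 - p_anc) * shape)
    p2 <- rbeta(n_variants, p_anc * shape, (1 - p_anc) * shape)
  }
  draw_pop <- function(p, n) t(vapply(seq_len(n), function(i)
    rbinom(length(p), 2L, p), integer(length(p))))
  dos1 <- draw_pop(p1, n_per_group)
  dos2 <- draw_pop(p2, n_per_group)
  dosage <- rbind(dos1, dos2)
  samples <- c(sprintf("P1_%02d", seq_len(n_per_group)),
               sprintf("P2_%02d", seq_len(n_per_group)))
  population <- rep(c("pop1", "pop2"), each = n_per_group)
  if (n_hybrids > 0) {
    hyb <- t(vapply(seq_len(n_hybrids), function(i)
      rbinom(n_variants, 1L, p1) + rbinom(n_variants, 1L, p2),
      integer(n_variants)))
    dosage <- rbind(dosage, hyb)
    samples <- c(samples, sprintf("H_%02d", seq_len(n_hybrids)))
    population <- c(population, rep("hybrid", n_hybrids))
  }
  if (is.null(chrom_len)) chrom_len <- n_variants * 1000
  spacing <- floor(chrom_len / n_variants)
  stopifnot(spacing >= 1)
  pos <- spacing * (seq_len(n_variants) - 1L) + floor(spacing / 2) + 1L
  variants <- data.frame(chrom = chrom, pos = as.integer(pos),
                         ref = "A", alt = "T", stringsAsFactors = FALSE)
  gm <- genotype_matrix(dosage, samples, variants,
                        chrom_lengths = setNames(chrom_len, chrom))
  labels <- data.frame(sample_id = samples, population = population,
                       is_hybrid = population == "hybrid",
                       stringsAsFactors = FALSE)
  list(gm = gm, labels = labels)
}

#' Simulate aligned sequences under the F84 substitution model
#'
#' Evolves sequences along a phylogeny under F84 (unequal base frequencies,
#' transition/transversion bias), expressed as a general time-reversible
#' rate matrix with transition exchangeabilities `1 + K/pi_R` (purines) and
#' `1 + K/pi_Y` (pyrimidines). Branch lengths are in expected substitutions
#' per site.
#'
#' @param tree an `ape::phylo` tree with nonnegative branch lengths.
#' @param base_freqs equilibrium base frequencies in A, C, G, T order
#'   (must sum to 1).
#' @param ts_tv_ratio expected transition/transversion ratio (must exceed
#'   the model's F81 floor for the given frequencies).
#' @param seq_len alignment length in bp (>= 1).
#' @param seed RNG seed.
#' @return A `DNAbin` alignment (taxa x sites).
#' @export
simulate_f84_sequences <- function(tree, base_freqs = rep(0.25, 4),
                                   ts_tv_ratio = 2, seq_len = 1000,
                                   seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("branch lengths must be >= 0")
  if (abs(sum(base_freqs) - 1) > 1e-8)
    stop("base_freqs must sum to 1")
  if (seq_len < 1) stop("zero-length alignment rejected")
  pi_a <- base_freqs[1]; pi_c <- base_freqs[2]
  pi_g <- base_freqs[3]; pi_t <- base_freqs[4]
  pi_r <- pi_a + pi_g; pi_y <- pi_c + pi_t
  K <- (ts_tv_ratio * pi_r * pi_y - pi_a * pi_g - pi_c * pi_t) /
    (pi_a * pi_g / pi_r + pi_c * pi_t / pi_y)
  if (K < 0)
    stop("ts_tv_ratio below the F81 floor for these base frequencies")
  Q <- c(1, 1 + K / pi_r, 1, 1, 1 + K / pi_y, 1) # ac, ag, at, cg, ct, gt
  set.seed(seed)
  sim <- phangorn::simSeq(tree, l = seq_len, Q = Q, bf = base_freqs,
                          type = "DNA")
  as.matrix(ape::as.DNAbin(sim))
}
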