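#' Configuration for the two-population divergence simulation
#'
#' Parameters of the forward Wright-Fisher validation model: an ancestral
#' population splits into Pop A and Pop B; gene flow is unidirectional from
#' B to A at rate `mig` per offspring per generation; Pop A experiences
#' divergent (viability) selection of strength `sel` at a single focal site
#' introduced in one copy at the split. The defaults are the study
#' conditions: N = 3100 diploids per population, mutation rate 1.2e-8 /bp
#' /generation, recombination rate 1.19e-8 /bp /generation, migration 0.001,
#' selection 0.05, 2 Mb of sequence with the selected site at the midpoint.
#'
#' Full-size forward simulation of those conditions is not desk-scale, so
#' the model is rescaled by `rescale_q`: population size is divided by `q`
#' and `mu`, `rec`, `mig` and `sel` are multiplied by `q`, keeping the
#' products `N*s`, `N*m`, `N*mu*L` and `N*r*L` invariant.
#'
#' @param n_diploid diploid population size per population (default 3100).
#' @param mu per-bp per-generation mutation rate (default 1.2e-8).
#' @param rec per-bp per-generation recombination rate (default 1.19e-8).
#' @param mig per-generation migration fraction B to A (default 0.001).
#' @param sel selection coefficient at the focal site in Pop A (default 0.05).
#' @param dominance heterozygote effect multiplier h, fitness `1 + h s`
#'   (default 0.5, genic selection).
#' @param seq_len simulated sequence length in bp (default 2e6).
#' @param focal_pos 0-based coordinate of the selected site (default
#'   midpoint).
#' @param burnin_gens generations before the split (in rescaled units;
#'   default `10 * N/q`).
#' @param split_gens generations after the split (default `4 * N/q`).
#' @param rescale_q rescaling factor `q >= 1`.
#' @param n_sample haploid sample size per population at output (even;
#'   default 40).
#' @param seed base RNG seed; replicate `r` uses `seed + r`.
#' @return An object of class `sim_config` (validated list, including the
#'   derived rescaled fields `n_rescaled`, `mu_total`, `rec_total`,
#'   `mig_rescaled`, `sel_rescaled`).
#' @export
sim_config <- function(n_diploid = 3100, mu = 1.2e-8, rec = 1.19e-8,
                       mig = 0.001, sel = 0.05, dominance = 0.5,
                       seq_len = 2e6, focal_pos = floor(seq_len / 2),
                       burnin_gens = NULL, split_gens = NULL,
                       rescale_q = 1, n_sample = 40, seed = 1) {
  num_ok <- function(x) length(x) == 1 && is.finite(x)
  for (v in list(n_diploid, mu, rec, mig, sel, dominance, seq_len, focal_pos,
                 rescale_q, n_sample, seed))
    if (!num_ok(v)) stop("all parameters must be finite scalars")
  if (mu < 0 || mu > 1 || rec < 0 || rec > 1 || mig < 0 || mig > 1)
    stop("rates mu, rec, mig must lie in [0, 1]")
  if (sel < 0) stop("sel must be >= 0")
  if (rescale_q < 1) stop("rescale_q must be >= 1")
  if (focal_pos < 0 || focal_pos >= seq_len)
    stop("focal_pos must lie in [0, seq_len)")
  if (n_sample %% 2 != 0 || n_sample < 2)
    stop("n_sample must be an even count >= 2")
  n_rescaled <- max(2, round(n_diploid / rescale_q))
  mig_rescaled <- mig * rescale_q
  if (mig_rescaled > 1) stop("rescaled migration rate exceeds 1")
  if (n_sample > 2 * n_rescaled)
    stop("n_sample exceeds the rescaled haploid population size")
  if (is.null(burnin_gens)) burnin_gens <- 10 * n_rescaled
  if (is.null(split_gens)) split_gens <- 4 * n_rescaled
  structure(list(
    n_diploid = n_diploid, mu = mu, rec = rec, mig = mig, sel = sel,
    dominance = dominance, seq_len = as.integer(seq_len),
    focal_pos = as.integer(focal_pos), burnin_gens = as.integer(burnin_gens),
    split_gens = as.integer(split_gens), rescale_q = rescale_q,
    n_sample = as.integer(n_sample), seed = as.integer(seed),
    n_rescaled = as.integer(n_rescaled),
    mu_total = mu * rescale_q * seq_len,
    rec_total = rec * rescale_q * seq_len,
    mig_rescaled = mig_rescaled,
    sel_rescaled = sel * rescale_q
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: N=%d (rescaled %d, q=%g), mu=%.3g, r=%.3g, m=%.3g, s=%.3g, L=%d bp\n",
    x$n_diploid, x$n_rescaled, x$rescale_q, x$mu, x$rec, x$mig, x$sel,
    x$seq_len))
  cat(sprintf("  burnin %d + split %d generations, %d haplotypes sampled/pop\n",
              x$burnin_gens, x$split_gens, x$n_sample))
  invisible(x)
}

#' Forward simulation of divergence with reduced gene flow
#'
#' Runs `n_reps` independent replicates of the two-population model described
#' in [sim_config()] and summarizes each replicate with windowed
#' Weir-Cockerham F_ST and D_XY (20 kb windows by default), averaged over
#' replicates. If the selected allele is lost in Pop A it is re-seeded into a
#' random haplotype (counted and reported), never silently dropped.
#'
#' @param config a [sim_config()].
#' @param n_reps number of replicates (default 50).
#' @param window_size window size in bp for the summary statistics
#'   (default 20 kb).
#' @param keep_genotypes keep the per-replicate [genotype_matrix()] objects.
#' @return An object of class `sim_result`: list with `config`, `n_reps`,
#'   `windows`, `window_fst` / `window_dxy` (per-window replicate averages),
#'   `fst_reps` / `dxy_reps` (replicate x window matrices), `genotypes`
#'   (list, possibly empty), `metadata` and `reseeds`.
#' @export
simulate_divergence <- function(config, n_reps = 50, window_size = 2e4,
                                keep_genotypes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  windows <- make_windows(c(sim1 = config$seq_len), size_bp = window_size,
                          step_bp = window_size)
  nw <- nrow(windows)
  fst_reps <- matrix(NA_real_, n_reps, nw)
  dxy_reps <- matrix(NA_real_, n_reps, nw)
  genotypes <- vector("list", if (keep_genotypes) n_reps else 0)
  n_ind <- config$n_sample / 2
  samples <- c(sprintf("A%02d", seq_len(n_ind)), sprintf("B%02d", seq_len(n_ind)))
  metadata <- data.frame(sample_id = samples,
                         population = rep(c("A", "B"), each = n_ind),
                         is_hybrid = FALSE, stringsAsFactors = FALSE)
  group_a <- samples[seq_len(n_ind)]
  group_b <- samples[-seq_len(n_ind)]
  reseeds <- 0L
  for (r in seq_len(n_reps)) {
    set.seed(config$seed + r)
    raw <- wf_sim_cpp(config$n_rescaled, config$mu_total, config$rec_total,
                      config$mig_rescaled, config$sel_rescaled,
                      config$dominance, config$seq_len, config$focal_pos,
                      config$burnin_gens, config$split_gens, config$n_sample)
    reseeds <- reseeds + raw$reseeds
    gm <- haplotypes_to_gm(c(raw$hapA, raw$hapB), samples, config$seq_len)
    if (keep_genotypes) genotypes[[r]] <- gm
    if (nrow(gm$variants) > 0) {
      fst_reps[r, ] <- wc_fst(gm, group_a, group_b, windows)$fst
      dxy_reps[r, ] <- window_dxy(gm, group_a, group_b, windows)$dxy
    }
  }
  if (reseeds > 0)
    message("selected allele re-seeded ", reseeds, " time(s) across replicates")
  structure(list(
    config = config, n_reps = n_reps, windows = windows,
    window_fst = cbind(windows, fst = colMeans(fst_reps, na.rm = TRUE)),
    window_dxy = cbind(windows, dxy = colMeans(dxy_reps, na.rm = TRUE)),
    fst_reps = fst_reps, dxy_reps = dxy_reps,
    genotypes = genotypes, metadata = metadata, reseeds = reseeds
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d replicate(s), %d windows of %d bp\n",
              x$n_reps, nrow(x$windows),
              as.integer(x$windows$end[1] - x$windows$start[1])))
  invisible(x)
}

# haps: list of 0-based integer position vectors (sorted); consecutive pairs
# form diploid individuals
haplotypes_to_gm <- function(haps, samples, seq_len,
                             chrom = "sim1") {
  pos <- sort(unique(unlist(haps)))
  n_ind <- length(haps) / 2
  if (!length(pos)) {
    return(genotype_matrix(matrix(0L, n_ind, 0), samples,
                           data.frame(chrom = character(), pos = integer(),
                                      ref = character(), alt = character()),
                           chrom_lengths = setNames(seq_len, chrom)))
  }
  hapmat <- matrix(vapply(haps, function(h) as.integer(pos %in% h),
                          integer(length(pos))),
                   nrow = length(pos))
  dosage <- t(hapmat[, seq(1, length(haps), 2), drop = FALSE] +
                hapmat[, seq(2, length(haps), 2), drop = FALSE])
  variants <- data.frame(chrom = chrom, pos = pos + 1L, ref = "A", alt = "T",
                         stringsAsFactors = FALSE)
  genotype_matrix(dosage, samples, variants,
                  chrom_lengths = setNames(seq_len, chrom))
}

#' Index of the window containing the focal (selected) site
#'
#' @param sim a `sim_result` from [simulate_divergence()].
#' @return Integer window row index.
#' @export
focal_window <- function(sim) {
  which(sim$windows$start <= sim$config$focal_pos &
          sim$windows$end > sim$config$focal_pos)
}

#' Write a simulation replicate to disk
#'
#' Emits the replicate's genotypes as VCF v4.2, the sample metadata as TSV
#' and the averaged windowed summaries as TSV.
#'
#' @param sim a `sim_result` with `keep_genotypes = TRUE`.
#' @param dir output directory (created if needed).
#' @param rep replicate index to export (default 1).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim_result <- function(sim, dir, rep = 1) {
  stopifnot(inherits(sim, "sim_result"), length(sim$genotypes) >= rep)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, sprintf("replicate%02d.vcf", rep)),
             metadata = file.path(dir, "samples.tsv"),
             windows = file.path(dir, "window_summary.tsv"))
  write_vcf(sim$genotypes[[rep]], paths[["vcf"]])
  write_sample_metadata(sim$metadata, paths[["metadata"]])
  ws <- cbind(sim$windows,
              n_snps = vapply(window_variant_index(sim$genotypes[[rep]],
                                                   sim$windows), length,
                              numeric(1)),
              fst = sim$window_fst$fst, dxy = sim$window_dxy$dxy)
  write_tsv(ws, paths[["windows"]])
  invisible(paths)
}
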