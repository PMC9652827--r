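test_that("simulation config validates rates, rescaling and focal site", {
  expect_error(sim_config(mu = -1), "rates")
  expect_error(sim_config(mig = 2), "rates")
  expect_error(sim_config(rescale_q = 0.5), "rescale_q")
  expect_error(sim_config(focal_pos = 2e6), "focal_pos")
  expect_error(sim_config(sel = NaN), "finite")
  expect_error(sim_config(n_sample = 7), "even")
  cfg <- sim_config(rescale_q = 31)
  # rescaled products preserved
  expect_equal(cfg$n_rescaled * cfg$sel_rescaled, 3100 * 0.05)
  expect_equal(cfg$n_rescaled * cfg$mig_rescaled, 3100 * 0.001)
  expect_equal(cfg$n_rescaled * cfg$mu_total, 3100 * 1.2e-8 * 2e6)
})

test_that("mu = 0 yields no segregating sites and missing window stats", {
  cfg <- sim_config(n_diploid = 60, mu = 0, rec = 1e-8, sel = 0,
                    seq_len = 1e5, rescale_q = 1, n_sample = 10, seed = 2)
  sim <- simulate_divergence(cfg, n_reps = 1, window_size = 2e4)
  expect_equal(nrow(sim$genotypes[[1]]$variants), 0)
  expect_true(all(is.na(sim$fst_reps)))
  expect_true(all(is.na(sim$dxy_reps)))
})

test_that("identical seed and config reproduce bit-identical output", {
  cfg <- sim_config(n_diploid = 200, mu = 1e-7, rec = 1e-7, seq_len = 1e5,
                    rescale_q = 2, n_sample = 20, seed = 33)
  s1 <- simulate_divergence(cfg, n_reps = 2, window_size = 2e4)
  s2 <- simulate_divergence(cfg, n_reps = 2, window_size = 2e4)
  expect_identical(s1$genotypes[[1]]$dosage, s2$genotypes[[1]]$dosage)
  expect_identical(s1$fst_reps, s2$fst_reps)
  expect_identical(s1$dxy_reps, s2$dxy_reps)
})

test_that("neutral single-population diversity matches 4 N mu", {
  # rescale_q = 6 with a desk-scale base population; the coalescent
  # expectation 4 N mu per site is invariant under the rescaling
  cfg <- sim_config(n_diploid = 620, mu = 2e-7, rec = 1e-7, mig = 0, sel = 0,
                    seq_len = 5e4, rescale_q = 6, split_gens = 0,
                    n_sample = 20, seed = 7)
  sim <- simulate_divergence(cfg, n_reps = 200, window_size = 5e4,
                             keep_genotypes = TRUE)
  pis <- vapply(sim$genotypes, function(gm)
    nucleotide_diversity(gm, samples = 1:10), numeric(1))
  expect_equal(mean(pis), 4 * 620 * 2e-7, tolerance = 0.15)
})

test_that("the focal window is elevated under divergent selection only", {
  cfg <- sim_config(rescale_q = 31, seed = 19)
  sim <- suppressMessages(simulate_divergence(cfg, n_reps = 10,
                                              keep_genotypes = FALSE))
  fw <- focal_window(sim)
  distal <- order(abs(sim$windows$start + 1e4 - 1e6),
                  decreasing = TRUE)[1:10]
  expect_gt(sim$window_fst$fst[fw], mean(sim$window_fst$fst[distal]))
  expect_gt(sim$window_dxy$dxy[fw], mean(sim$window_dxy$dxy[distal]))
})

test_that("neutral limit: focal window is not an outlier", {
  cfg <- sim_config(rescale_q = 31, sel = 0, seed = 23)
  sim <- simulate_divergence(cfg, n_reps = 50, keep_genotypes = FALSE)
  fw <- focal_window(sim)
  fst <- sim$window_fst$fst
  expect_lte(abs(fst[fw] - mean(fst, na.rm = TRUE)),
             2 * sd(fst, na.rm = TRUE))
})

test_that("rescaling leaves the focal-window statistics invariant", {
  base <- function(q) sim_config(n_diploid = 400, mu = 5e-8, rec = 5e-8,
                                 mig = 0.001, sel = 0.05, seq_len = 2e5,
                                 rescale_q = q, n_sample = 40, seed = 55)
  s4 <- suppressMessages(simulate_divergence(base(4), n_reps = 50,
                                             keep_genotypes = FALSE))
  s8 <- suppressMessages(simulate_divergence(base(8), n_reps = 50,
                                             keep_genotypes = FALSE))
  ci <- function(x) mean(x, na.rm = TRUE) +
    c(-1.96, 1.96) * sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  for (field in c("fst_reps", "dxy_reps")) {
    fw4 <- ci(s4[[field]][, focal_window(s4)])
    fw8 <- ci(s8[[field]][, focal_window(s8)])
    expect_true(fw4[1] <= fw8[2] && fw8[1] <= fw4[2])
  }
})

test_that("unidirectional gene flow homogenizes the populations", {
  base <- function(m) sim_config(n_diploid = 400, mu = 5e-8, rec = 5e-8,
                                 mig = m, sel = 0, seq_len = 1e5,
                                 rescale_q = 4, split_gens = 300,
                                 n_sample = 20, seed = 71)
  genome_fst <- function(sim) vapply(sim$genotypes, function(gm) {
    if (!nrow(gm$variants)) return(NA_real_)
    wc_fst(gm, 1:10, 11:20)
  }, numeric(1))
  f_iso <- genome_fst(simulate_divergence(base(0), n_reps = 8))
  f_mig <- genome_fst(simulate_divergence(base(0.02), n_reps = 8))
  expect_lt(mean(f_mig, na.rm = TRUE), mean(f_iso, na.rm = TRUE))
})

test_that("structured fixture calibration and hybrid construction", {
  expect_error(make_structured_fixture(fst_target = 0.96), "0.95")
  expect_error(make_structured_fixture(n_per_group = 1), "n_per_group")
  fx0 <- make_structured_fixture(n_per_group = 20, n_variants = 2000,
                                 fst_target = 0, seed = 12)
  g0 <- fixture_groups(fx0)
  expect_lt(abs(wc_fst(fx0$gm, g0$a, g0$b)), 0.02)
  fx <- make_structured_fixture(n_per_group = 20, n_variants = 2000,
                                fst_target = 0.1, n_hybrids = 1, seed = 12)
  g <- fixture_groups(fx)
  expect_equal(wc_fst(fx$gm, g$a, g$b), 0.1, tolerance = 0.2)
  expect_equal(sum(fx$labels$is_hybrid), 1)
  expect_equal(nrow(fx$gm$dosage), 41)
})

test_that("F84 simulator: zero branches, consistency, NJ topology recovery", {
  tz <- ape::read.tree(text = "(a:0,b:0,c:0);")
  aln <- simulate_f84_sequences(tz, seq_len = 300, seed = 1)
  expect_true(all(aln["a", ] == aln["b", ]) && all(aln["b", ] == aln["c", ]))
  expect_error(simulate_f84_sequences(tz, seq_len = 0), "zero-length")
  expect_error(simulate_f84_sequences(tz, base_freqs = c(0.5, 0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(simulate_f84_sequences(tz, ts_tv_ratio = 0.01), "floor")
  # four-taxon topology recovery across seeds
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05);")
  wins <- 0
  for (s in 1:100) {
    a4 <- simulate_f84_sequences(tr, base_freqs = c(0.3, 0.2, 0.2, 0.3),
                                 ts_tv_ratio = 2, seq_len = 2000, seed = s)
    nj <- neighbor_joining(f84_distance_matrix(a4))
    split_ab <- ape::cophenetic.phylo(nj)
    # correct topology iff the a-b path is shorter than a-c and a-d
    wins <- wins + (split_ab["a", "b"] < split_ab["a", "c"] &&
                      split_ab["a", "b"] < split_ab["a", "d"])
  }
  expect_gte(wins, 95)
})
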