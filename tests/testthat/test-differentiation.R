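make_gm <- function(dosage, chrom_len = NULL) {
  n <- ncol(dosage)
  genotype_matrix(dosage, sprintf("s%02d", seq_len(nrow(dosage))),
                  data.frame(chrom = "chr1", pos = seq_len(n) * 100L,
                             ref = "A", alt = "T"),
                  chrom_lengths = c(chr1 = if (is.null(chrom_len))
                    n * 100 + 100 else chrom_len))
}

test_that("WC F_ST handles fixed differences and identical groups", {
  gm <- make_gm(matrix(c(rep(0, 4), rep(2, 4)), 8, 1))
  expect_equal(wc_fst(gm, 1:4, 5:8), 1)
  # identical genotype composition in both groups: no between component
  dos <- matrix(rep(c(0, 1, 1, 2), 2), 8, 3)
  gm2 <- make_gm(dos)
  comp <- wc_components(gm2, 1:4, 5:8)
  expect_true(all(comp$a <= 1e-12))
  expect_lte(wc_fst(gm2, 1:4, 5:8), 0)
})

test_that("WC components match the frozen hand-computed example", {
  # groupA {0/0, 0/1}, groupB {0/1, 1/1}
  gm <- make_gm(matrix(c(0, 1, 1, 2), 4, 1))
  comp <- wc_components(gm, 1:2, 3:4)
  expect_equal(comp$a, 0.0625)
  expect_equal(comp$b, 0)
  expect_equal(comp$c, 0.25)
  expect_equal(wc_fst(gm, 1:2, 3:4), 0.2)
  # and agrees with the independent ANOVA oracle
  expect_equal(unname(oracle_wc_site(c(0, 1), c(1, 2))),
               c(0.0625, 0, 0.25))
})

test_that("WC F_ST equals the brute-force oracle on random instances", {
  for (seed in 1:200) {
    inst <- random_gm_instance(seed)
    got <- tryCatch(wc_fst(inst$gm, inst$group_a, inst$group_b),
                    error = function(e) NA_real_)
    want <- oracle_wc_fst(inst$gm$dosage[match(inst$group_a, inst$gm$samples), ,
                                         drop = FALSE],
                          inst$gm$dosage[match(inst$group_b, inst$gm$samples), ,
                                         drop = FALSE])
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("D_XY matches closed forms and is additive over windows", {
  # fixed difference in a 1000 bp window
  gm <- make_gm(matrix(c(0, 0, 2, 2), 4, 1), chrom_len = 1000)
  w <- make_windows(c(chr1 = 1000), 1000, 1000)
  expect_equal(window_dxy(gm, 1:2, 3:4, w)$dxy, 0.001)
  # identical monomorphic groups -> 0
  gm0 <- make_gm(matrix(2, 4, 3), chrom_len = 1000)
  expect_equal(window_dxy(gm0, 1:2, 3:4, w)$dxy, 0)
  # pA = 0.5, pB = 0.25 single site, 100 bp window
  gm1 <- genotype_matrix(matrix(c(1, 1, 1, 0), 4, 1), letters[1:4],
                         data.frame(chrom = "chr1", pos = 50L, ref = "A",
                                    alt = "T"),
                         chrom_lengths = c(chr1 = 100))
  w100 <- make_windows(c(chr1 = 100), 100, 100)
  expect_equal(window_dxy(gm1, 1:2, 3:4, w100)$dxy, 0.005)
  # additivity: window numerators sum to the chromosome-wide numerator
  fx <- make_structured_fixture(n_per_group = 8, n_variants = 200,
                                fst_target = 0.15, seed = 9,
                                chrom_len = 2e5)
  g <- fixture_groups(fx)
  wins <- make_windows(fx$gm$chrom_lengths, 2e4, 2e4)
  dxy <- window_dxy(fx$gm, g$a, g$b, wins)
  whole <- window_dxy(fx$gm, g$a, g$b, make_windows(fx$gm$chrom_lengths,
                                                    2e5, 2e5))
  expect_equal(sum(dxy$dxy * (dxy$end - dxy$start)),
               whole$dxy * 2e5, tolerance = 1e-12)
  expect_error(window_dxy(fx$gm, character(0), g$b, wins), "empty")
})

test_that("permutation test follows the (k+1)/(B+1) convention", {
  fx <- make_structured_fixture(n_per_group = 10, n_variants = 300,
                                fst_target = 0.4, seed = 3)
  g <- fixture_groups(fx)
  pt <- permutation_test(fx$gm, g$a, g$b, B = 100, seed = 11)
  expect_identical(pt$p_empirical, 1 / 101)
  expect_lt(pt$p_empirical, 0.01)
  expect_true(all(pt$null_values < pt$observed))
  # formula holds whatever the configuration
  fx0 <- make_structured_fixture(n_per_group = 6, n_variants = 50,
                                 fst_target = 0, seed = 4)
  g0 <- fixture_groups(fx0)
  pt0 <- permutation_test(fx0$gm, g0$a, g0$b, B = 37, seed = 2)
  expect_equal(pt0$p_empirical,
               (1 + sum(pt0$null_values >= pt0$observed)) / 38)
  expect_gt(pt0$p_empirical, 0)
  expect_lte(pt0$p_empirical, 1)
  # reproducible and invariant to sample order within groups
  pt1 <- permutation_test(fx$gm, g$a, g$b, B = 20, seed = 7)
  pt2 <- permutation_test(fx$gm, rev(g$a), rev(g$b), B = 20, seed = 7)
  expect_identical(pt1$null_values, pt2$null_values)
  expect_identical(pt1$observed, pt2$observed)
})

test_that("window significance: construction power and BH with m = 1", {
  fx <- make_structured_fixture(n_per_group = 15, n_variants = 600,
                                fst_target = 0.2, seed = 6, chrom_len = 6e5)
  g <- fixture_groups(fx)
  wins <- make_windows(fx$gm$chrom_lengths, 3e4, 3e4) # 20 windows
  ws <- window_significance(fx$gm, g$a, g$b, wins, B_window = 199, seed = 8)
  expect_gte(mean(ws$significant), 0.95)
  expect_true(all(ws$q_value >= ws$p_value - 1e-12))
  # single-window family: q = p
  w1 <- make_windows(fx$gm$chrom_lengths, 6e5, 6e5)
  ws1 <- window_significance(fx$gm, g$a, g$b, w1, B_window = 99, seed = 8)
  expect_equal(ws1$q_value, ws1$p_value)
})

test_that("GD classifier applies the strict > 90% rule", {
  mk <- function(q, fst = 0.1) data.frame(
    chrom = "c", start = seq_along(q), end = seq_along(q) + 1,
    untruncated = TRUE, n_snps = 5, fst = fst, p_value = q, q_value = q)
  gd <- gd_classify(mk(c(rep(0.01, 249), 0.5)))
  expect_equal(gd$frac_significant, 0.996)
  expect_equal(gd$frac_positive, 1)
  expect_true(gd$gd_flag)
  # exactly 0.90 -> not GD (strict inequality)
  gd90 <- gd_classify(mk(c(rep(0.01, 9), 0.5)))
  expect_equal(gd90$frac_significant, 0.9)
  expect_false(gd90$gd_flag)
  # all F_ST <= 0
  gd0 <- gd_classify(mk(rep(0.8, 10), fst = -0.01))
  expect_equal(gd0$frac_positive, 0)
  expect_false(gd0$gd_flag)
})

test_that("region report ranks a region within its chromosome", {
  ws <- data.frame(chrom = "c1", start = seq(0, 300, 100),
                   end = seq(100, 400, 100), untruncated = TRUE,
                   n_snps = 5, fst = c(0.1, 0.2, 0.3, 0.4))
  med <- region_report(ws, "c1", 100, 200) # the 0.2 window
  expect_equal(med$percentile, 50)
  top <- region_report(ws, "c1", 300, 400)
  expect_equal(top$percentile, 100)
  expect_error(region_report(ws, "c1", 1000, 1100), "no window")
  expect_error(region_report(ws, "c9", 0, 100), "not present")
})

test_that("median realized F_ST rises with the divergence parameter", {
  med_fst <- vapply(c(0.05, 0.15, 0.3), function(t) {
    median(vapply(1:5, function(s) {
      fx <- make_structured_fixture(n_per_group = 10, n_variants = 300,
                                    fst_target = t, seed = 100 + s)
      g <- fixture_groups(fx)
      wc_fst(fx$gm, g$a, g$b)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_fst) > 0))
})
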