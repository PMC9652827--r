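test_that("F84 distance: identity, symmetry, saturation, reference check", {
  s1 <- rep(c("A", "C", "G", "T"), 25)
  expect_equal(f84_distance(s1, s1), 0)
  s2 <- s1; s2[1:5] <- c("G", "T", "A", "C", "A")
  d12 <- f84_distance(s1, s2)
  expect_gt(d12, 0)
  expect_equal(d12, f84_distance(s2, s1))
  # complementary saturated pair
  comp <- c(A = "T", C = "G", G = "C", T = "A")[s1]
  expect_error(f84_distance(s1, comp), class = "f84_saturation")
  # gap/ambiguity columns excluded pairwise
  s3 <- s2; s3[6] <- "-"; s3[7] <- "N"
  expect_equal(f84_distance(s1, s3),
               f84_distance(s1[-c(6, 7)], s2[-c(6, 7)]))
  # agreement with the reference implementation on simulated sequences
  tr <- ape::read.tree(text = "(x:0.06,y:0.06);")
  aln <- simulate_f84_sequences(tr, base_freqs = c(0.3, 0.2, 0.2, 0.3),
                                ts_tv_ratio = 3, seq_len = 5000, seed = 2)
  mine <- f84_distance(aln["x", ], aln["y", ])
  ref <- as.numeric(ape::dist.dna(aln, model = "F84"))
  expect_equal(mine, ref, tolerance = 1e-8)
})

test_that("F84 distance estimator is consistent on simulated pairs", {
  tr <- ape::read.tree(text = "(x:0.05,y:0.05);")
  ests <- vapply(1:40, function(s) {
    aln <- simulate_f84_sequences(tr, base_freqs = c(0.35, 0.15, 0.15, 0.35),
                                  ts_tv_ratio = 2, seq_len = 10000, seed = s)
    f84_distance(aln["x", ], aln["y", ])
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.10), 3 * se)
})

test_that("neighbor joining solves n = 3 exactly and recovers additivity", {
  D3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(D3)
  # three-point equations: la = (dab + dac - dbc)/2 etc.
  el <- setNames(t3$edge.length,
                 c(t3$tip.label, "")[t3$edge[, 2]])
  expect_equal(unname(el[c("a", "b", "c")]), c(1, 2, 4))
  # additive 4-taxon matrix: exact topology and path lengths
  true_tree <- ape::read.tree(text = "((a:2,b:3):1,(c:4,d:5):1);")
  D4 <- ape::cophenetic.phylo(true_tree)
  t4 <- neighbor_joining(D4)
  expect_true(ape::is.monophyletic(ape::unroot(t4), c("a", "b")))
  got <- ape::cophenetic.phylo(t4)
  expect_equal(got[rownames(D4), colnames(D4)], D4, tolerance = 1e-9)
  # degenerate equal-distance matrix resolves deterministically
  De <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(De) <- 0
  e1 <- neighbor_joining(De)
  e2 <- neighbor_joining(De)
  expect_identical(ape::write.tree(e1), ape::write.tree(e2))
  expect_error(neighbor_joining(matrix(c(0, NA, NA, 0), 2, 2)), "3 taxa")
  Dn <- D3; Dn[1, 2] <- NA
  expect_error(neighbor_joining(Dn), "NA")
})

make_tpi_fixture <- function(seed = 10, n_per_group = 12, flip_one = FALSE) {
  set.seed(seed)
  n_var <- 15
  p1 <- runif(n_var, 0.9, 0.99)
  dos <- rbind(t(replicate(n_per_group, rbinom(n_var, 2, p1))),
               t(replicate(n_per_group, rbinom(n_var, 2, 1 - p1))))
  samples <- c(sprintf("C%02d", 1:n_per_group), sprintf("R%02d", 1:n_per_group))
  gm <- genotype_matrix(dos, samples,
                        data.frame(chrom = "chrZ", pos = seq_len(n_var) * 100L,
                                   ref = "A", alt = "T"),
                        chrom_lengths = c(chrZ = 2000), z_chroms = "chrZ")
  list(gm = gm, truth = rep(c("C", "R"), each = n_per_group))
}

test_that("TPI assignment recovers planted strains via locus PCA", {
  fx <- make_tpi_fixture(10)
  refs <- setNames(c("C", "C", "R", "R"), c("C01", "C02", "R01", "R02"))
  locus <- list(chrom = "chrZ", start = 0, end = 2000)
  calls <- tpi_assign(fx$gm, locus, refs)
  expect_equal(calls$tpi_strain, fx$truth)
  # order invariance
  perm <- sample(length(fx$gm$samples))
  calls_p <- tpi_assign(subset_gm(fx$gm, samples = perm), locus, refs)
  expect_equal(calls_p$tpi_strain[match(calls$sample_id, calls_p$sample_id)],
               calls$tpi_strain)
  # non-diagnostic locus (single cluster) is an error
  pan <- make_structured_fixture(n_per_group = 10, n_variants = 15,
                                 fst_target = 0, seed = 3, chrom = "chrZ",
                                 chrom_len = 2000)
  refs_pan <- setNames(c("C", "R"), pan$labels$sample_id[c(1, 11)])
  expect_error(tpi_assign(pan$gm, locus, refs_pan), "not diagnostic")
  # fewer than 3 polymorphic variants is an error
  expect_error(tpi_assign(subset_gm(fx$gm, variants = 1:2), locus, refs),
               "polymorphic")
})

test_that("COX1 assignment: nearest reference with margin and tie rules", {
  tr <- ape::read.tree(text = paste0(
    "((q1:0.004,q2:0.004,refC1:0.004,refC2:0.004):0.06,",
    "(q3:0.004,q4:0.004,refR1:0.004,refR2:0.004):0.06);"))
  aln <- simulate_f84_sequences(tr, base_freqs = c(0.3, 0.2, 0.15, 0.35),
                                ts_tv_ratio = 3, seq_len = 1500, seed = 5)
  labels <- setNames(c("C", "C", "R", "R"),
                     c("refC1", "refC2", "refR1", "refR2"))
  res <- cox1_assign(aln[paste0("q", 1:4), ], aln[names(labels), ], labels)
  expect_equal(res$calls$cox1_strain, c("C", "C", "R", "R"))
  expect_true(all(res$calls$evidence > 0))
  expect_s3_class(res$tree, "phylo")
  # query identical to a C reference
  res_id <- cox1_assign(aln["refC1", , drop = FALSE],
                        aln[names(labels), ], labels)
  expect_equal(res_id$calls$cox1_strain, "C")
  expect_gt(res_id$calls$evidence, 0)
  # exactly equidistant query -> ambiguous
  s <- rep(c("A", "C", "G", "T"), 50)
  idxA <- which(s == "A")
  S1 <- idxA[1:10]; S2 <- idxA[11:20]
  refC <- s; refC[S1] <- "G"
  refR <- s; refR[S2] <- "G"
  q <- s; q[c(S1[1:5], S2[1:5])] <- "G" # 10 A<->G diffs to each reference
  eq <- cox1_assign(rbind(q = q), rbind(refC = refC, refR = refR),
                    c(refC = "C", refR = "R"))
  expect_equal(eq$calls$cox1_strain, "ambiguous")
})

test_that("simulated two-clade assignment is fully concordant over seeds", {
  labels <- setNames(c("C", "C", "R", "R"),
                     c("refC1", "refC2", "refR1", "refR2"))
  hits <- 0
  for (s in 1:20) {
    tr <- ape::read.tree(text = paste0(
      "((q1:0.005,q2:0.005,refC1:0.005,refC2:0.005):0.05,",
      "(q3:0.005,q4:0.005,refR1:0.005,refR2:0.005):0.05);"))
    aln <- simulate_f84_sequences(tr, base_freqs = c(0.31, 0.17, 0.14, 0.38),
                                  ts_tv_ratio = 4, seq_len = 1200, seed = s)
    res <- cox1_assign(aln[paste0("q", 1:4), ], aln[names(labels), ], labels)
    hits <- hits + all(res$calls$cox1_strain == c("C", "C", "R", "R"))
  }
  expect_equal(hits, 20)
})
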