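#' Nuclear strain assignment from a diagnostic locus (TPI-style)
#'
#' Mirrors the locus-restricted PCA approach to host-strain calling: PCA on
#' the variants inside the diagnostic locus (e.g. the Z-linked TPI gene),
#' 2-means split on PC1, clusters mapped to strain labels through reference
#' samples of known strain. Samples within half a (pooled within-cluster)
#' standard deviation of the midpoint between cluster centers are labeled
#' ambiguous.
#'
#' @param gm a [genotype_matrix()].
#' @param locus list or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open) delimiting the diagnostic locus.
#' @param reference_labels named character vector `sample_id -> strain` with
#'   at least one reference per strain.
#' @param ambig_sd ambiguity half-width in units of the pooled within-cluster
#'   SD (default 0.5).
#' @return Data frame with `sample_id`, `tpi_strain` (strain label or
#'   `"ambiguous"`) and `evidence` (PC1 score).
#' @export
tpi_assign <- function(gm, locus, reference_labels, ambig_sd = 0.5) {
  strains <- unique(reference_labels)
  if (length(strains) < 2)
    stop("need references for at least two strains")
  in_locus <- gm$variants$chrom == locus$chrom[1] &
    (gm$variants$pos - 1) >= locus$start[1] &
    (gm$variants$pos - 1) < locus$end[1]
  sub <- subset_gm(gm, variants = in_locus)
  p <- allele_freq(sub)
  if (sum(!is.na(p) & p > 0 & p < 1) < 3)
    stop("locus contains fewer than 3 polymorphic variants")
  pc1 <- genotype_pca(sub, 1)$coordinates[, 1]
  km <- split_1d_2means(pc1)
  ref_idx <- match(names(reference_labels), gm$samples)
  if (anyNA(ref_idx)) stop("unknown reference sample(s)")
  ref_cluster <- km$cluster[ref_idx]
  cl_of <- vapply(strains, function(s)
    unique(ref_cluster[reference_labels == s]), numeric(1))
  if (anyDuplicated(cl_of) || any(vapply(strains, function(s)
    length(unique(ref_cluster[reference_labels == s])) != 1, logical(1))))
    stop("reference strains do not separate into distinct clusters: ",
         "locus not diagnostic")
  strain_of_cluster <- setNames(strains[order(cl_of)], sort(cl_of))
  mid <- mean(km$centers)
  calls <- strain_of_cluster[as.character(km$cluster)]
  dist_mid <- abs(pc1 - mid)
  ambiguous <- dist_mid < ambig_sd * km$within_sd | dist_mid == 0
  calls[ambiguous] <- "ambiguous"
  data.frame(sample_id = gm$samples, tpi_strain = unname(calls),
             evidence = unname(pc1), stringsAsFactors = FALSE)
}

# exact 1-D 2-means: minimize within-cluster SS over all sorted splits;
# deterministic (first minimizing split in sorted order)
split_1d_2means <- function(x) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  ss <- function(lo_n, lo_s, lo_s2) lo_s2 - lo_s^2 / lo_n
  tot_s <- cs[n]; tot_s2 <- cs2[n]
  wss <- vapply(seq_len(n - 1), function(k)
    ss(k, cs[k], cs2[k]) + ss(n - k, tot_s - cs[k], tot_s2 - cs2[k]),
    numeric(1))
  k <- which.min(wss)
  cluster <- integer(n)
  cluster[o] <- rep(1:2, c(k, n - k))
  centers <- c(mean(xs[seq_len(k)]), mean(xs[(k + 1):n]))
  within_sd <- if (n > 2) sqrt(wss[k] / (n - 2)) else 0
  list(cluster = cluster, centers = centers, within_sd = within_sd)
}

#' Maximum-likelihood F84 distance between two aligned sequences
#'
#' Closed-form F84 distance from the transition proportion `P`, transversion
#' proportion `Q` and base frequencies (pooled empirical over the two
#' sequences by default). Alignment columns containing gaps or ambiguity
#' codes are excluded pairwise. When a logarithm argument drops to or below
#' zero the distance is undefined (saturation) and an error of class
#' `f84_saturation` is signaled.
#'
#' @param seq_a,seq_b equal-length aligned sequences: character vectors of
#'   bases or `DNAbin` rows.
#' @param base_freqs optional base frequencies (A, C, G, T order) overriding
#'   the pooled empirical frequencies.
#' @return Distance in substitutions/site.
#' @export
f84_distance <- function(seq_a, seq_b, base_freqs = NULL) {
  a <- as_base_vector(seq_a)
  b <- as_base_vector(seq_b)
  if (length(a) != length(b)) stop("sequences must have equal aligned length")
  nt <- c("A", "C", "G", "T")
  use <- a %in% nt & b %in% nt
  a <- a[use]; b <- b[use]
  L <- length(a)
  if (!L) stop("no comparable alignment columns")
  if (is.null(base_freqs)) {
    tab <- table(factor(c(a, b), levels = nt))
    base_freqs <- as.numeric(tab) / sum(tab)
  }
  pi_a <- base_freqs[1]; pi_c <- base_freqs[2]
  pi_g <- base_freqs[3]; pi_t <- base_freqs[4]
  pi_r <- pi_a + pi_g; pi_y <- pi_c + pi_t
  diff <- a != b
  transition <- diff & ((a %in% c("A", "G") & b %in% c("A", "G")) |
                          (a %in% c("C", "T") & b %in% c("C", "T")))
  P <- sum(transition) / L
  Q <- sum(diff & !transition) / L
  A <- pi_a * pi_g / pi_r + pi_c * pi_t / pi_y
  B <- pi_a * pi_g + pi_c * pi_t
  C <- pi_r * pi_y
  arg1 <- 1 - P / (2 * A) - (A - B) * Q / (2 * A * C)
  arg2 <- 1 - Q / (2 * C)
  if (arg1 <= 0 || arg2 <= 0)
    stop(structure(class = c("f84_saturation", "error", "condition"),
                   list(message = "F84 distance undefined: saturated divergence",
                        call = sys.call(-1))))
  -2 * A * log(arg1) + 2 * (A - B - C) * log(arg2)
}

#' Pairwise F84 distance matrix
#'
#' Saturated pairs yield `NA` with a warning.
#'
#' @param seqs named list/matrix of aligned sequences (or a `DNAbin`
#'   alignment).
#' @param base_freqs optional fixed base frequencies (A, C, G, T).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
f84_distance_matrix <- function(seqs, base_freqs = NULL) {
  seqs <- as_seq_list(seqs)
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- tryCatch(f84_distance(seqs[[i]], seqs[[j]], base_freqs),
                  f84_saturation = function(e) NA_real_)
    D[i, j] <- D[j, i] <- d
  }
  if (anyNA(D)) warning("saturated sequence pair(s): NA distances")
  D
}

as_base_vector <- function(s) {
  if (inherits(s, "DNAbin")) s <- as.character(s)
  if (is.matrix(s)) s <- s[1, ]
  toupper(as.character(s))
}

as_seq_list <- function(seqs) {
  if (inherits(seqs, "DNAbin")) seqs <- as.character(seqs)
  if (is.matrix(seqs)) {
    out <- lapply(seq_len(nrow(seqs)), function(i) seqs[i, ])
    names(out) <- rownames(seqs)
    return(out)
  }
  as.list(seqs)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining (rate-corrected join criterion,
#' usual branch-length split equations). Negative branch-length estimates
#' are clamped to zero; the pre-clamp values are kept in the
#' `pre_clamp_lengths` attribute.
#'
#' @param D symmetric numeric matrix with zero diagonal, `n >= 3`, no `NA`.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need at least 3 taxa")
  if (anyNA(D)) stop("distance matrix contains NA/NaN")
  if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0))
    stop("matrix must be symmetric with zero diagonal")
  tree <- ape::nj(D)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    attr(tree, "pre_clamp_lengths") <- tree$edge.length
    message(sum(neg), " negative branch length(s) clamped to 0")
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Mitochondrial strain assignment from COX1-like sequences
#'
#' Assigns each query to the strain of its nearest reference by F84
#' distance; the evidence margin is the gap between the nearest
#' other-strain reference and the nearest reference overall. A margin below
#' `epsilon` (including exact ties) yields `"ambiguous"`, as does saturation
#' against every reference. A neighbor-joining tree over all sequences is
#' returned for inspection, mirroring clade-based strain identification.
#'
#' @param query_seqs named aligned query sequences (list, matrix or
#'   `DNAbin`).
#' @param ref_seqs named aligned reference sequences (same length).
#' @param ref_labels named character vector `reference -> strain` (at least
#'   one reference per strain, two or more strains).
#' @param epsilon minimum margin (substitutions/site) below which the call is
#'   ambiguous (default 1e-9).
#' @param base_freqs optional fixed base frequencies (A, C, G, T).
#' @return List with `calls` (data frame `sample_id`, `cox1_strain`,
#'   `evidence` = margin) and `tree` (NJ `phylo` over all sequences, or
#'   `NULL` if distances are incomplete).
#' @export
cox1_assign <- function(query_seqs, ref_seqs, ref_labels, epsilon = 1e-9,
                        base_freqs = NULL) {
  q <- as_seq_list(query_seqs)
  r <- as_seq_list(ref_seqs)
  if (is.null(names(q))) names(q) <- sprintf("query%02d", seq_along(q))
  ref_labels <- ref_labels[names(r)]
  if (length(unique(ref_labels)) < 2)
    stop("need references from at least two strains")
  calls <- lapply(names(q), function(qn) {
    d <- vapply(r, function(rs)
      tryCatch(f84_distance(q[[qn]], rs, base_freqs),
               f84_saturation = function(e) NA_real_), numeric(1))
    if (all(is.na(d))) {
      warning("query ", qn, " saturated against all references")
      return(data.frame(sample_id = qn, cox1_strain = "ambiguous",
                        evidence = NA_real_, stringsAsFactors = FALSE))
    }
    best <- names(which.min(d))
    best_strain <- ref_labels[[best]]
    d_best <- min(d, na.rm = TRUE)
    other <- d[ref_labels != best_strain]
    d_other <- if (all(is.na(other))) Inf else min(other, na.rm = TRUE)
    margin <- d_other - d_best
    strain <- if (is.finite(margin) && margin < epsilon) "ambiguous"
    else best_strain
    data.frame(sample_id = qn, cox1_strain = strain,
               evidence = margin, stringsAsFactors = FALSE)
  })
  all_seqs <- c(q, r)
  tree <- NULL
  if (length(all_seqs) >= 3) {
    D <- suppressWarnings(f84_distance_matrix(all_seqs, base_freqs))
    if (!anyNA(D)) tree <- neighbor_joining(D)
  }
  list(calls = do.call(rbind, calls), tree = tree)
}
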