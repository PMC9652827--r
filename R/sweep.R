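#' Build a (folded) site frequency spectrum for a group
#'
#' Tallies per-site minor-allele counts into folded frequency classes
#' `1..floor(n/2)` (or derived-allele classes `1..n-1` when `folded = FALSE`,
#' taking the alternate allele as derived). Sites monomorphic within the
#' group and sites with missing genotypes in the group are excluded.
#'
#' @param gm a [genotype_matrix()].
#' @param group sample IDs (or indices) of the group.
#' @param folded fold the spectrum (default `TRUE`; no ancestral-state
#'   polarization is assumed).
#' @return An object of class `sfs`: list with `n` (haploid sample size),
#'   `counts` (per-class site counts), `folded`, and `site_class` /
#'   `site_index` giving each retained site's class and variant column.
#' @export
build_sfs <- function(gm, group, folded = TRUE) {
  if (!length(group)) stop("empty group")
  dos <- group_dosage(gm, group)
  if (nrow(dos) < 1) stop("empty group")
  n <- 2L * nrow(dos)
  complete <- colSums(is.na(dos)) == 0
  ac <- colSums(dos, na.rm = TRUE)
  seg <- complete & ac > 0 & ac < n
  idx <- which(seg)
  cls <- if (folded) pmin(ac[idx], n - ac[idx]) else ac[idx]
  n_classes <- if (folded) floor(n / 2) else n - 1L
  counts <- tabulate(cls, nbins = n_classes)
  structure(list(n = n, counts = counts, folded = folded,
                 site_class = as.integer(cls), site_index = idx),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("%s SFS: n = %d haplotypes, %d segregating sites, %d classes\n",
              if (x$folded) "folded" else "unfolded", x$n, sum(x$counts),
              length(x$counts)))
  invisible(x)
}

#' Composite-likelihood-ratio scan for selective sweeps
#'
#' SweepFinder/SweeD-family scan: at each of `grid_n` evenly spaced grid
#' points per chromosome, the composite likelihood of the chromosome's data
#' is computed under a sweep model and compared with the background
#' (whole-chromosome) site frequency spectrum. Every position is treated as
#' a site: polymorphic with the background probability `pi0 = S/L` and class
#' probabilities from the background spectrum. Under a sweep centered at the
#' grid point, a position at distance `d` is caught by the sweep with
#' probability `w(d) = lambda exp(-alpha d)` -- `1 - exp(-alpha d)` being
#' the lineage escape probability and `lambda` the sweep intensity at the
#' center -- and a caught position is either wiped monomorphic (probability
#' `1 - rho`; the hitchhiking diversity deficit) or left as a lowest-class
#' variant (probability `rho`; recent post-sweep or migrant-derived rare
#' alleles). The composite likelihood is maximized over the
#' `alpha`/`lambda`/`rho` grids; `lambda -> 0` (or `alpha -> Inf`) recovers
#' the background model, so `CLR = 2 (max sweep log-CL - background log-CL)`
#' is nonnegative. The monomorphic positions' contribution is accumulated
#' analytically through the integral of `w` over the chromosome.
#'
#' @param gm a [genotype_matrix()].
#' @param group sample IDs of the scanned group.
#' @param grid_n grid points per chromosome (default 1000).
#' @param alpha_grid spatial decay rates of the sweep effect, per bp
#'   (default logarithmic over `[10^-6.5, 10^-2.5]`; `1/alpha` is the
#'   footprint scale in bp).
#' @param lambda_grid sweep intensities at the center, in `(0, 1]`.
#' @param rho_grid fraction of caught positions surfacing as lowest-class
#'   variants rather than monomorphic.
#' @param folded fold the spectrum (default `TRUE`).
#' @param min_sites chromosomes with fewer usable segregating sites are
#'   skipped with a warning (default 50).
#' @return An object of class `sweep_scan`: data frame with `chrom`,
#'   `grid_pos`, `clr`, `alpha_hat` (maximizing decay rate).
#' @export
clr_scan <- function(gm, group, grid_n = 1000,
                     alpha_grid = 10^seq(-6.5, -2.5, length.out = 14),
                     lambda_grid = c(0.5, 0.8, 0.95, 0.999),
                     rho_grid = c(0, 0.3, 1),
                     folded = TRUE, min_sites = 50) {
  out <- list()
  for (ch in names(gm$chrom_lengths)) {
    L <- gm$chrom_lengths[[ch]]
    sub <- subset_gm(gm, variants = gm$variants$chrom == ch)
    sfs <- build_sfs(sub, group, folded = folded)
    S <- sum(sfs$counts)
    if (S < min_sites) {
      warning("chromosome ", ch, " has fewer than ", min_sites,
              " usable sites; scan skipped")
      next
    }
    pi0 <- S / L
    p0 <- sfs$counts / S
    pos <- sub$variants$pos[sfs$site_index]
    p0_site <- p0[sfs$site_class]
    is_low <- as.numeric(sfs$site_class == 1L)
    grid <- round(seq(1, L, length.out = grid_n))
    fit <- clr_grid_cpp(as.numeric(pos), p0_site, is_low, as.numeric(grid),
                        as.numeric(L), as.numeric(alpha_grid),
                        as.numeric(lambda_grid), as.numeric(rho_grid), pi0)
    out[[ch]] <- data.frame(chrom = ch, grid_pos = grid,
                            clr = pmax(fit$clr, 0),
                            alpha_hat = fit$alpha_hat,
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no chromosome with enough sites to scan")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("sweep_scan", "data.frame")
  res
}

#' Group-specific sweep outliers
#'
#' Formalizes outlier calling across two groups: a grid point is an
#' A-specific outlier iff its robust z-score within scan A exceeds
#' `z_thresh` AND the nearest grid value in scan B lies at or below scan B's
#' `other_max_quantile` quantile (shared peaks, e.g. from background
#' selection, are thereby excluded). Adjacent outlier grid points are merged
#' into intervals, and intervals narrower than `min_points` grid points are
#' dropped: a sweep footprint spans many grid points at the default grid
#' spacing, whereas isolated single-point spikes are noise.
#'
#' The CLR null is zero-inflated and heavy-tailed, so the median/MAD scale
#' collapses; the robust scale is taken as the larger of the MAD and the
#' upper-quantile spread `(q90 - median) / 1.2816` (their Gaussian-consistent
#' forms agree for well-behaved data). If both are zero the scan is constant
#' and no outlier is called (with a warning).
#'
#' @param scan_a,scan_b `sweep_scan` objects over matching chromosomes.
#' @param z_thresh robust z-score threshold (default 6).
#' @param other_max_quantile quantile of the other group's scan that the
#'   nearest grid value must not exceed (default 0.9).
#' @param min_points minimum merged-interval width in grid points
#'   (default 3).
#' @param min_clr absolute CLR floor for an outlier point (default 20,
#'   beyond the extreme tail of the three-fitted-parameter chi-square null):
#'   however extreme relative to a flat scan, a likelihood ratio this small
#'   is not an obvious sweep.
#' @return List with `a` and `b`: data frames of merged outlier intervals
#'   (`chrom`, `start`, `end`, `n_points`, `max_clr`) specific to each group.
#' @export
group_specific_outliers <- function(scan_a, scan_b, z_thresh = 6,
                                    other_max_quantile = 0.9,
                                    min_points = 3, min_clr = 20) {
  chroms <- intersect(unique(scan_a$chrom), unique(scan_b$chrom))
  if (!length(chroms)) stop("scans share no chromosome")
  one_side <- function(sa, sb) {
    res <- list()
    for (ch in chroms) {
      a <- sa[sa$chrom == ch, , drop = FALSE]
      b <- sb[sb$chrom == ch, , drop = FALSE]
      med <- median(a$clr)
      s <- max(mad(a$clr),
               (quantile(a$clr, 0.9, names = FALSE) - med) / 1.2816)
      if (s == 0) {
        warning("CLR scan on ", ch, " has no spread; no outliers called")
        hit_a <- rep(FALSE, nrow(a))
      } else {
        hit_a <- (a$clr - med) / s > z_thresh
      }
      nearest <- vapply(a$grid_pos, function(p)
        b$clr[which.min(abs(b$grid_pos - p))], numeric(1))
      hit <- hit_a & a$clr > min_clr &
        nearest <= quantile(b$clr, other_max_quantile)
      ints <- merge_grid_intervals(a, hit)
      res[[ch]] <- ints[ints$n_points >= min_points, , drop = FALSE]
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  }
  list(a = one_side(scan_a, scan_b), b = one_side(scan_b, scan_a))
}

# merge runs of adjacent flagged grid points into [first, last+1) intervals
merge_grid_intervals <- function(scan_chr, hit) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_points = integer(),
                      max_clr = numeric(), stringsAsFactors = FALSE)
  if (!any(hit)) return(empty)
  idx <- which(hit)
  run_id <- cumsum(c(1, diff(idx) != 1))
  do.call(rbind, lapply(split(idx, run_id), function(ii)
    data.frame(chrom = scan_chr$chrom[1],
               start = scan_chr$grid_pos[ii[1]],
               end = scan_chr$grid_pos[ii[length(ii)]] + 1,
               n_points = length(ii),
               max_clr = max(scan_chr$clr[ii]),
               stringsAsFactors = FALSE)))
}

#' Classify a sweep interval by its differentiation signature
#'
#' A sweep interval is a reproductive-isolation candidate when it shows both
#' elevated relative differentiation (F_ST) and elevated absolute divergence
#' (D_XY): the interval means of both statistics exceed their chromosome's
#' 95th window percentile. Elevated F_ST without elevated D_XY is
#' "differentiation-only"; neither elevated is "background".
#'
#' @param interval one-row data frame (or list) with `chrom`, `start`, `end`.
#' @param fst_stats window table with an `fst` column (from [wc_fst()]).
#' @param dxy_stats window table with a `dxy` column (from [window_dxy()]).
#' @param prob percentile threshold as a probability (default 0.95).
#' @return List with `classification` (one of `"isolation-candidate"`,
#'   `"differentiation-only"`, `"background"`), the interval means and the
#'   chromosome thresholds.
#' @export
sweep_signature <- function(interval, fst_stats, dxy_stats, prob = 0.95) {
  ch <- interval$chrom[1]
  pick <- function(ws, col) {
    on_chr <- ws[ws$chrom == ch & !is.na(ws[[col]]), , drop = FALSE]
    ov <- on_chr$start < interval$end[1] & on_chr$end > interval$start[1]
    if (!any(ov)) stop("interval overlaps no window with data (", col, ")")
    list(mean = mean(on_chr[[col]][ov]),
         thresh = quantile(on_chr[[col]], prob, names = FALSE))
  }
  f <- pick(fst_stats, "fst")
  d <- pick(dxy_stats, "dxy")
  classification <- if (f$mean > f$thresh && d$mean > d$thresh)
    "isolation-candidate"
  else if (f$mean > f$thresh) "differentiation-only"
  else "background"
  list(classification = classification,
       fst_mean = f$mean, fst_threshold = f$thresh,
       dxy_mean = d$mean, dxy_threshold = d$thresh)
}
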