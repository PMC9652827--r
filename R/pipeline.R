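#' Assemble and validate a full-run configuration
#'
#' Collects every input and threshold of the full analysis: genotype data
#' (in-memory objects or VCF/metadata paths), optional strain-marker inputs,
#' window specification, permutation counts, GD/hybrid/outlier thresholds,
#' the global seed and the output directory.
#'
#' @param gm optional [genotype_matrix()] (alternative to `vcf`).
#' @param metadata optional metadata data frame (alternative to
#'   `metadata_path`); must contain `sample_id` and `population`.
#' @param vcf,metadata_path optional input file paths.
#' @param group_a,group_b population labels compared; default: the first two
#'   non-hybrid population values in the metadata.
#' @param tpi_locus optional list `chrom`, `start`, `end` for nuclear strain
#'   assignment.
#' @param tpi_refs optional named vector `sample_id -> strain`.
#' @param cox1_query,cox1_refs,cox1_labels optional aligned mitochondrial
#'   sequences and reference labels for [cox1_assign()].
#' @param window_size,window_step F_ST window size/step in bp.
#' @param dxy_step D_XY window step in bp (same window size).
#' @param B genome-wide permutation count; `B_window` per-window count.
#' @param alpha FDR level; `gd_threshold` GD fraction (strict).
#' @param hybrid_lo,hybrid_hi ancestry interval for hybrid flagging.
#' @param grid_n sweep-scan grid points per chromosome.
#' @param z_thresh,other_max_quantile outlier-calling thresholds.
#' @param seed global seed (fanned out per stage).
#' @param outdir output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(gm = NULL, metadata = NULL, vcf = NULL,
                       metadata_path = NULL, group_a = NULL, group_b = NULL,
                       tpi_locus = NULL, tpi_refs = NULL, cox1_query = NULL,
                       cox1_refs = NULL, cox1_labels = NULL,
                       window_size = 5e5, window_step = 5e5, dxy_step = 1e5,
                       B = 100, B_window = 199, alpha = 0.05,
                       gd_threshold = 0.90, hybrid_lo = 0.35,
                       hybrid_hi = 0.65, grid_n = 1000, z_thresh = 6,
                       other_max_quantile = 0.9, seed = 1,
                       outdir = tempfile("fawpopgen_run")) {
  if (is.null(gm) && is.null(vcf)) stop("provide gm or a vcf path")
  for (p in c(vcf, metadata_path))
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  stopifnot(alpha > 0, alpha < 1, gd_threshold > 0, gd_threshold < 1,
            hybrid_lo < hybrid_hi, B >= 1, B_window >= 19, grid_n >= 2)
  structure(list(gm = gm, metadata = metadata, vcf = vcf,
                 metadata_path = metadata_path, group_a = group_a,
                 group_b = group_b, tpi_locus = tpi_locus,
                 tpi_refs = tpi_refs, cox1_query = cox1_query,
                 cox1_refs = cox1_refs, cox1_labels = cox1_labels,
                 window_size = window_size, window_step = window_step,
                 dxy_step = dxy_step, B = B, B_window = B_window,
                 alpha = alpha, gd_threshold = gd_threshold,
                 hybrid_lo = hybrid_lo, hybrid_hi = hybrid_hi,
                 grid_n = grid_n, z_thresh = z_thresh,
                 other_max_quantile = other_max_quantile,
                 seed = seed, outdir = outdir),
            class = "run_config")
}

# hash of every analysis-relevant config field (the output location is
# excluded so identical analyses hash identically wherever they are written)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "outdir")]), tmp)
  unname(tools::md5sum(tmp))
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + sum(utf8ToInt(stage))) %% 2147483647L
}

#' Run the full host-strain divergence analysis
#'
#' Executes the stages in order -- load, strain identification, structure
#' (PCA + ancestry + hybrid flags), genome-wide differentiation with the
#' random-grouping permutation test, windowed significance with the GD
#' classifier and D_XY, and the sweep scan with group-specific outliers and
#' signature classification -- writing every stage output as TSV under
#' `config$outdir` together with a manifest (stage, status, row counts,
#' timing, config hash, per-stage seed). Any stage error aborts with the
#' stage name; outputs of completed stages are preserved. Re-running with an
#' identical config reproduces identical statistic tables.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `manifest`, `config_hash` and the main
#'   in-memory results (`gm`, `straincalls`, `table1`, `pca`, `ancestry`,
#'   `hybrids`, `permutation`, `window_fst`, `window_dxy`, `gd`, `scans`,
#'   `outliers`, `signatures`).
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  manifest <- data.frame(stage = character(), status = character(),
                         rows = integer(), seed = integer(),
                         stringsAsFactors = FALSE)
  res <- list(config_hash = hash)
  run_stage <- function(name, fn) {
    seed <- stage_seed(config$seed, name)
    out <- tryCatch(fn(seed), error = function(e) {
      write_tsv(manifest, file.path(config$outdir, "manifest.tsv"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest <<- rbind(manifest, data.frame(
      stage = name, status = "completed", rows = out$rows, seed = seed,
      stringsAsFactors = FALSE))
    out$value
  }

  loaded <- run_stage("load", function(seed) {
    if (is.null(config$gm)) {
      rv <- read_vcf(config$vcf, config$metadata_path)
      gm <- rv$gm; metadata <- rv$metadata
    } else {
      gm <- config$gm; metadata <- config$metadata
    }
    if (is.null(metadata)) stop("metadata required")
    list(value = list(gm = gm, metadata = metadata), rows = nrow(gm$variants))
  })
  gm <- loaded$gm
  metadata <- loaded$metadata
  res$gm <- gm
  pops <- setdiff(unique(metadata$population), "hybrid")
  group_a_label <- if (is.null(config$group_a)) pops[1] else config$group_a
  group_b_label <- if (is.null(config$group_b)) pops[2] else config$group_b
  group_a <- metadata$sample_id[metadata$population == group_a_label]
  group_b <- metadata$sample_id[metadata$population == group_b_label]

  res$straincalls <- run_stage("strain_id", function(seed) {
    calls <- data.frame(sample_id = gm$samples, stringsAsFactors = FALSE)
    if (!is.null(config$tpi_locus) && !is.null(config$tpi_refs)) {
      tpi <- tpi_assign(gm, config$tpi_locus, config$tpi_refs)
      calls <- merge(calls, tpi[, c("sample_id", "tpi_strain")],
                     by = "sample_id", all.x = TRUE, sort = FALSE)
    }
    if (!is.null(config$cox1_query) && !is.null(config$cox1_refs)) {
      cox <- cox1_assign(config$cox1_query, config$cox1_refs,
                         config$cox1_labels)
      calls <- merge(calls, cox$calls[, c("sample_id", "cox1_strain")],
                     by = "sample_id", all.x = TRUE, sort = FALSE)
    }
    calls <- calls[match(gm$samples, calls$sample_id), , drop = FALSE]
    write_tsv(calls, file.path(config$outdir, "straincalls.tsv"))
    t1 <- summarize_table1(calls, metadata)
    write_tsv(t1, file.path(config$outdir, "table1.tsv"))
    list(value = calls, rows = nrow(calls))
  })
  res$table1 <- summarize_table1(res$straincalls, metadata)

  st <- run_stage("structure", function(seed) {
    pca <- genotype_pca(gm, 4)
    anc <- ancestry_coefficients(gm, K = 2, seed = seed)
    hyb <- hybrid_flag(anc, config$hybrid_lo, config$hybrid_hi)
    df <- data.frame(sample_id = gm$samples,
                     PC1 = pca$coordinates[, 1],
                     PC2 = if (ncol(pca$coordinates) > 1)
                       pca$coordinates[, 2] else NA_real_,
                     Q1 = anc$Q[, 1], Q2 = anc$Q[, 2],
                     hybrid = hyb, stringsAsFactors = FALSE)
    write_tsv(df, file.path(config$outdir, "structure.tsv"))
    list(value = list(pca = pca, ancestry = anc, hybrids = hyb),
         rows = nrow(df))
  })
  res$pca <- st$pca; res$ancestry <- st$ancestry; res$hybrids <- st$hybrids

  res$permutation <- run_stage("differentiation", function(seed) {
    pt <- permutation_test(gm, group_a, group_b, B = config$B, seed = seed)
    write_tsv(data.frame(observed_fst = pt$observed, B = pt$B,
                         p_empirical = pt$p_empirical),
              file.path(config$outdir, "genomewide_fst.tsv"))
    write_tsv(data.frame(null_fst = pt$null_values),
              file.path(config$outdir, "permutation_null.tsv"))
    list(value = pt, rows = pt$B)
  })

  win <- run_stage("windows", function(seed) {
    w_fst <- make_windows(gm$chrom_lengths, config$window_size,
                          config$window_step)
    ws <- window_significance(gm, group_a, group_b, w_fst,
                              B_window = config$B_window,
                              alpha = config$alpha, seed = seed)
    gd <- gd_classify(ws, alpha = config$alpha,
                      threshold = config$gd_threshold)
    w_dxy <- make_windows(gm$chrom_lengths, config$window_size,
                          config$dxy_step, untruncated_only = FALSE)
    dxy <- window_dxy(gm, group_a, group_b, w_dxy)
    write_tsv(ws, file.path(config$outdir, "windows_fst.tsv"))
    write_tsv(dxy, file.path(config$outdir, "windows_dxy.tsv"))
    write_tsv(data.frame(frac_positive = gd$frac_positive,
                         frac_significant = gd$frac_significant,
                         gd_flag = gd$gd_flag, n_windows = gd$n_windows),
              file.path(config$outdir, "gd.tsv"))
    list(value = list(window_fst = ws, window_dxy = dxy, gd = gd),
         rows = nrow(ws))
  })
  res$window_fst <- win$window_fst
  res$window_dxy <- win$window_dxy
  res$gd <- win$gd

  sw <- run_stage("sweep", function(seed) {
    scan_a <- clr_scan(gm, group_a, grid_n = config$grid_n)
    scan_b <- clr_scan(gm, group_b, grid_n = config$grid_n)
    outl <- group_specific_outliers(scan_a, scan_b,
                                    z_thresh = config$z_thresh,
                                    other_max_quantile =
                                      config$other_max_quantile)
    classify <- function(ints, grp) {
      ints$classification <- vapply(seq_len(nrow(ints)), function(i)
        sweep_signature(ints[i, , drop = FALSE], res$window_fst,
                        res$window_dxy)$classification, character(1))
      ints$group <- rep(grp, nrow(ints))
      ints
    }
    out_a <- classify(outl$a, "a"); out_b <- classify(outl$b, "b")
    write_tsv(scan_a, file.path(config$outdir, "sweep_scan_a.tsv"))
    write_tsv(scan_b, file.path(config$outdir, "sweep_scan_b.tsv"))
    write_tsv(rbind(out_a, out_b),
              file.path(config$outdir, "sweep_outliers.tsv"))
    list(value = list(scans = list(a = scan_a, b = scan_b),
                      outliers = list(a = out_a, b = out_b)),
         rows = nrow(out_a) + nrow(out_b))
  })
  res$scans <- sw$scans
  res$outliers <- sw$outliers

  manifest$config_hash <- hash
  write_tsv(manifest, file.path(config$outdir, "manifest.tsv"))
  res$manifest <- manifest
  invisible(res)
}

#' Cross-tabulate strain calls by host-plant group
#'
#' Builds the concordance table of per-marker strain labels against the
#' metadata grouping: one row per (marker, strain, group) cell. Samples
#' without a call for a marker are counted in the `ambiguous` margin.
#'
#' @param straincalls data frame with `sample_id` and any of `tpi_strain`,
#'   `cox1_strain`.
#' @param metadata data frame with `sample_id` and the grouping column.
#' @param strains strain label set (default `c("C", "R")`).
#' @param group_col metadata column to tabulate against; defaults to
#'   `host_plant` if present, else `population`.
#' @return Data frame with columns `marker`, `strain`, `group`, `n`; cell
#'   sums per marker equal the sample count.
#' @export
summarize_table1 <- function(straincalls, metadata, strains = c("C", "R"),
                             group_col = NULL) {
  if (is.null(group_col))
    group_col <- if ("host_plant" %in% names(metadata)) "host_plant"
  else "population"
  markers <- intersect(c("tpi_strain", "cox1_strain"), names(straincalls))
  groups <- sort(unique(as.character(metadata[[group_col]])))
  levels <- c(strains, "ambiguous")
  out <- list()
  for (m in markers) {
    g <- metadata[[group_col]][match(straincalls$sample_id,
                                     metadata$sample_id)]
    s <- as.character(straincalls[[m]])
    s[is.na(s) | !(s %in% strains)] <- "ambiguous"
    tab <- table(factor(s, levels = levels),
                 factor(as.character(g), levels = groups))
    out[[m]] <- data.frame(marker = rep(sub("_strain$", "", m),
                                        length(tab)),
                           strain = rep(rownames(tab), ncol(tab)),
                           group = rep(colnames(tab), each = nrow(tab)),
                           n = as.integer(tab), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(marker = character(), strain = character(),
                      group = character(), n = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bundled synthetic demonstration dataset
#'
#' Generates, in code, a small complete input set for [run_full()]: a
#' structured two-population genotype matrix with one planted F1 hybrid, a
#' strongly diagnostic Z-linked locus standing in for the TPI marker, and
#' COX1-like mitochondrial alignments simulated under F84 on a two-clade
#' tree with labeled references.
#'
#' @param seed RNG seed.
#' @param n_per_group diploid samples per population (default 12).
#' @param n_variants autosomal SNVs (default 600).
#' @param fst_target autosomal differentiation target (default 0.2).
#' @return List with `gm`, `metadata`, `tpi_locus`, `tpi_refs`,
#'   `cox1_query`, `cox1_refs`, `cox1_labels` and `labels` (truth).
#' @export
demo_dataset <- function(seed = 42, n_per_group = 12, n_variants = 600,
                         fst_target = 0.2) {
  fx <- make_structured_fixture(n_per_group = n_per_group,
                                n_variants = n_variants,
                                fst_target = fst_target, n_hybrids = 1,
                                seed = seed)
  gm <- fx$gm
  set.seed(seed + 1)
  # Z-linked diagnostic locus: near-fixed differences between strains
  n_tpi <- 20
  p1 <- runif(n_tpi, 0.9, 0.99)
  p2 <- 1 - p1
  n_tot <- length(gm$samples)
  tpi_dos <- matrix(NA_integer_, n_tot, n_tpi)
  pop <- fx$labels$population
  for (i in seq_len(n_tot)) {
    tpi_dos[i, ] <- switch(pop[i],
      pop1 = rbinom(n_tpi, 2L, p1),
      pop2 = rbinom(n_tpi, 2L, p2),
      hybrid = rbinom(n_tpi, 1L, p1) + rbinom(n_tpi, 1L, p2))
  }
  tpi_var <- data.frame(chrom = "chrZ", pos = as.integer(seq(501, by = 500,
                                                             length.out = n_tpi)),
                        ref = "A", alt = "T", stringsAsFactors = FALSE)
  gm2 <- genotype_matrix(cbind(gm$dosage, tpi_dos), gm$samples,
                         rbind(gm$variants, tpi_var),
                         chrom_lengths = c(gm$chrom_lengths, chrZ = 20000),
                         z_chroms = "chrZ")
  metadata <- data.frame(
    sample_id = gm$samples,
    population = pop,
    host_plant = c(pop1 = "corn", pop2 = "grass", hybrid = "corn")[pop],
    site = "synthetic", stringsAsFactors = FALSE)
  tpi_refs <- setNames(c("C", "C", "R", "R"),
                       c(gm$samples[1], gm$samples[2],
                         gm$samples[n_per_group + 1],
                         gm$samples[n_per_group + 2]))
  # COX1-like alignment: two haplogroup clades, references in each
  n_q <- n_tot
  clade_of <- ifelse(pop == "pop2", "R", "C")
  tip_names <- c(paste0("q", seq_len(n_q)), "refC1", "refC2", "refR1", "refR2")
  newick <- paste0("((",
    paste(c(paste0("q", which(clade_of == "C")), "refC1", "refC2"),
          ":0.005", collapse = ","), "):0.05,(",
    paste(c(paste0("q", which(clade_of == "R")), "refR1", "refR2"),
          ":0.005", collapse = ","), "):0.05);")
  tree <- ape::read.tree(text = newick)
  aln <- simulate_f84_sequences(tree, base_freqs = c(0.31, 0.17, 0.14, 0.38),
                                ts_tv_ratio = 4, seq_len = 1200,
                                seed = seed + 2)
  rn <- rownames(aln)
  q_idx <- match(paste0("q", seq_len(n_q)), rn)
  cox1_query <- aln[q_idx, , drop = FALSE]
  rownames(cox1_query) <- gm$samples
  cox1_refs <- aln[match(c("refC1", "refC2", "refR1", "refR2"), rn), ,
                   drop = FALSE]
  cox1_labels <- setNames(c("C", "C", "R", "R"),
                          c("refC1", "refC2", "refR1", "refR2"))
  list(gm = gm2, metadata = metadata,
       tpi_locus = list(chrom = "chrZ", start = 0, end = 20000),
       tpi_refs = tpi_refs, cox1_query = cox1_query, cox1_refs = cox1_refs,
       cox1_labels = cox1_labels, labels = fx$labels)
}

#' Ready-to-run demo configuration on the bundled synthetic dataset
#'
#' @param seed global seed.
#' @param outdir output directory.
#' @param ... overrides passed to [run_config()].
#' @return A [run_config()] whose inputs come from [demo_dataset()].
#' @export
demo_run_config <- function(seed = 42, outdir = tempfile("fawpopgen_demo"),
                            ...) {
  d <- demo_dataset(seed)
  run_config(gm = d$gm, metadata = d$metadata, tpi_locus = d$tpi_locus,
             tpi_refs = d$tpi_refs, cox1_query = d$cox1_query,
             cox1_refs = d$cox1_refs, cox1_labels = d$cox1_labels,
             window_size = 50000, window_step = 50000, dxy_step = 25000,
             B = 100, B_window = 99, grid_n = 200, seed = seed,
             outdir = outdir, ...)
}
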