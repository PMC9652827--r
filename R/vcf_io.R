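#' Read a multi-sample VCF into a genotype matrix
#'
#' Reads VCF v4.x (plain text or gzipped) with a GT field. Multiallelic
#' records and non-SNV records (indels, symbolic alleles) are skipped with a
#' logged count; half-calls and `./.` genotypes become missing dosages.
#'
#' @param path path to the VCF file.
#' @param metadata_path optional path to a tab-separated sample metadata table
#'   (header required, first column `sample_id`); must cover every VCF sample.
#' @param z_chroms chromosome names treated as Z-linked.
#' @param apply_hard_filter if `TRUE`, run [hard_filter()] on the INFO
#'   annotations and drop failing records.
#' @return A list with `gm` (a [genotype_matrix()]), `metadata` (data frame or
#'   `NULL`), `info` (data frame of the retained records' filter annotations)
#'   and `n_skipped` (records dropped as multiallelic/non-SNV).
#' @export
read_vcf <- function(path, metadata_path = NULL, z_chroms = character(),
                     apply_hard_filter = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  nt <- c("A", "C", "G", "T")
  keep <- !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% nt & fix$ALT %in% nt
  n_skipped <- sum(!keep)
  if (n_skipped)
    message(n_skipped, " multiallelic/non-SNV record(s) skipped")

  info_fields <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
  info <- lapply(info_fields, function(f)
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = f))))
  info <- as.data.frame(setNames(info, info_fields))[keep, , drop = FALSE]
  rownames(info) <- NULL

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (apply_hard_filter) {
    ok <- hard_filter(info)
    gt <- gt[ok, , drop = FALSE]
    fix <- fix[ok, , drop = FALSE]
    info <- info[ok, , drop = FALSE]
  }

  dosage <- apply(gt, 2, gt_to_dosage)
  if (is.null(dim(dosage)))
    dosage <- matrix(dosage, nrow = nrow(gt),
                     dimnames = list(NULL, colnames(gt)))
  dosage <- t(dosage)  # samples x variants

  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  chrom_lengths <- vcf_contig_lengths(v)

  metadata <- NULL
  if (!is.null(metadata_path)) {
    metadata <- read_sample_metadata(metadata_path)
    missing_samples <- setdiff(colnames(gt), metadata$sample_id)
    if (length(missing_samples))
      stop("samples absent from metadata: ",
           paste(missing_samples, collapse = ", "))
  }

  gm <- genotype_matrix(dosage, colnames(gt), variants,
                        chrom_lengths = chrom_lengths, z_chroms = z_chroms)
  list(gm = gm, metadata = metadata, info = info, n_skipped = n_skipped)
}

# "0/1", "0|1" -> 1; "./." or half calls -> NA
gt_to_dosage <- function(gt) {
  a <- strsplit(gt, "[/|]")
  vapply(a, function(x) {
    if (length(x) != 2 || any(x == ".") || any(is.na(x))) return(NA_real_)
    sum(x == "1")
  }, numeric(1))
}

vcf_contig_lengths <- function(v) {
  meta <- v@meta
  contig <- grep("^##contig=", meta, value = TRUE)
  if (!length(contig)) return(NULL)
  ids <- sub('.*ID=([^,>]+).*', '\\1', contig)
  lens <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', '\\1', contig)))
  if (any(is.na(lens))) return(NULL)
  setNames(lens, ids)
}

#' Read a sample metadata table
#'
#' Tab-separated with a header; the first column is taken as `sample_id`.
#' Typical columns: `population`/`group`, `host_plant`, `site`, optional
#' `tpi_strain` and `cox1_strain`.
#'
#' @param path path to the TSV file.
#' @return A data frame with unique `sample_id`.
#' @export
read_sample_metadata <- function(path) {
  md <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(md)[1] <- "sample_id"
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata")
  md
}

#' GATK-style hard filter for SNVs
#'
#' A record is discarded iff `QD < 2.0`, `FS > 60.0`, `MQ < 40.0`,
#' `MQRankSum < -12.5` or `ReadPosRankSum < -8.0` (strict inequalities).
#' A missing annotation never triggers its clause.
#'
#' @param info data frame with any of the columns `QD`, `FS`, `MQ`,
#'   `MQRankSum`, `ReadPosRankSum` (numeric, `NA` allowed).
#' @return Logical vector, `TRUE` for retained records.
#' @export
hard_filter <- function(info) {
  info <- as.data.frame(info)
  n <- nrow(info)
  clause <- function(field, f) {
    if (!field %in% names(info)) return(rep(FALSE, n))
    x <- as.numeric(info[[field]])
    out <- f(x)
    out[is.na(out)] <- FALSE
    out
  }
  discard <- clause("QD", function(x) x < 2.0) |
    clause("FS", function(x) x > 60.0) |
    clause("MQ", function(x) x < 40.0) |
    clause("MQRankSum", function(x) x < -12.5) |
    clause("ReadPosRankSum", function(x) x < -8.0)
  !discard
}

#' Write a genotype matrix as VCF v4.2
#'
#' Plain-text VCF with contig header lines and a GT-only FORMAT field.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=fawpopgen",
    sprintf("##contig=<ID=%s,length=%d>", names(gm$chrom_lengths),
            as.integer(gm$chrom_lengths)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  ), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  if (nrow(gm$variants)) {
    gt <- matrix("./.", nrow = ncol(gm$dosage), ncol = nrow(gm$dosage))
    obs <- !is.na(t(gm$dosage))
    gt[obs] <- gt_code[as.character(t(gm$dosage)[obs])]
    lines <- paste(gm$variants$chrom, gm$variants$pos, ".",
                   gm$variants$ref, gm$variants$alt, ".", "PASS", ".", "GT",
                   apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a sample metadata table as TSV
#'
#' @param metadata data frame with a `sample_id` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
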