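#' Build a sliding/tiling window partition
#'
#' Windows are half-open `[start, start + size)` in 0-based coordinates,
#' anchored at coordinate 0 of every chromosome. With `untruncated_only`,
#' windows extending past the chromosome end are dropped; otherwise the last
#' window is truncated at the chromosome end and flagged.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param size_bp window size in bp (default 500 kb, the scale used for
#'   genome-wide F_ST scans).
#' @param step_bp step between window starts (defaults to `size_bp`, i.e.
#'   non-overlapping tiling; 100 kb is the conventional D_XY step).
#' @param untruncated_only drop windows that would extend past the
#'   chromosome end.
#' @return Data frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive) and `untruncated`.
#' @export
make_windows <- function(chrom_lengths, size_bp = 5e5, step_bp = size_bp,
                         untruncated_only = TRUE) {
  stopifnot(size_bp > 0, step_bp > 0, step_bp <= size_bp,
            all(chrom_lengths > 0))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step_bp)
    starts <- starts[starts < len]
    end <- pmin(starts + size_bp, len)
    untrunc <- (starts + size_bp) <= len
    if (untruncated_only) {
      starts <- starts[untrunc]; end <- end[untrunc]; untrunc <- untrunc[untrunc]
    }
    if (!length(starts)) return(NULL)
    data.frame(chrom = ch, start = starts, end = end, untruncated = untrunc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), untruncated = logical())
  rownames(out) <- NULL
  out
}

#' Assign variants to windows
#'
#' @param gm a [genotype_matrix()].
#' @param windows window table from [make_windows()].
#' @return Integer list: for each window, the variant column indices whose
#'   (1-based) position falls inside the half-open 0-based window.
#' @keywords internal
window_variant_index <- function(gm, windows) {
  pos0 <- gm$variants$pos - 1L
  lapply(seq_len(nrow(windows)), function(i) {
    which(gm$variants$chrom == windows$chrom[i] &
            pos0 >= windows$start[i] & pos0 < windows$end[i])
  })
}

#' Write windows (or windowed statistics) as BED
#'
#' 0-based half-open intervals; any extra numeric columns are appended after
#' the name column.
#'
#' @param windows data frame with `chrom`, `start`, `end` and optional
#'   statistic columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(windows, path) {
  extra <- setdiff(names(windows), c("chrom", "start", "end", "untruncated"))
  df <- data.frame(windows$chrom, as.integer(windows$start),
                   as.integer(windows$end),
                   name = sprintf("win%05d", seq_len(nrow(windows))))
  for (e in extra) df[[e]] <- windows[[e]]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a table as TSV
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
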