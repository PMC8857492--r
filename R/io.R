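# Plain-text genomic interval and track I/O. All coordinates are 0-based
# half-open, as in BED/bedGraph themselves, so no conversion happens here.

#' Read / write BED intervals
#'
#' BED6-style tab-separated intervals (`chrom start end name score strand`);
#' trailing columns are optional on read and filled with defaults.
#'
#' @param path file path.
#' @return data frame `chrom, start, end, name, score, strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  defaults <- list(NULL, NULL, NULL, ".", 0, "*")
  names_full <- c("chrom", "start", "end", "name", "score", "strand")
  for (k in seq_len(6)) {
    if (ncol(df) < k) df[[k]] <- defaults[[k]]
  }
  names(df) <- names_full[seq_len(ncol(df))]
  df[, names_full]
}

#' @rdname read_bed
#' @param df data frame with at least `chrom`, `start`, `end`.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = df$name %||% df$peak_id %||% ".",
                    score = df$score %||% 0,
                    strand = df$strand %||% "*")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write loop calls as BEDPE
#'
#' @param loops loop-call data frame (see [detect_loops()]).
#' @param path file path.
#' @export
write_bedpe <- function(loops, path) {
  out <- data.frame(chrom1 = loops$chrom, start1 = loops$start1,
                    end1 = loops$end1, chrom2 = loops$chrom,
                    start2 = loops$start2, end2 = loops$end2,
                    name = sprintf("loop_%d", seq_len(nrow(loops))),
                    score = loops$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track into per-bin values
#'
#' Interval values are averaged into bins by overlap-weighted mean; bins
#' without coverage are NA.
#'
#' @param path bedGraph file (`chrom start end value`).
#' @param chrom chromosome to extract.
#' @param bin_size bin width in bp.
#' @param n_bins number of bins.
#' @return numeric vector of length `n_bins`.
#' @export
read_bedgraph_track <- function(path, chrom, bin_size, n_bins) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          col.names = c("chrom", "start", "end", "value"))
  df <- df[df$chrom == chrom, , drop = FALSE]
  num <- den <- rep(0, n_bins)
  for (k in seq_len(nrow(df))) {
    idx <- bins_overlapping(df$start[k], df$end[k], bin_size, n_bins)
    for (i in idx) {
      b0 <- (i - 1) * bin_size
      ov <- min(df$end[k], b0 + bin_size) - max(df$start[k], b0)
      num[i] <- num[i] + ov * df$value[k]
      den[i] <- den[i] + ov
    }
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Write a per-bin track as bedGraph
#'
#' @param values per-bin numeric values (NA bins skipped).
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param path file path.
#' @export
write_bedgraph_track <- function(values, chrom, bin_size, path) {
  idx <- which(!is.na(values))
  out <- data.frame(chrom = chrom, start = (idx - 1) * bin_size,
                    end = idx * bin_size, value = values[idx])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write differential tables (TSV: id, log2FC, padj)
#'
#' @param path file path.
#' @export
read_diff_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_diff_table
#' @param tbl data frame with `id`, `log2FC`, `padj`.
#' @export
write_diff_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
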