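#' Read and write marker allele-count tables
#'
#' Allele-count tables are plain TSV files with a header line and columns
#' `pos`, `n_blue_high`, `n_red_high`, `n_blue_low`, `n_red_low`
#' (positions in bp, 0-based; counts of blue/red ancestral alleles in the
#' high and low pool).
#'
#' @param file Path to a TSV file.
#' @return `read_allele_counts()`: a tibble sorted by position.
#' @export
read_allele_counts <- function(file) {
  df <- utils::read.delim(file, check.names = TRUE)
  need <- c("pos", "n_blue_high", "n_red_high", "n_blue_low", "n_red_low")
  if (!all(need %in% names(df))) {
    stop("allele-count table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$pos), need]
  if (any(df[-1] < 0)) stop("allele counts must be non-negative",
                            call. = FALSE)
  tibble::as_tibble(df)
}

#' @rdname read_allele_counts
#' @param counts Allele-count table (see [genotype_pools()]).
#' @export
write_allele_counts <- function(counts, file) {
  utils::write.table(counts, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a G' track as TSV
#'
#' Columns `pos`, `G`, `Gprime`.
#'
#' @param track A `"gprime_track"` (see [smooth_gprime()]).
#' @param file Output path.
#' @export
write_gprime_track <- function(track, file) {
  utils::write.table(as.data.frame(track)[c("pos", "G", "Gprime")], file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write called peaks as BED plus a JSON summary
#'
#' The BED file is 0-based half-open (`chrom`, `start`, `end`, `name`,
#' `score`); the JSON summary records the significance threshold and, for
#' each peak, its span, length, maximum G' and its position.
#'
#' @param peaks Peak table from [call_peaks()].
#' @param prefix Output path prefix; writes `<prefix>.peaks.bed` and
#'   `<prefix>.peaks.json`.
#' @param chrom Chromosome name used in the BED file.
#' @return Invisibly, the two file paths.
#' @export
write_peaks <- function(peaks, prefix, chrom = "chr1") {
  bed <- data.frame(chrom = chrom,
                    start = format(peaks$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(peaks$end + 1, scientific = FALSE,
                                 trim = TRUE),
                    name = ifelse(peaks$is_main, "peak_main",
                                  paste0("peak_", seq_len(nrow(peaks)))),
                    score = round(peaks$max_gprime, 3))
  bed_file <- paste0(prefix, ".peaks.bed")
  utils::write.table(bed, bed_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  json_file <- paste0(prefix, ".peaks.json")
  jsonlite::write_json(list(threshold = attr(peaks, "threshold"),
                            peaks = as.data.frame(peaks)),
                       json_file, auto_unbox = TRUE, digits = NA)
  invisible(c(bed = bed_file, json = json_file))
}
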