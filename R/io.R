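# Plain-text readers/writers for the pipeline's hand-off formats. All
# writers emit headers; coordinates in files are 1-based inclusive.

write_tsv_ <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_cols_ <- function(d, cols, what) {
  missing <- setdiff(cols, names(d))
  if (length(missing)) {
    stop(what, " file lacks columns: ", paste(missing, collapse = ", "))
  }
  d
}

#' Read / write pipeline tables
#'
#' TSV/CSV round-trip helpers for the standard hand-off formats: SNP
#' LRR/BAF profiles (`chrom, pos, lrr, baf, het`), coverage bins (`chrom,
#' start, end, log_ratio`), variant tables, caliper growth studies (CSV:
#' `study, arm, animal, day, length_mm, width_mm`) and SEG-style segment
#' tables (`sample, chrom, start, end, n_sites, mean_lrr`).
#'
#' @param path File path.
#' @param d,segments,sample Data to write / sample label for SEG output.
#' @return Readers return data.frames; writers return the path invisibly.
#' @name pdx_io
NULL

#' @rdname pdx_io
#' @export
read_snp_profile <- function(path) {
  d <- read.delim(path)
  d <- check_cols_(d, c("chrom", "pos", "lrr", "baf", "het"), "SNP profile")
  d$het <- as.logical(d$het)
  d
}

#' @rdname pdx_io
#' @export
write_snp_profile <- function(d, path) {
  write_tsv_(d[c("chrom", "pos", "lrr", "baf", "het")], path)
}

#' @rdname pdx_io
#' @export
read_coverage_bins <- function(path) {
  check_cols_(read.delim(path), c("chrom", "start", "end", "log_ratio"),
              "coverage bin")
}

#' @rdname pdx_io
#' @export
write_coverage_bins <- function(d, path) {
  write_tsv_(d[c("chrom", "start", "end", "log_ratio")], path)
}

#' @rdname pdx_io
#' @export
read_variant_table <- function(path) {
  d <- read.delim(path)
  d <- check_cols_(d, c("chrom", "pos", "ref", "alt", "qss", "tumor_depth",
                        "alt_reads", "vaf_t", "coding"), "variant")
  d$coding <- as.logical(d$coding)
  d
}

#' @rdname pdx_io
#' @export
write_variant_table <- function(d, path) write_tsv_(d, path)

#' @rdname pdx_io
#' @export
read_growth_study <- function(path) {
  check_cols_(read.csv(path), c("study", "arm", "animal", "day",
                                "length_mm", "width_mm"), "growth study")
}

#' @rdname pdx_io
#' @export
write_growth_study <- function(d, path) {
  write.csv(d[c("study", "arm", "animal", "day", "length_mm", "width_mm")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pdx_io
#' @export
write_seg <- function(segments, sample, path) {
  d <- data.frame(sample = sample, chrom = segments$chrom,
                  start = segments$start, end = segments$end,
                  n_sites = segments$n_sites,
                  mean_lrr = segments$mean_lrr)
  write_tsv_(d, path)
}

#' @rdname pdx_io
#' @export
read_seg <- function(path) {
  check_cols_(read.delim(path), c("sample", "chrom", "start", "end",
                                  "n_sites", "mean_lrr"), "SEG")
}

#' @rdname pdx_io
#' @export
write_json_report <- function(d, path) {
  jsonlite::write_json(d, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
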