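# Plain-text interchange: tab-separated tables with '#' header comments
# recording totals and configuration, so counts, lookups, enrichments and
# fits can enter or leave the pipeline at any stage.

#' Write / read a barcode count table
#'
#' TSV with columns `barcode`, `condition`, `co2_um`, `replicate`, `n_pre`,
#' `n_post`; per condition/replicate totals are stored in `# total` header
#' comment lines and restored on read.
#'
#' @param counts a `count_table`.
#' @param path output file.
#' @return `path`, invisibly; `read_count_table()` returns a `count_table`.
#' @export
write_count_table <- function(counts, path) {
  totals <- attr(counts, "totals")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(totals)))
    writeLines(sprintf("# total\t%s\t%.15g\t%d\t%s\t%s",
                       totals$condition[i], totals$co2_um[i],
                       totals$replicate[i],
                       format(totals$pre_tot[i], scientific = FALSE),
                       format(totals$post_tot[i], scientific = FALSE)), con)
  utils::write.table(counts, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# total\t", lines, value = TRUE)
  parts <- strsplit(hdr, "\t")
  totals <- data.frame(
    condition = vapply(parts, `[`, "", 2),
    co2_um = as.numeric(vapply(parts, `[`, "", 3)),
    replicate = as.integer(vapply(parts, `[`, "", 4)),
    pre_tot = as.numeric(vapply(parts, `[`, "", 5)),
    post_tot = as.numeric(vapply(parts, `[`, "", 6)),
    stringsAsFactors = FALSE)
  counts <- utils::read.table(text = lines[!startsWith(lines, "#")],
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  structure(counts, totals = totals, class = c("count_table", "data.frame"))
}

#' Write / read a barcode lookup table
#'
#' TSV with columns `barcode`, `assignment`, `support`.
#'
#' @param lookup a `barcode_lookup`.
#' @param path file path.
#' @return `path` invisibly; the reader returns a `barcode_lookup`.
#' @export
write_lookup <- function(lookup, path) {
  utils::write.table(lookup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lookup
#' @export
read_lookup <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  structure(d, class = c("barcode_lookup", "data.frame"))
}

#' Write an enrichment or kinetic-fit table
#'
#' Plain TSV export of [compute_enrichment()] / [normalize_enrichment()] /
#' [reliability_sweep()] outputs.
#'
#' @param x a data.frame-like result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
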