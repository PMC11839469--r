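# Barcode -> variant lookup from long reads, and barcode counting in
# short-read amplicons. Retention rules: a consensus is kept only if it is
# exactly wild type or carries exactly one designed amino-acid substitution;
# any other change (second mutation, indel, ambiguity, synonymous-only edit)
# invalidates the barcode.

#' Per-column majority consensus of a read bundle
#'
#' All reads of one barcode are stacked and each position takes the majority
#' base. A tied column has no majority and is marked `N` (ambiguous); such a
#' consensus is invalidated downstream.
#'
#' @param reads character vector of equal-length reads (one barcode's bundle).
#' @return consensus sequence (character scalar, possibly containing `N`).
#' @export
call_consensus <- function(reads) {
  if (length(reads) == 0) stop("empty read bundle")
  L <- unique(nchar(reads))
  if (length(L) != 1) stop("reads must be equal length")
  if (length(reads) == 1) return(reads)
  m <- matrix(unlist(strsplit(reads, ""), use.names = FALSE), nrow = L)
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) rowSums(m == b), numeric(L))
  top <- max.col(counts, ties.method = "first")
  best <- counts[cbind(seq_len(L), top)]
  tie <- rowSums(counts == best) > 1
  cons <- c("A", "C", "G", "T")[top]
  cons[tie] <- "N"
  paste(cons, collapse = "")
}

#' Classify a consensus coding sequence against the designed library
#'
#' Returns `"WT"` for an exact match to the reference coding sequence, the
#' variant identifier if the consensus carries exactly one amino-acid change
#' that matches a designed variant (with all nucleotide edits confined to that
#' codon), and `"INVALID"` otherwise — including length changes (indels),
#' ambiguous bases, synonymous-only edits, changes at more than one codon, and
#' amino-acid changes not in the design.
#'
#' @param consensus consensus coding sequence (character scalar).
#' @param design a [reference_design()] carrying a `cds`.
#' @return assignment string: `"WT"`, a `variant_id`, or `"INVALID"`.
#' @export
classify_consensus <- function(consensus, design) {
  if (is.null(design$cds)) stop("design must carry a coding sequence")
  ref <- design$cds
  if (nchar(consensus) != nchar(ref)) return("INVALID")
  if (consensus == ref) return("WT")
  if (grepl("[^ACGT]", consensus)) return("INVALID")
  a <- strsplit(consensus, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  diff_nt <- which(a != b)
  codons <- unique((diff_nt - 1L) %/% 3L + 1L)
  if (length(codons) != 1) return("INVALID")
  p <- codons
  mut_codon <- substr(consensus, 3 * p - 2, 3 * p)
  mut_aa <- unname(Biostrings::GENETIC_CODE[mut_codon])
  wt_aa <- substr(design$protein, p, p)
  if (mut_aa == wt_aa) return("INVALID")  # synonymous, not an exact WT match
  hit <- design$variants$position == p & design$variants$mut_aa == mut_aa
  if (any(hit)) design$variants$variant_id[hit] else "INVALID"
}

# barcode + payload extraction at fixed positions, exact anchor match
.parse_reads <- function(seqs, anchors, with_payload = FALSE) {
  n5 <- nchar(anchors$five); n3 <- nchar(anchors$three)
  ok <- substr(seqs, 1, n5) == anchors$five &
    substr(seqs, n5 + 31, n5 + 30 + n3) == anchors$three
  barcode <- substr(seqs, n5 + 1, n5 + 30)
  payload <- if (with_payload) substr(seqs, n5 + 31 + n3, nchar(seqs)) else NULL
  list(ok = ok, barcode = barcode, payload = payload)
}

.read_fastq <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    as.character(Biostrings::readDNAStringSet(x, format = "fastq"))
  } else {
    as.character(x)
  }
}

#' Build the barcode-to-variant lookup table from long reads
#'
#' Reads are parsed for their fixed-position 30-nt barcode, grouped by
#' barcode, and each group with at least `min_support` reads is collapsed to a
#' per-column majority consensus and classified against the design. Reads with
#' unparseable barcode regions are dropped (and counted).
#'
#' @param reads path to a long-read FASTQ, or a character vector of read
#'   sequences.
#' @param design a [reference_design()] carrying a `cds`.
#' @param min_support minimum long reads per barcode (default 3).
#' @param anchors a [read_anchors()] list.
#' @return object of class `barcode_lookup`: data.frame with columns
#'   `barcode`, `assignment` (`"WT"`, `variant_id`, or `"INVALID"`),
#'   `support`; attribute `stats` records reads dropped/retained counts.
#' @export
build_lookup <- function(reads, design, min_support = 3, anchors = read_anchors()) {
  seqs <- .read_fastq(reads)
  if (length(seqs) == 0) {
    return(structure(data.frame(barcode = character(0),
                                assignment = character(0),
                                support = integer(0), stringsAsFactors = FALSE),
                     stats = c(reads = 0, dropped = 0, retained = 0, invalid = 0),
                     class = c("barcode_lookup", "data.frame")))
  }
  p <- .parse_reads(seqs, anchors, with_payload = TRUE)
  n_drop <- sum(!p$ok)
  bundles <- split(p$payload[p$ok], p$barcode[p$ok])
  bundles <- bundles[lengths(bundles) >= min_support]
  assignment <- vapply(bundles, function(b)
    classify_consensus(call_consensus(b), design), "")
  lookup <- data.frame(barcode = names(bundles),
                       assignment = unname(assignment),
                       support = unname(lengths(bundles)),
                       stringsAsFactors = FALSE)
  rownames(lookup) <- NULL
  structure(lookup,
            stats = c(reads = length(seqs), dropped = n_drop,
                      retained = sum(lookup$assignment != "INVALID"),
                      invalid = sum(lookup$assignment == "INVALID")),
            class = c("barcode_lookup", "data.frame"))
}

#' Lookup table from a simulated library's ground truth
#'
#' Convenience constructor: the error-free lookup implied by a synthetic
#' library's barcode map, for running the counting and enrichment stages
#' directly on simulated counts.
#'
#' @param lib a [generate_library()] result.
#' @return a `barcode_lookup` data.frame.
#' @export
lookup_from_library <- function(lib) {
  structure(data.frame(barcode = lib$barcode_map$barcode,
                       assignment = lib$barcode_map$variant_id,
                       support = NA_integer_, stringsAsFactors = FALSE),
            class = c("barcode_lookup", "data.frame"))
}

#' Count barcodes in a short-read amplicon run
#'
#' Exact-match counting of retained (non-`INVALID`) lookup barcodes; reads
#' whose barcode is not in the lookup (or whose anchors do not match) are
#' tallied to an unassigned bucket. Retained counts plus unassigned equal the
#' total number of reads exactly.
#'
#' @param reads path to a short-read FASTQ or a character vector of read
#'   sequences.
#' @param lookup a [build_lookup()] result.
#' @param anchors a [read_anchors()] list.
#' @return data.frame with columns `barcode`, `count` (one row per retained
#'   barcode); attributes `total` and `unassigned`.
#' @export
count_barcodes <- function(reads, lookup, anchors = read_anchors()) {
  if (nrow(lookup) == 0) stop("lookup non-empty")
  keep <- lookup$barcode[lookup$assignment != "INVALID"]
  seqs <- .read_fastq(reads)
  if (length(seqs) == 0) {
    return(structure(data.frame(barcode = keep, count = 0L,
                                stringsAsFactors = FALSE),
                     total = 0L, unassigned = 0L))
  }
  p <- .parse_reads(seqs, anchors)
  bc <- p$barcode[p$ok]
  tab <- table(factor(bc, levels = keep))
  counts <- as.integer(tab)
  unassigned <- length(seqs) - sum(counts)
  structure(data.frame(barcode = keep, count = counts, stringsAsFactors = FALSE),
            total = length(seqs), unassigned = unassigned)
}
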