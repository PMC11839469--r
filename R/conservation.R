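# Per-position phylogenetic conservation from a protein multiple sequence
# alignment, and its relation to the positional mean of the fitness map.

#' Per-position conservation profile from an alignment
#'
#' Maps every ungapped position of the reference row to its alignment column
#' and computes, for each of the 20 amino acids, the fraction of sequences
#' carrying it there. The conservation of a position is the maximum fraction
#' (a column that is 90% alanine scores 0.9). By default gaps (and unknown
#' residues X/B/Z) are excluded from the denominator, so fractions are over
#' sequences with a residue at that column; set `count_gaps = TRUE` to divide
#' by the full number of sequences instead.
#'
#' @param alignment aligned protein FASTA path, `Biostrings::AAStringSet`, or
#'   named character vector of equal-length aligned sequences.
#' @param reference_id name of the reference row.
#' @param count_gaps include gapped rows in the denominator.
#' @return object of class `conservation_profile`: data.frame with columns
#'   `position` (1-based ungapped reference position), `column` (alignment
#'   column), `wt_aa`, `conservation`, `top_aa`, `gap_fraction`; attribute
#'   `fractions` is the positions x 20 amino-acid fraction matrix.
#' @export
column_conservation <- function(alignment, reference_id, count_gaps = FALSE) {
  if (is.character(alignment) && length(alignment) == 1 && file.exists(alignment))
    alignment <- Biostrings::readAAStringSet(alignment)
  seqs <- if (is.character(alignment)) alignment else as.character(alignment)
  seqs <- stats::setNames(toupper(seqs), names(seqs))
  if (is.null(names(seqs)) || !reference_id %in% names(seqs))
    stop("reference id absent from alignment")
  if (length(unique(nchar(seqs))) != 1) stop("sequences are not aligned")
  m <- do.call(rbind, strsplit(seqs, ""))
  ref <- m[reference_id, ]
  gap_chars <- c("-", ".")
  cols <- which(!ref %in% gap_chars)   # ungapped ref position k -> column
  n_seq <- nrow(m)
  frac <- matrix(0, length(cols), length(AA20),
                 dimnames = list(NULL, AA20))
  gap_fraction <- numeric(length(cols))
  for (k in seq_along(cols)) {
    col <- m[, cols[k]]
    is_gap <- col %in% gap_chars
    gap_fraction[k] <- mean(is_gap)
    counted <- col %in% AA20
    denom <- if (count_gaps) n_seq else sum(counted)
    if (denom > 0)
      frac[k, ] <- tabulate(factor(col[counted], levels = AA20),
                            nbins = length(AA20)) / denom
  }
  top <- max.col(frac, ties.method = "first")
  out <- data.frame(position = seq_along(cols), column = cols,
                    wt_aa = ref[cols],
                    conservation = frac[cbind(seq_along(cols), top)],
                    top_aa = AA20[top],
                    gap_fraction = gap_fraction,
                    stringsAsFactors = FALSE)
  structure(out, fractions = frac,
            class = c("conservation_profile", "data.frame"))
}

#' Relate conservation to positional mean fitness
#'
#' Averages normalized enrichment over the (up to 19) mutants at each
#' position, computes the Spearman rank correlation with the conservation
#' profile over shared positions, and lists outlier positions: highly
#' conserved yet mutation-tolerant, and weakly conserved yet intolerant, by
#' quantile cuts.
#'
#' @param profile a [column_conservation()] result.
#' @param norm a normalized `enrichment_table`; typically restricted to the
#'   reference condition (use `condition` to subset).
#' @param condition optional condition label to subset `norm`.
#' @param quantile_cut quantile defining "high"/"low" for the outlier lists.
#' @return list with `per_position` (data.frame `position`, `mean_fitness`,
#'   `conservation`, `n_mutants`), `spearman` (NA when fitness is constant),
#'   `conserved_tolerant`, `variable_intolerant` (position vectors).
#' @export
conservation_vs_fitness <- function(profile, norm, condition = NULL,
                                    quantile_cut = 0.75) {
  if (!is.null(condition)) norm <- norm[norm$condition == condition, ]
  d <- norm[!is.na(norm$position) & !is.na(norm$e_norm), ]
  mf <- stats::aggregate(e_norm ~ position, data = d, FUN = mean)
  nm <- stats::aggregate(variant_id ~ position, data = d,
                         FUN = function(x) length(unique(x)))
  per <- merge(merge(mf, nm, by = "position"),
               profile[, c("position", "conservation")], by = "position")
  names(per) <- c("position", "mean_fitness", "n_mutants", "conservation")
  per <- per[, c("position", "mean_fitness", "conservation", "n_mutants")]
  if (nrow(per) == 0) stop("no shared positions")
  rho <- if (stats::sd(per$mean_fitness) == 0 || stats::sd(per$conservation) == 0)
    NA_real_
  else suppressWarnings(stats::cor(per$mean_fitness, per$conservation,
                                   method = "spearman"))
  hi_c <- stats::quantile(per$conservation, quantile_cut)
  lo_c <- stats::quantile(per$conservation, 1 - quantile_cut)
  hi_f <- stats::quantile(per$mean_fitness, quantile_cut)
  lo_f <- stats::quantile(per$mean_fitness, 1 - quantile_cut)
  list(per_position = per, spearman = rho,
       conserved_tolerant = per$position[per$conservation >= hi_c &
                                           per$mean_fitness >= hi_f],
       variable_intolerant = per$position[per$conservation <= lo_c &
                                            per$mean_fitness <= lo_f])
}
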