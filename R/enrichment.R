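# Per-variant enrichment from barcode counts: total-normalized log10
# pre/post ratios with total-weighted pseudo-counts, median over a variant's
# barcodes; normalization to wild type (=1) and the catalytically dead panel
# (median = 0); replicate-correlation-driven choice of the processing
# parameters c_min (count threshold) and alpha_p (pseudo-count constant).

#' Enrichment processing parameters
#'
#' `c_min` is the minimum read count a barcode must reach either pre- or
#' post-selection to enter the median; `alpha_p` is the pseudo-count constant,
#' multiplied by the total reads of each timepoint before being added to each
#' barcode count. Defaults are the sweep-optimized values `c_min = 5`,
#' `alpha_p = 3.65e-7` (about 0.3 pseudo-counts at typical depth).
#'
#' @param c_min non-negative integer count threshold.
#' @param alpha_p positive pseudo-count constant (dimensionless).
#' @return object of class `enrichment_config`.
#' @export
enrichment_config <- function(c_min = 5, alpha_p = 3.65e-7) {
  stopifnot(c_min >= 0, alpha_p > 0)
  structure(list(c_min = c_min, alpha_p = alpha_p),
            class = "enrichment_config")
}

# parse the 1-based protein position out of "<wt><pos><mut>" ids; "WT" -> NA
.variant_position <- function(variant_id) {
  p <- suppressWarnings(as.integer(sub("^[A-Z]([0-9]+)[A-Z]$", "\\1", variant_id)))
  p[variant_id == "WT"] <- NA_integer_
  p
}

# raw enrichment of each variant group for one condition/replicate slice.
# groups: named list of row indices into (n_pre, n_post) per variant.
.enrich_slice <- function(n_pre, n_post, pre_tot, post_tot, groups, c_min, alpha_p) {
  l <- log10((n_post + post_tot * alpha_p) / (n_pre + pre_tot * alpha_p)) -
    log10(post_tot / pre_tot)
  pass <- pmax(n_pre, n_post) >= c_min
  e <- vapply(groups, function(idx) {
    v <- l[idx[pass[idx]]]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }, 0)
  n_bc <- vapply(groups, function(idx) sum(pass[idx]), 0L)
  list(e = e, n_barcodes = n_bc)
}

#' Raw per-variant enrichment
#'
#' For every condition and replicate in the count table, computes the variant
#' enrichment as the median over the variant's passing barcodes of the
#' total-normalized log10 count ratio:
#' `log10((N_f,i + N_f,tot*alpha_p) / (N_0,i + N_0,tot*alpha_p)) -
#'  log10(N_f,tot / N_0,tot)`,
#' where a barcode passes if `max(N_0,i, N_f,i) >= c_min`. The wild type is a
#' group like any other (the pool of all wild-type barcodes). Variants with no
#' passing barcode are emitted with `e_raw = NA` (missing, not zero).
#'
#' @param counts a `count_table` (e.g. from [simulate_selection()]), long
#'   format with columns `barcode`, `condition`, `co2_um`, `replicate`,
#'   `n_pre`, `n_post` and a `totals` attribute.
#' @param lookup a `barcode_lookup`; `INVALID` barcodes are excluded.
#' @param config an [enrichment_config()].
#' @return object of class `enrichment_table`: data.frame with columns
#'   `variant_id`, `position`, `condition`, `co2_um`, `replicate`, `e_raw`,
#'   `n_barcodes`.
#' @export
compute_enrichment <- function(counts, lookup, config = enrichment_config()) {
  totals <- attr(counts, "totals")
  if (is.null(totals)) {
    totals <- stats::aggregate(cbind(pre_tot = n_pre, post_tot = n_post) ~
                                 condition + replicate, data = counts, FUN = sum)
  }
  if (any(totals$pre_tot <= 0) || any(totals$post_tot <= 0))
    stop("empty condition")
  keep <- lookup$assignment != "INVALID"
  assign_of <- stats::setNames(lookup$assignment[keep], lookup$barcode[keep])
  slices <- split(seq_len(nrow(counts)),
                  list(condition = counts$condition,
                       replicate = counts$replicate), drop = TRUE)
  out <- vector("list", length(slices))
  variants <- sort(unique(assign_of))
  for (s in seq_along(slices)) {
    rows <- slices[[s]]
    bc <- counts$barcode[rows]
    va <- assign_of[bc]
    known <- !is.na(va)
    groups <- split(seq_along(rows)[known],
                    factor(va[known], levels = variants))
    cond <- counts$condition[rows[1]]
    repl <- counts$replicate[rows[1]]
    tot <- totals[totals$condition == cond & totals$replicate == repl, ]
    res <- .enrich_slice(counts$n_pre[rows], counts$n_post[rows],
                         tot$pre_tot[1], tot$post_tot[1], groups,
                         config$c_min, config$alpha_p)
    out[[s]] <- data.frame(variant_id = variants,
                           position = .variant_position(variants),
                           condition = cond,
                           co2_um = counts$co2_um[rows[1]],
                           replicate = repl,
                           e_raw = unname(res$e),
                           n_barcodes = unname(res$n_barcodes),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("enrichment_table", "data.frame"))
}

#' Normalize enrichments to wild type and the dead panel
#'
#' Within each condition and replicate, rescales raw enrichments as
#' `e_norm = (e_j - e_dead) / (e_WT - e_dead)` where `e_WT` is the raw
#' enrichment of the pooled wild-type barcodes and `e_dead` is the median raw
#' enrichment over all mutants at the dead-panel positions. After
#' normalization the wild type is exactly 1 and the dead-panel median exactly
#' 0 in every condition/replicate.
#'
#' @param raw an `enrichment_table` from [compute_enrichment()].
#' @param dead_positions protein positions defining the dead panel.
#' @return the table with an added `e_norm` column.
#' @export
normalize_enrichment <- function(raw, dead_positions = dead_panel_positions()) {
  if (length(dead_positions) == 0) stop("dead panel non-empty")
  key <- interaction(raw$condition, raw$replicate, drop = TRUE)
  raw$e_norm <- NA_real_
  for (k in levels(key)) {
    rows <- which(key == k)
    e <- raw$e_raw[rows]
    e_wt <- e[raw$variant_id[rows] == "WT"]
    if (length(e_wt) != 1 || is.na(e_wt)) stop("wild-type enrichment missing")
    dead <- raw$position[rows] %in% dead_positions
    if (!any(dead)) stop("no dead-panel variants in table")
    e_dead <- stats::median(e[dead], na.rm = TRUE)
    if (!is.finite(e_dead) || abs(e_wt - e_dead) < 1e-12)
      stop("no selection signal")
    raw$e_norm[rows] <- (e - e_dead) / (e_wt - e_dead)
  }
  raw
}

#' Mean pairwise Pearson correlation across replicates
#'
#' For every condition, computes the Pearson correlation of normalized
#' enrichments over the variants shared (non-missing) between each unordered
#' pair of replicates, and returns the mean over all pairs and conditions.
#' Variants missing in one replicate are excluded from that pair only.
#'
#' @param norm a normalized `enrichment_table` (with `e_norm`).
#' @return mean pairwise Pearson coefficient (scalar).
#' @export
pairwise_replicate_correlation <- function(norm) {
  cors <- c()
  for (cond in unique(norm$condition)) {
    d <- norm[norm$condition == cond, ]
    reps <- sort(unique(d$replicate))
    if (length(reps) < 2) next
    wide <- stats::reshape(d[, c("variant_id", "replicate", "e_norm")],
                           idvar = "variant_id", timevar = "replicate",
                           direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    for (i in seq_along(reps)[-length(reps)]) for (j in (i + 1):length(reps)) {
      ok <- stats::complete.cases(m[, c(i, j)])
      if (sum(ok) < 2) stop("fewer than 2 shared variants between replicates")
      cors <- c(cors, stats::cor(m[ok, i], m[ok, j]))
    }
  }
  if (length(cors) == 0) stop("need at least 2 replicates")
  mean(cors)
}

#' Sweep the processing parameters for maximal replicate agreement
#'
#' Evaluates every combination of the `c_min` and `alpha_p` grids by
#' recomputing normalized enrichments and scoring the mean pairwise Pearson
#' correlation across replicates; returns the maximizing pair (ties broken
#' toward smaller `c_min`, then smaller `alpha_p`) together with the full
#' correlation surface. Default grids: 11 `c_min` values linearly spaced
#' 0–50 and 10 `alpha_p` values log-spaced 1e-9–1e-6.
#'
#' @param counts a `count_table`.
#' @param lookup a `barcode_lookup`.
#' @param c_min_grid,alpha_p_grid numeric grids (non-empty).
#' @param dead_positions dead-panel positions for normalization.
#' @return list with `c_min`, `alpha_p`, `correlation`, and `surface`
#'   (data.frame `c_min`, `alpha_p`, `correlation`).
#' @export
sweep_processing_params <- function(counts, lookup,
                                    c_min_grid = seq(0, 50, length.out = 11),
                                    alpha_p_grid = 10^seq(-9, -6, length.out = 10),
                                    dead_positions = dead_panel_positions()) {
  if (length(c_min_grid) == 0 || length(alpha_p_grid) == 0)
    stop("grids non-empty")
  grid <- expand.grid(c_min = c_min_grid, alpha_p = alpha_p_grid)
  grid$correlation <- NA_real_
  for (i in seq_len(nrow(grid))) {
    norm <- normalize_enrichment(
      compute_enrichment(counts, lookup,
                         enrichment_config(grid$c_min[i], grid$alpha_p[i])),
      dead_positions)
    grid$correlation[i] <- pairwise_replicate_correlation(norm)
  }
  # correlations equal to within numerical noise count as ties
  ord <- order(-signif(grid$correlation, 12), grid$c_min, grid$alpha_p)
  best <- grid[ord[1], ]
  list(c_min = best$c_min, alpha_p = best$alpha_p,
       correlation = best$correlation, surface = grid)
}
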