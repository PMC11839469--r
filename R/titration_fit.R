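# Ratiometric Michaelis-Menten inference: per-variant maximal-velocity ratio
# and effective CO2 affinity (KC) from normalized enrichments across a CO2
# titration, plus the processing-parameter x subsampling sweep that scores
# how reliable each variant's KC is.

#' Titration-fit configuration
#'
#' Holds the wild-type KC (fixed at the literature value 149 uM), parameter
#' bounds, the reliability-sweep grids (11 `c_min` values linear 0–50 and 10
#' `alpha_p` values log 1e-9–1e-6, times 10 replicate subsamplings = 1,100
#' fits per variant), the reliability threshold (quartile-based CV < 1), and
#' the sweep seed.
#'
#' @param kc_wt wild-type CO2 Michaelis constant in uM.
#' @param vr_max upper bound on the maximal-velocity ratio.
#' @param kc_min,kc_max bounds on the mutant KC in uM.
#' @param c_min_grid,alpha_p_grid processing-parameter grids for the sweep.
#' @param n_subsamples replicate subsamplings per grid cell.
#' @param cv_threshold reliability cut on the coefficient of variation.
#' @param cv_method `"quartile"` for the robust IQR-based CV (default) or
#'   `"sd"` for plain sd/mean.
#' @param seed seed governing the subsample draws.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(kc_wt = 149, vr_max = 10, kc_min = 1e-2, kc_max = 1e4,
                       c_min_grid = seq(0, 50, length.out = 11),
                       alpha_p_grid = 10^seq(-9, -6, length.out = 10),
                       n_subsamples = 10, cv_threshold = 1,
                       cv_method = c("quartile", "sd"), seed = 1L) {
  stopifnot(kc_wt > 0, vr_max > 0, kc_min > 0, kc_max > kc_min,
            n_subsamples >= 1, cv_threshold > 0)
  structure(list(kc_wt = kc_wt, vr_max = vr_max, kc_min = kc_min,
                 kc_max = kc_max, c_min_grid = c_min_grid,
                 alpha_p_grid = alpha_p_grid,
                 n_subsamples = as.integer(n_subsamples),
                 cv_threshold = cv_threshold,
                 cv_method = match.arg(cv_method), seed = as.integer(seed)),
            class = "fit_config")
}

#' Expected normalized enrichment at a CO2 concentration
#'
#' The ratiometric Michaelis-Menten model: a variant's normalized enrichment
#' equals its velocity relative to wild type,
#' `vmax_ratio * (KC_wt + [CO2]) / (KC_mut + [CO2])`.
#' At saturating CO2 it tends to `vmax_ratio`; the wild type
#' (`vmax_ratio = 1`, `KC_mut = KC_wt`) sits at 1 everywhere.
#'
#' @param vmax_ratio mutant/wild-type maximal-velocity ratio (>= 0).
#' @param kc_mut mutant CO2 Michaelis constant in uM (> 0).
#' @param co2_um dissolved CO2 concentration(s) in uM (> 0).
#' @param kc_wt wild-type KC in uM.
#' @return expected normalized enrichment (vectorized over `co2_um`).
#' @examples
#' predict_enrichment(1, 298, 149)  # 298/447
#' @export
predict_enrichment <- function(vmax_ratio, kc_mut, co2_um, kc_wt = 149) {
  if (any(kc_mut <= 0)) stop("kc_mut must be positive")
  if (any(co2_um <= 0)) stop("co2_um must be positive")
  if (any(vmax_ratio < 0)) stop("vmax_ratio must be non-negative")
  vmax_ratio * (kc_wt + co2_um) / (kc_mut + co2_um)
}

# profiled residual machinery: for fixed KC the optimal vmax_ratio is linear
# least squares, clipped into [0, vr_max].
.profile_vr <- function(kc, co2, y, kc_wt, vr_max) {
  f <- (kc_wt + co2) / (kc + co2)
  vr <- sum(y * f) / sum(f * f)
  min(max(vr, 0), vr_max)
}

.sse_at <- function(kc, co2, y, kc_wt, vr_max) {
  f <- (kc_wt + co2) / (kc + co2)
  vr <- min(max(sum(y * f) / sum(f * f), 0), vr_max)
  sum((vr * f - y)^2)
}

#' Fit the CO2 titration of one variant
#'
#' Bounded non-linear least squares of the ratiometric Michaelis-Menten model
#' against a variant's normalized enrichments over all replicate points
#' jointly, requiring both parameters positive. The maximal-velocity ratio is
#' profiled analytically for fixed KC; KC is located by a coarse log-spaced
#' multi-start grid, refined with 1-D optimization, and polished with
#' box-constrained quasi-Newton steps. Ties (flat objective, e.g. all-zero
#' enrichments) resolve toward the smallest KC and are flagged as
#' boundary-pinned.
#'
#' @param co2_um dissolved CO2 per observation (uM).
#' @param enrichment normalized enrichment per observation; `NA`s are dropped.
#' @param config a [fit_config()].
#' @return list with `vmax_ratio`, `kc_um`, `sse`, `boundary` (TRUE if a
#'   parameter is pinned at a bound or the KC is unidentifiable), `n_points`.
#'   A dead variant (all enrichments ~0) returns `vmax_ratio = 0`,
#'   `kc_um = NA`, `boundary = TRUE`.
#' @export
fit_titration <- function(co2_um, enrichment, config = fit_config()) {
  ok <- is.finite(co2_um) & is.finite(enrichment)
  co2 <- co2_um[ok]; y <- enrichment[ok]
  if (length(unique(co2)) < 2)
    stop("need at least 2 distinct CO2 levels with data")
  kc_wt <- config$kc_wt; vr_max <- config$vr_max
  if (all(abs(y) < 1e-10)) {
    return(list(vmax_ratio = 0, kc_um = NA_real_, sse = 0,
                boundary = TRUE, n_points = length(y)))
  }
  lg <- log10(config$kc_min); ug <- log10(config$kc_max)
  # multi-start: coarse log grid on KC with profiled vmax_ratio
  grid <- 10^seq(lg, ug, length.out = 40)
  sse <- vapply(grid, .sse_at, 0, co2 = co2, y = y, kc_wt = kc_wt,
                vr_max = vr_max)
  i <- which.min(sse)
  lo <- max(1, i - 1); hi <- min(length(grid), i + 1)
  opt <- stats::optimize(function(l) .sse_at(10^l, co2, y, kc_wt, vr_max),
                         lower = log10(grid[lo]), upper = log10(grid[hi]),
                         tol = 1e-10)
  kc <- 10^opt$minimum
  vr <- .profile_vr(kc, co2, y, kc_wt, vr_max)
  # joint polish within the box
  obj <- function(p) {
    f <- (kc_wt + co2) / (10^p[2] + co2)
    sum((p[1] * f - y)^2)
  }
  gr <- function(p) {
    k <- 10^p[2]
    f <- (kc_wt + co2) / (k + co2)
    r <- p[1] * f - y
    dfdl <- -f / (k + co2) * k * log(10)
    c(2 * sum(r * f), 2 * p[1] * sum(r * dfdl))
  }
  pol <- tryCatch(
    stats::optim(c(vr, log10(kc)), obj, gr, method = "L-BFGS-B",
                 lower = c(0, lg), upper = c(vr_max, ug),
                 control = list(factr = 10)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= opt$objective + 1e-15) {
    vr <- pol$par[1]; kc <- 10^pol$par[2]; sse_best <- pol$value
  } else sse_best <- opt$objective
  tol <- 1e-6
  boundary <- vr <= tol || vr >= vr_max * (1 - 1e-9) ||
    kc <= config$kc_min * (1 + 1e-6) || kc >= config$kc_max * (1 - 1e-6)
  list(vmax_ratio = vr, kc_um = kc, sse = sse_best,
       boundary = boundary, n_points = length(y))
}

#' Robust (quartile-based) coefficient of variation
#'
#' `IQR / (1.349 * |median|)`: the Gaussian-consistent robust analogue of
#' sd/mean, insensitive to the outlying fits a parameter sweep can produce.
#' Scale-invariant: multiplying all values by a constant leaves it unchanged.
#' With `method = "sd"` the plain sd/|mean| is returned instead.
#'
#' @param x numeric vector (NAs dropped).
#' @param method `"quartile"` or `"sd"`.
#' @return non-negative scalar (Inf when the centre is 0; NA if fewer than 2
#'   finite values).
#' @export
robust_cv <- function(x, method = c("quartile", "sd")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  if (method == "quartile") {
    m <- stats::median(x)
    if (m == 0) return(Inf)
    stats::IQR(x) / (1.349 * abs(m))
  } else {
    m <- mean(x)
    if (m == 0) return(Inf)
    stats::sd(x) / abs(m)
  }
}

# enrichment array E[variant, condition, replicate] + co2 per condition
.enrichment_array <- function(norm) {
  variants <- sort(unique(norm$variant_id))
  conds <- unique(norm[, c("condition", "co2_um")])
  conds <- conds[order(conds$co2_um), ]
  reps <- sort(unique(norm$replicate))
  E <- array(NA_real_, dim = c(length(variants), nrow(conds), length(reps)),
             dimnames = list(variants, conds$condition, reps))
  i <- match(norm$variant_id, variants)
  j <- match(norm$condition, conds$condition)
  k <- match(norm$replicate, reps)
  E[cbind(i, j, k)] <- norm$e_norm
  list(E = E, co2 = conds$co2_um, variants = variants, n_rep = length(reps))
}

#' Reliability sweep: bootstrap fits across processing parameters
#'
#' For every cell of the `c_min` x `alpha_p` grid, recomputes normalized
#' enrichments, draws `n_subsamples` resamples of the replicates (with
#' replacement, to the original replicate count), and fits the ratiometric
#' Michaelis-Menten model to each — with the default grids, 1,100 fits per
#' variant. The per-variant KC point estimate is the median of the sweep's KC
#' values; spread is summarized by the quartile-based coefficient of
#' variation, and a variant is flagged reliable iff CV < 1. Boundary-pinned
#' fits (e.g. catalytically dead variants, whose KC is unidentifiable)
#' contribute their velocity ratio but no KC; variants without a usable KC in
#' more than half of the grid cells get an infinite CV and are unreliable.
#'
#' @param counts a `count_table`.
#' @param lookup a `barcode_lookup`.
#' @param config a [fit_config()].
#' @param dead_positions dead-panel positions used for normalization.
#' @param variants optional character vector restricting the fitted variants.
#' @return object of class `kinetic_fits`: data.frame with columns
#'   `variant_id`, `vmax_ratio` (sweep median), `kc_um` (sweep median KC),
#'   `cv`, `q1`, `median`, `q3` (KC quartiles, uM), `reliable`, `n_fits`.
#' @export
reliability_sweep <- function(counts, lookup, config = fit_config(),
                              dead_positions = dead_panel_positions(),
                              variants = NULL) {
  cells <- expand.grid(c_min = config$c_min_grid, alpha_p = config$alpha_p_grid)
  first <- TRUE
  kc_store <- NULL; vr_store <- NULL; vnames <- NULL
  for (ci in seq_len(nrow(cells))) {
    norm <- normalize_enrichment(
      compute_enrichment(counts, lookup,
                         enrichment_config(cells$c_min[ci], cells$alpha_p[ci])),
      dead_positions)
    arr <- .enrichment_array(norm)
    if (!is.null(variants)) {
      keep <- arr$variants %in% variants
      arr$E <- arr$E[keep, , , drop = FALSE]
      arr$variants <- arr$variants[keep]
    }
    if (first) {
      vnames <- arr$variants
      n_total <- nrow(cells) * config$n_subsamples
      kc_store <- matrix(NA_real_, length(vnames), n_total,
                         dimnames = list(vnames, NULL))
      vr_store <- kc_store
      first <- FALSE
    }
    set.seed(child_seed(config$seed, sprintf("subsample/%d", ci)))
    draws <- matrix(sample.int(arr$n_rep, arr$n_rep * config$n_subsamples,
                               replace = TRUE),
                    nrow = config$n_subsamples)
    vmatch <- match(arr$variants, vnames)
    for (s in seq_len(config$n_subsamples)) {
      reps <- draws[s, ]
      co2 <- rep(arr$co2, times = length(reps))
      col <- (ci - 1L) * config$n_subsamples + s
      for (v in seq_along(arr$variants)) {
        y <- as.vector(arr$E[v, , reps])
        fit <- tryCatch(fit_titration(co2, y, config), error = function(e) NULL)
        if (!is.null(fit)) {
          vr_store[vmatch[v], col] <- fit$vmax_ratio
          # boundary-pinned solutions carry no usable KC (unidentifiable)
          if (!fit$boundary) kc_store[vmatch[v], col] <- fit$kc_um
        }
      }
    }
  }
  n_sub <- config$n_subsamples
  n_cells <- nrow(cells)
  res <- lapply(seq_along(vnames), function(v) {
    kc <- kc_store[v, ]; vr <- vr_store[v, ]
    n_fits <- sum(is.finite(vr))
    # cell is "missing" if no subsample in it produced a usable KC
    cell_ok <- vapply(seq_len(n_cells), function(ci)
      any(is.finite(kc[(ci - 1L) * n_sub + seq_len(n_sub)])), TRUE)
    kcf <- kc[is.finite(kc)]
    if (mean(cell_ok) < 0.5 || length(kcf) < 2) {
      cv <- Inf
      q <- rep(NA_real_, 3)
    } else {
      cv <- robust_cv(kcf, config$cv_method)
      q <- unname(stats::quantile(kcf, c(0.25, 0.5, 0.75)))
    }
    data.frame(variant_id = vnames[v],
               vmax_ratio = stats::median(vr[is.finite(vr)]),
               kc_um = q[2], cv = cv, q1 = q[1], median = q[2], q3 = q[3],
               reliable = is.finite(cv) && cv < config$cv_threshold,
               n_fits = n_fits, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, n_attempted = n_cells * n_sub,
            class = c("kinetic_fits", "data.frame"))
}
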