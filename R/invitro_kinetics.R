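# In-vitro kinetics calculation layer: initial carboxylation rates from NADH
# absorbance decay (2 NADH oxidized per carboxylation), Michaelis-Menten
# fits, kcat from a CABP active-site titration (y-intercept over
# x-intercept), and CO2/O2 specificity from membrane-inlet mass spectrometry.

#' Michaelis-Menten velocity
#'
#' @param s substrate concentration (uM).
#' @param vmax maximal velocity (uM/s).
#' @param km Michaelis constant (uM).
#' @return velocity `vmax * s / (km + s)`.
#' @export
mm_velocity <- function(s, vmax, km) vmax * s / (km + s)

#' Initial carboxylation rate from an absorbance trace
#'
#' Searches rectangular windows of the A340 trace for the one that best
#' represents the monotonic NADH decline: candidate windows start at every
#' `start_step`-th point with lengths given as fractions of the trace, and
#' each is scored by the linear fit's R-squared times the fraction of the
#' total absorbance decrease it covers. The best window's slope is converted
#' to a carboxylation rate as `|slope| / epsilon_path / stoichiometry`
#' (2 NADH per carboxylation). Adding a constant baseline to the trace does
#' not change the result. A non-decreasing trace returns 0 with a warning.
#'
#' @param time_s time points in seconds (strictly increasing).
#' @param a340 absorbance values.
#' @param epsilon_path extinction coefficient times path length, per uM.
#' @param stoichiometry NADH oxidized per carboxylation (default 2).
#' @param start_step window starts every this many points.
#' @param window_fracs candidate window lengths as fractions of the trace.
#' @return carboxylation velocity in uM/s; attribute `window` gives the
#'   selected start/end indices and slope.
#' @export
extract_initial_rate <- function(time_s, a340, epsilon_path,
                                 stoichiometry = 2, start_step = 5,
                                 window_fracs = c(0.1, 0.2, 0.4)) {
  n <- length(time_s)
  stopifnot(n == length(a340), n >= 5, epsilon_path > 0)
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing")
  total_dec <- max(a340) - min(a340)
  if (total_dec <= 0) {
    warning("non-decreasing trace; returning velocity 0")
    return(structure(0, window = NULL))
  }
  lens <- unique(pmax(5L, round(window_fracs * n)))
  starts <- seq(1L, n, by = start_step)
  best <- NULL; best_score <- -Inf
  for (len in lens) for (s in starts) {
    e <- s + len - 1L
    if (e > n) next
    x <- time_s[s:e]; y <- a340[s:e]
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) next
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    if (slope >= 0) next
    fitted <- mean(y) + slope * (x - mean(x))
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst == 0) 0 else 1 - sum((y - fitted)^2) / sst
    covered <- max(0, y[1] - y[length(y)]) / total_dec
    score <- r2 * covered
    if (score > best_score) {
      best_score <- score
      best <- list(start = s, end = e, slope = slope)
    }
  }
  if (is.null(best)) {
    warning("no decreasing window found; returning velocity 0")
    return(structure(0, window = NULL))
  }
  structure(abs(best$slope) / epsilon_path / stoichiometry, window = best)
}

#' Fit the Michaelis-Menten curve to rate measurements
#'
#' Least-squares fit of `v = Vmax * [S] / (Km + [S])` with both parameters
#' positive. Vmax is profiled analytically for fixed Km and Km located by a
#' log-spaced grid plus 1-D refinement, which is exact on noiseless data.
#' Standard errors come from the square root of the diagonal of the
#' asymptotic covariance `sigma^2 (J'J)^-1`. Replicates are pooled: fitting
#' the concatenated data of several experiments equals fitting the pooled
#' point set.
#'
#' @param conc substrate concentrations (uM), at least 3 distinct.
#' @param velocity measured velocities (uM/s).
#' @return list with `vmax`, `km`, `se_vmax`, `se_km`, `sse`, `boundary`
#'   (TRUE when Km is pinned far outside the sampled range, i.e. the data
#'   show no curvature).
#' @export
fit_michaelis_menten <- function(conc, velocity) {
  ok <- is.finite(conc) & is.finite(velocity)
  s <- conc[ok]; v <- velocity[ok]
  if (length(unique(s)) < 3) stop("need at least 3 distinct concentrations")
  km_lo <- min(s[s > 0]) / 1e3; km_hi <- max(s) * 1e3
  prof <- function(km) {
    f <- s / (km + s)
    vmax <- max(sum(v * f) / sum(f * f), 0)
    sum((vmax * f - v)^2)
  }
  grid <- 10^seq(log10(km_lo), log10(km_hi), length.out = 60)
  sse <- vapply(grid, prof, 0)
  i <- which.min(sse)
  opt <- stats::optimize(function(l) prof(10^l),
                         lower = log10(grid[max(1, i - 1)]),
                         upper = log10(grid[min(length(grid), i + 1)]),
                         tol = 1e-12)
  km <- 10^opt$minimum
  f <- s / (km + s)
  vmax <- max(sum(v * f) / sum(f * f), 0)
  res <- vmax * f - v
  n <- length(v)
  sigma2 <- sum(res^2) / max(n - 2, 1)
  J <- cbind(f, -vmax * s / (km + s)^2)
  cv <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  se <- if (is.null(cv)) c(NA_real_, NA_real_) else unname(sqrt(pmax(diag(cv), 0)))
  boundary <- km <= km_lo * (1 + 1e-6) || km >= km_hi * (1 - 1e-6)
  list(vmax = vmax, km = km, se_vmax = se[1], se_km = se[2],
       sse = sum(res^2), boundary = boundary)
}

#' Michaelis-Menten fits to a low/mid/high rate band
#'
#' Error-band recipe for technical triplicates: rates are extracted from the
#' median trace and from median +/- s.d. traces, each set is fitted
#' separately, and the three fits bracket the reported parameters.
#'
#' @param conc substrate concentrations (uM).
#' @param v_low,v_mid,v_high the three rate sets (uM/s).
#' @return list of three [fit_michaelis_menten()] results: `low`, `mid`,
#'   `high`.
#' @export
fit_michaelis_menten_band <- function(conc, v_low, v_mid, v_high) {
  list(low = fit_michaelis_menten(conc, v_low),
       mid = fit_michaelis_menten(conc, v_mid),
       high = fit_michaelis_menten(conc, v_high))
}

#' Turnover number from a CABP active-site titration
#'
#' Reaction rates decline linearly with the concentration of the tight-binding
#' inhibitor CABP; the line's y-intercept is the uninhibited rate and its
#' x-intercept the active-site concentration, so
#' `kcat = y-intercept / x-intercept`, which algebraically equals the slope
#' magnitude. Rates in uM/s against CABP in uM give kcat in 1/s.
#'
#' @param cabp_um CABP concentrations (uM), at least 3.
#' @param rate_um_s reaction rates (uM/s).
#' @return kcat in 1/s.
#' @export
kcat_from_cabp <- function(cabp_um, rate_um_s) {
  if (length(unique(cabp_um)) < 3) stop("need at least 3 CABP concentrations")
  if (stats::sd(rate_um_s) == 0) stop("no titration signal")
  fit <- stats::lm(rate_um_s ~ cabp_um)
  b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || b >= 0) stop("no titration signal")
  -b
}

#' CO2/O2 specificity from MIMS velocities
#'
#' `S_C/O = v_C [O2] / (v_O [DIC])`: the carboxylation and oxygenation
#' velocities measured by membrane-inlet mass spectrometry, normalized by the
#' dissolved O2 and dissolved-inorganic-carbon concentrations at which they
#' were measured.
#'
#' @param nu_c carboxylation velocity.
#' @param nu_o oxygenation velocity (> 0).
#' @param o2_um dissolved O2 (uM).
#' @param dic_um dissolved inorganic carbon (uM, > 0).
#' @return the dimensionless specificity factor.
#' @export
specificity_from_mims <- function(nu_c, nu_o, o2_um, dic_um) {
  if (any(nu_o <= 0)) stop("no oxygenation detected")
  if (any(dic_um <= 0)) stop("dic_um must be positive")
  nu_c * o2_um / (nu_o * dic_um)
}

#' Dissolved CO2 from a bicarbonate concentration
#'
#' Henderson-Hasselbalch partitioning of the bicarbonate buffer:
#' `[CO2] = [HCO3-] / 10^(pH - pKa')`. The apparent pKa' of carbonic
#' acid/bicarbonate in assay buffer is configurable (6.35 at 25 C in dilute
#' solution).
#'
#' @param hco3_um bicarbonate concentration (uM).
#' @param ph assay pH.
#' @param pka apparent pKa'.
#' @return dissolved CO2 (uM).
#' @export
co2_from_bicarbonate <- function(hco3_um, ph = 8, pka = 6.35) {
  if (any(hco3_um < 0)) stop("hco3_um must be non-negative")
  hco3_um / 10^(ph - pka)
}
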