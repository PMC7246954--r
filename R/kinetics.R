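#' Normalize a reporter shut-off luminescence time series
#'
#' Each variant x replicate decay track is normalized to its luminescence at
#' time 0. Steady-state expression is the time-0 luminescence divided by the
#' per-strain normalization scalar (`cat_norm`, e.g. the expression of a
#' constitutive marker), then expressed relative to the mean steady state of
#' the `reference` variant.
#'
#' @param ts Data.frame with columns `variant`, `replicate`, `time_h`,
#'   `luminescence` and optionally `cat_norm` (default 1).
#' @param reference Variant whose mean steady state is scaled to 1, or `NULL`
#'   to skip the relative scaling.
#' @return List with `decay` (the input plus `norm_lum`) and `steady`
#'   (one row per variant x replicate with `steady_state`).
#' @export
normalize_series <- function(ts, reference = "P") {
  if (is.null(ts$cat_norm)) ts$cat_norm <- 1
  bad <- which(ts$luminescence <= 0)
  if (length(bad)) {
    stop("nonpositive luminescence at variant=", ts$variant[bad[1]],
         " replicate=", ts$replicate[bad[1]], " time=", ts$time_h[bad[1]])
  }
  key <- paste(ts$variant, ts$replicate)
  t0 <- ts[ts$time_h == 0, ]
  if (!all(unique(key) %in% paste(t0$variant, t0$replicate))) {
    stop("every variant x replicate needs a time-0 point")
  }
  lum0 <- stats::setNames(t0$luminescence, paste(t0$variant, t0$replicate))
  ts$norm_lum <- ts$luminescence / lum0[key]

  steady <- data.frame(variant = t0$variant, replicate = t0$replicate,
                       steady_state = t0$luminescence / t0$cat_norm,
                       stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    ref <- steady$steady_state[steady$variant == reference]
    if (length(ref) == 0L) stop("reference variant '", reference,
                                "' not present")
    steady$steady_state <- steady$steady_state / mean(ref)
  }
  list(decay = ts, steady = steady)
}

#' Fit first-order decay rates from normalized shut-off tracks
#'
#' For each variant x replicate, ordinary least squares of
#' log(normalized luminescence) on time over the post-shut-off time points
#' (free intercept; the time-0 point is excluded from the regression). The
#' degradation rate is d = -slope (per hour); the half-life is ln(2)/d.
#'
#' @param decay `decay` element of [normalize_series()] (needs `norm_lum`).
#' @param fit_times Time points used in the regression (hours).
#' @return A `decay_fit` data.frame with one row per variant x replicate:
#'   `d`, `intercept`, `r2`, `half_life`. Replicates with fewer than 3
#'   positive points at `fit_times` are excluded with a message; d <= 0 is
#'   reported with a warning (no decay) and an infinite half-life.
#' @export
fit_decay <- function(decay, fit_times = c(2, 4, 6, 8)) {
  out <- NULL
  for (key in unique(paste(decay$variant, decay$replicate, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- decay[decay$variant == parts[1] & decay$replicate == parts[2] &
                   decay$time_h %in% fit_times & decay$norm_lum > 0, ]
    if (nrow(sub) < 3L) {
      message("variant ", parts[1], " replicate ", parts[2],
              " excluded (fewer than 3 usable points)")
      next
    }
    fit <- stats::lm(log(norm_lum) ~ time_h, data = sub)
    d <- -unname(stats::coef(fit)[2])
    if (d <= 0) warning("variant ", parts[1], " replicate ", parts[2],
                        ": no decay (d <= 0)")
    out <- rbind(out, data.frame(
      variant = parts[1], replicate = parts[2], d = d,
      intercept = unname(stats::coef(fit)[1]),
      r2 = summary(fit)$r.squared,
      half_life = half_life(d), stringsAsFactors = FALSE))
  }
  if (is.null(out)) stop("no replicate could be fitted")
  class(out) <- c("decay_fit", "data.frame")
  out
}

#' Per-variant summary of replicate decay fits
#'
#' @param fits A `decay_fit` from [fit_decay()].
#' @return Data.frame with per-variant mean and SD of d (over replicates),
#'   the number of replicates, and the half-life of the mean rate.
#' @export
decay_summary <- function(fits) {
  v <- sort(unique(fits$variant))
  data.frame(
    variant = v,
    d_mean = as.numeric(tapply(fits$d, fits$variant, mean)[v]),
    d_sd = as.numeric(tapply(fits$d, fits$variant, stats::sd)[v]),
    n_replicates = as.integer(table(fits$variant)[v]),
    half_life = half_life(as.numeric(tapply(fits$d, fits$variant, mean)[v])),
    stringsAsFactors = FALSE)
}

#' Half-life of first-order decay
#'
#' @param d Degradation rate (per hour).
#' @return ln(2)/d hours; `Inf` when d <= 0 (no decay).
#' @export
half_life <- function(d) ifelse(d > 0, log(2) / d, Inf)

#' Regression of steady-state expression on inverse degradation rate
#'
#' Under a constant synthesis rate s, steady-state abundance follows
#' X = s/d, so X is linear in 1/d with slope s and zero intercept. Ordinary
#' least squares of X on 1/d (free intercept) quantifies, via the adjusted
#' R-squared, how much of the steady-state variation degradation explains.
#'
#' @param X Per-variant steady-state expression values.
#' @param d Per-variant degradation rates (all positive).
#' @return List with `s` (slope), `intercept`, `adj_r2` and the `lm` fit.
#' @export
steady_state_fit <- function(X, d) {
  stopifnot(length(X) == length(d), all(d > 0))
  if (length(X) < 3L) stop("need at least 3 variants")
  inv_d <- 1 / d
  fit <- stats::lm(X ~ inv_d)
  list(s = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       adj_r2 = summary(fit)$adj.r.squared,
       fit = fit)
}

#' Fold difference between two expression values
#'
#' @param x_a,x_b Values to compare (`x_b` must be nonzero).
#' @return `x_a / x_b`.
#' @export
fold_difference <- function(x_a, x_b) {
  if (any(x_b == 0)) stop("zero denominator")
  x_a / x_b
}

#' Two-sided independent t-test between two groups of values
#'
#' Equal-variance two-sample t-test, the convention used for all group
#' contrasts in the analyses. The degenerate case of two constant groups is
#' handled explicitly: equal means give p = 1.
#'
#' @param values Numeric vector.
#' @param labels Vector with exactly two distinct labels, parallel to
#'   `values`; each group needs at least 2 values.
#' @return List with `t`, `df`, `p`.
#' @export
group_compare <- function(values, labels) {
  gl <- unique(labels)
  stopifnot(length(gl) == 2L)
  a <- values[labels == gl[1]]; b <- values[labels == gl[2]]
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p = if (eq) 1 else 0))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
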