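## Effective diffusion from mean-squared displacement of a scalar
## coordinate: MSD curves, burst-phase-excluded linear fits, split-half
## uncertainty, drift diagnostics, energetic roughness.

kBoltzKcal <- 0.0019872041  # kcal / mol / K

#' Mean-squared displacement versus lag time
#'
#' For each lag tau on the series' sampling grid up to `maxLag`,
#' `msd(tau)` is the average of `(x(t + tau) - x(t))^2` over all frame
#' pairs separated by tau (overlapping pairs).  Lag 0 is included with
#' msd 0.
#'
#' @param series an [AngleSeries-class] on a uniform time grid.
#' @param maxLag largest lag, ns; must be smaller than the series span.
#' @param lagStride evaluate every `lagStride`-th grid lag (default 1,
#'   i.e. the full native grid).
#' @return an [MSDCurve-class].
#' @export
msdCurve <- function(series, maxLag, lagStride = 1L) {
  x <- series@values
  if (length(x) < 2L) stop("need at least 2 points")
  dt <- series@times[2] - series@times[1]
  span <- series@times[length(series@times)] - series@times[1]
  if (maxLag >= span) stop("maxLag must be smaller than the series span")
  kmax <- floor(maxLag / dt)
  if (kmax < 1L) stop("maxLag below the sampling interval")
  ks <- seq(lagStride, kmax, by = lagStride)
  res <- cpp_msd(x, as.integer(ks))
  new("MSDCurve", lags = c(0, ks * dt), msd = c(0, res$msd),
      nPairs = c(length(x), res$n_pairs),
      units = series@units)
}

#' Fit an effective diffusion coefficient to an MSD window
#'
#' Ordinary least squares of msd against lag over `[tauMin, tauMax]`
#' (burst phase excluded below `tauMin`); one-dimensional convention
#' `D = slope / 2`.  A negative slope floors D at 0 with a
#' `"negative_slope"` flag.  A `"low_correlation"` warning flag is set when
#' the linear correlation coefficient falls below 0.95 (the diffusive
#' fits this mirrors report 0.97-0.99), and a
#' `"non_diffusive_curvature"` flag when adding a quadratic term reduces
#' the residual variance by more than 50 percent (ballistic-like
#' curvature).
#'
#' @param curve an [MSDCurve-class].
#' @param tauMin,tauMax fit window, ns; at least 5 lag points must fall
#'   inside.
#' @param weighted weight lags by their pair counts (default `FALSE`,
#'   unweighted).
#' @return a [DiffusionEstimate-class].
#' @export
fitDiffusion <- function(curve, tauMin, tauMax, weighted = FALSE) {
  if (tauMin >= tauMax) stop("tauMin must be below tauMax")
  in.win <- curve@lags >= tauMin & curve@lags <= tauMax & curve@lags > 0
  if (sum(in.win) < 5L) stop("need at least 5 lag points in the fit window")
  lag <- curve@lags[in.win]; msd <- curve@msd[in.win]
  w <- if (weighted) curve@nPairs[in.win] else rep(1, length(lag))
  fit <- stats::lm(msd ~ lag, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  cc <- stats::cor(lag, msd)
  flags <- character(0)
  D <- slope / 2
  if (slope < 0) { D <- 0; flags <- c(flags, "negative_slope") }
  if (is.finite(cc) && cc < 0.95) {
    flags <- c(flags, "low_correlation")
    warning("MSD linear correlation ", format(cc, digits = 3),
            " is below the diffusive-linearity criterion (0.95)")
  }
  fit2 <- stats::lm(msd ~ lag + I(lag^2), weights = w)
  rss1 <- sum(stats::residuals(fit)^2)
  rss2 <- sum(stats::residuals(fit2)^2)
  quadAtMax <- abs(unname(stats::coef(fit2)[3])) * max(lag)^2
  predAtMax <- abs(unname(stats::predict(fit2))[which.max(lag)])
  if (rss1 > 0 && (1 - rss2 / rss1) > 0.5 &&
      quadAtMax > 0.2 * predAtMax)
    flags <- c(flags, "non_diffusive_curvature")
  new("DiffusionEstimate", D = D, tauMin = tauMin, tauMax = tauMax,
      slope = slope, intercept = intercept, corrCoeff = cc, flags = flags)
}

#' Barrier-height shift implied by two diffusion estimates
#'
#' At a fixed observed rate, swapping the diffusion coefficient from `d1`
#' to `d2` shifts the inferred barrier height by `|ln(d1 / d2)|` kT (the
#' rate depends on D and barrier only through `D * exp(-barrier)` up to
#' slowly varying prefactors).
#'
#' @param d1,d2 positive diffusion coefficients (same units).
#' @return barrier shift in kT.
#' @export
barrierShift <- function(d1, d2) {
  if (any(c(d1, d2) <= 0)) stop("diffusion coefficients must be > 0")
  abs(log(d1 / d2))
}

#' Split-half diffusion uncertainty
#'
#' Splits the series into two contiguous halves, estimates D independently
#' in each (own MSD curve and fit), and reports the implied barrier-height
#' shift `|ln(D1 / D2)|` kT.
#'
#' @inheritParams fitDiffusion
#' @param series an [AngleSeries-class].
#' @param maxLag largest lag for each half's MSD curve (default `tauMax`).
#' @param lagStride passed to [msdCurve()].
#' @return list with elements `first`, `second`
#'   ([DiffusionEstimate-class]) and `deltaBarrier` (kT; `NA` with a
#'   warning when either half yields D = 0).
#' @export
splitHalf <- function(series, tauMin, tauMax, maxLag = tauMax,
                      lagStride = 1L) {
  n <- length(series@values)
  half <- floor(n / 2)
  if (half < 4L) stop("series too short to split")
  mk <- function(idx) new("AngleSeries", label = series@label,
                          times = series@times[idx] - series@times[idx[1]],
                          values = series@values[idx],
                          units = series@units)
  e1 <- fitDiffusion(msdCurve(mk(1:half), maxLag, lagStride),
                     tauMin, tauMax)
  e2 <- fitDiffusion(msdCurve(mk((half + 1L):n), maxLag, lagStride),
                     tauMin, tauMax)
  delta <- if (e1@D > 0 && e2@D > 0) barrierShift(e1@D, e2@D) else {
    warning("one half yielded D = 0; barrier shift undefined")
    NA_real_
  }
  list(first = e1, second = e2, deltaBarrier = delta)
}

#' Linear drift of a coordinate over a time window
#'
#' @param series an [AngleSeries-class].
#' @param window numeric length 2, (t_start, t_end) in ns.
#' @return a [DriftEstimate-class]; slope in coordinate units per
#'   microsecond.
#' @export
driftEstimate <- function(series, window = range(series@times)) {
  keep <- series@times >= window[1] & series@times <= window[2]
  if (sum(keep) < 3L) stop("fewer than 3 points in drift window")
  fit <- stats::lm(series@values[keep] ~ series@times[keep])
  new("DriftEstimate", window = as.numeric(window),
      slope = unname(stats::coef(fit)[2]) * 1000,  # per ns -> per us
      intercept = unname(stats::coef(fit)[1]))
}

#' Energetic roughness from effective versus free diffusion
#'
#' Inverts `D_eff = D_free * exp(-(epsilon/kT)^2)`:
#' `epsilon = kT * sqrt(ln(D_free / D_eff))`.  Reported in kT and in
#' kcal/mol at the stated temperature (kT = 0.596 kcal/mol at 300 K).
#'
#' @param dEff,dFree positive diffusion coefficients, same units, with
#'   `dEff <= dFree`.
#' @param temperature Kelvin (default 300).
#' @return a [RoughnessEstimate-class].
#' @export
roughness <- function(dEff, dFree, temperature = 300) {
  if (dEff <= 0 || dFree <= 0) stop("diffusion coefficients must be > 0")
  if (dEff > dFree)
    stop("roughness undefined (effective exceeds free diffusion)")
  eps <- sqrt(log(dFree / dEff))
  new("RoughnessEstimate", epsilonKT = eps,
      epsilonKcal = eps * kBoltzKcal * temperature,
      dEff = dEff, dFree = dFree, temperature = temperature)
}

#' Suggest a burst-phase cutoff from an MSD curve
#'
#' Heuristic helper only, never applied silently: returns the smallest lag
#' beyond which the local log-log slope of the MSD stays within
#' `1 +/- slackSlope` (diffusive linearity), or `NA` when no such lag
#' exists.  Burst cutoffs should normally be chosen by inspection; typical
#' values are ~30 ns for rotation angles and ~10 ns for the tRNA
#' coordinate.
#'
#' @param curve an [MSDCurve-class].
#' @param slackSlope tolerance on the local slope (default 0.1).
#' @param windowPoints points per local fit (default 5).
#' @return lag in ns, or `NA`.
#' @export
suggestTauMin <- function(curve, slackSlope = 0.1, windowPoints = 5L) {
  pos <- curve@lags > 0 & curve@msd > 0
  lg <- log(curve@lags[pos]); lm_ <- log(curve@msd[pos])
  n <- length(lg)
  if (n < windowPoints + 1L) return(NA_real_)
  ok <- rep(FALSE, n - windowPoints + 1L)
  for (i in seq_along(ok)) {
    j <- i:(i + windowPoints - 1L)
    s <- stats::cov(lg[j], lm_[j]) / stats::var(lg[j])
    ok[i] <- abs(s - 1) <= slackSlope
  }
  run <- rev(cumprod(rev(ok)))  # 1 where all later windows are ok
  first <- which(run == 1)[1]
  if (is.na(first)) return(NA_real_)
  curve@lags[pos][first]
}
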