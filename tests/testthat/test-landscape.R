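test_that("profiles satisfy their endpoint, peak and symmetry constraints", {
  for (fam in c("piecewise_parabola", "quartic_smooth")) {
    p0 <- buildProfile(15, 7.5, 0, fam)
    expect_true(all(abs(profileEnergy(p0, seq(0, 15, 0.1))) < 1e-14))

    p <- buildProfile(15, 7.5, 10, fam)
    expect_equal(profileEnergy(p, c(0, 15)), c(0, 0), tolerance = 1e-14)
    expect_equal(profileEnergy(p, 7.5), 10)
    x <- seq(0, 15, 0.01)
    expect_equal(profileEnergy(p, x), profileEnergy(p, 15 - x),
                 tolerance = 1e-12)

    # asymmetric peak located by independent dense grid search
    pa <- buildProfile(15, 3, 8, fam)
    xg <- seq(0, 15, length.out = 20001)
    expect_equal(xg[which.max(profileEnergy(pa, xg))], 3,
                 tolerance = 1e-3)
    expect_equal(max(profileEnergy(pa, xg)), 8, tolerance = 1e-9)
  }
  expect_error(buildProfile(15, 15, 5), "inside")
  expect_error(buildProfile(15, 0, 5), "inside")
})

test_that("profile gradients match numerical differentiation", {
  for (fam in c("piecewise_parabola", "quartic_smooth")) {
    p <- buildProfile(12, 4, 6, fam)
    x <- seq(0.1, 11.9, 0.37)
    h <- 1e-6
    num <- (profileEnergy(p, x + h) - profileEnergy(p, x - h)) / (2 * h)
    expect_equal(profileGradient(p, x), num, tolerance = 1e-6)
  }
})

test_that("MFPT reduces to the flat closed form and matches the trapezoid oracle", {
  for (L in c(15, 22)) for (D in c(0.06, 1)) {
    p0 <- buildProfile(L, L / 2, 0)
    expect_equal(mfpt(p0, D), L^2 / (2 * D), tolerance = 0.005)
  }
  for (fam in c("piecewise_parabola", "quartic_smooth"))
    for (xts in c(3, 7.5)) {
      p <- buildProfile(15, xts, 10, fam)
      expect_equal(mfpt(p, 1), oracleMfpt(p, 1), tolerance = 1e-3)
      expect_equal(mfpt(p, 1, from = "right"),
                   oracleMfpt(p, 1, from = "right"), tolerance = 1e-3)
    }
})

test_that("MFPT is invariant under coordinate rescaling", {
  p <- buildProfile(15, 6, 7)
  pScaled <- buildProfile(150, 60, 7)
  expect_equal(mfpt(p, 1), mfpt(pScaled, 100), tolerance = 1e-6)
})

test_that("the Kramers rate scales linearly in D and exponentially in barrier", {
  p <- buildProfile(15, 7.5, 10, "quartic_smooth")
  expect_equal(kramersRate(p, 2) / kramersRate(p, 1), 2,
               tolerance = 1e-12)
  # with endpoint-constrained shapes the curvatures scale with the
  # barrier, so ln k = const + ln(barrier) - barrier exactly
  bs <- seq(8, 15, 1)
  lnk <- vapply(bs, function(b)
    log(kramersRate(buildProfile(15, 7.5, b, "quartic_smooth"), 1)),
    numeric(1))
  expect_lt(diff(range(lnk - log(bs) + bs)), 1e-12)
  slope <- unname(coef(lm(lnk ~ bs))[2])
  expect_equal(slope, -1 + cov(log(bs), bs) / var(bs), tolerance = 1e-9)
  expect_error(kramersRate(buildProfile(15, 7.5, 1, "quartic_smooth"), 1),
               ">= 2")
})

test_that("rate-barrier curves are monotone, log-concave and oracle-accurate", {
  cv <- rateVsBarrier(D = 1, L = 15, barriers = c(0.5, seq(2, 20, 2)))
  expect_true(all(diff(cv@rates) < 0))
  # log-concave in the barrier: the prefactor grows with barrier height
  # and the flat-landscape floor dominates at small barriers
  lnr <- log(cv@rates)
  expect_true(all(diff(diff(lnr[cv@barriers >= 2])) < 1e-8))

  # flat barrier -> 2 D / L^2
  flat <- 1 / mfpt(buildProfile(15, 7.5, 1e-12), 1)
  expect_equal(flat, 2 / 15^2, tolerance = 1e-6)

  for (j in seq_along(cv@barriers))
    expect_equal(cv@rates[j],
                 1 / oracleMfpt(buildProfile(15, 7.5, cv@barriers[j]), 1),
                 tolerance = 1e-3)
})

test_that("attempt frequencies are recovered, plateau, and scale with D", {
  synth <- new("RateBarrierCurve", barriers = 5:15,
               rates = 7 * exp(-(5:15)), D = 1, L = 15, xTs = 7.5,
               family = "piecewise_parabola")
  af <- attemptFrequency(synth)
  expect_equal(af@nu, 7, tolerance = 1e-6)
  expect_lt(af@residualRMS, 1e-10)

  # the fitted prefactor tracks the barrier-dependent curvature of the
  # profile family; the window dependence matches the independent
  # trapezoid oracle and stays within a factor of two
  cv <- rateVsBarrier(D = 1, L = 15, barriers = seq(6, 14, 1))
  nuLow <- suppressWarnings(attemptFrequency(cv, fitRange = c(6, 10)))@nu
  nuHigh <- suppressWarnings(attemptFrequency(cv,
                                              fitRange = c(10, 14)))@nu
  oracleRates <- vapply(6:14, function(b)
    1 / oracleMfpt(buildProfile(15, 7.5, b), 1), numeric(1))
  lnnu <- function(idx) mean(log(oracleRates[idx]) + (6:14)[idx])
  expect_equal(nuLow / nuHigh, exp(lnnu(1:5) - lnnu(5:9)),
               tolerance = 1e-3)
  expect_lt(abs(log(nuLow / nuHigh)), log(2))

  cv2 <- rateVsBarrier(D = 2, L = 15, barriers = seq(6, 14, 1))
  expect_equal(suppressWarnings(attemptFrequency(cv2))@nu /
                 suppressWarnings(attemptFrequency(cv))@nu, 2,
               tolerance = 0.01)
  cv3 <- rateVsBarrier(D = 1, L = 15, barriers = 3:8)
  expect_error(attemptFrequency(cv3, fitRange = c(3, 6)), ">= 5")
})

test_that("barrier inversion round-trips and flags barrierless rates", {
  p8 <- buildProfile(22, 11, 8)
  rate8 <- 1 / mfpt(p8, 0.5)
  inv <- invertBarrier(rate8, D = 0.5, L = 22)
  expect_equal(inv$barrierKT, 8, tolerance = 1e-4)
  expect_equal(inv$barrierKcal, 8 * 0.596, tolerance = 0.01)

  flat <- invertBarrier(2 * 0.5 / 22^2, D = 0.5, L = 22)
  expect_equal(flat$barrierKT, 0)
  expect_match(flat$flag, "no barrier required")

  # doubling D at fixed observed rate raises the bound by ln 2 plus the
  # prefactor correction: the Kramers closed form k ~ D B exp(-B) gives
  # the shift as the root of B2 - ln B2 = B1 - ln B1 + ln 2
  r <- 1 / mfpt(buildProfile(15, 7.5, 9), 1)
  b1 <- invertBarrier(r, D = 1, L = 15)$barrierKT
  b2 <- invertBarrier(r, D = 2, L = 15)$barrierKT
  f <- function(B) B - log(B)
  b2pred <- uniroot(function(B) f(B) - (f(b1) + log(2)),
                    c(b1, b1 + 2))$root
  expect_equal(b2 - b1, b2pred - b1, tolerance = 0.1)
})

test_that("rates are robust to peak position and functional form", {
  single <- robustnessScan(1, 15, 8, peaks = 7.5)
  expect_equal(single$ratio, 1)

  rs <- robustnessScan(1, 15, 10, peaks = c(3, 7.5, 12))
  expect_lte(rs$ratio, 2)
  expect_equal(rs$impliedBarrierSpread, log(rs$ratio))
  expect_lt(rs$impliedBarrierSpread, 1)

  # peak-position robustness holds within each functional family
  for (fam in c("piecewise_parabola", "quartic_smooth"))
    expect_lte(robustnessScan(1, 15, 8, peaks = c(0.2, 0.5, 0.8) * 15,
                              family = fam)$ratio, 2)
})
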