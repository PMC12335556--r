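test_that("P2 autocorrelation handles degenerate geometries", {
  n <- 10
  vc <- vectorSeries(1L, (0:(n - 1)) * 10,
                     matrix(rep(c(0, 0, 1), each = n), n, 3))
  expect_equal(acfValues(computeP2Acf(vc, 1)), rep(1, n))

  v2 <- vectorSeries(1L, c(0, 10), rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(acfValues(computeP2Acf(v2, 1))[2], -0.5)

  expect_error(
    computeP2Acf(vectorSeries(1L, 0, matrix(c(0, 0, 1), 1, 3))),
    "at least 2 frames"
  )
})

test_that("P2 autocorrelation equals the brute-force double loop", {
  set.seed(31)
  for (rep in 1:3) {
    v <- matrix(rnorm(30), 10, 3)
    v <- v / sqrt(rowSums(v^2))
    vs <- vectorSeries(1L, (0:9) * 10, v)
    expect_equal(acfValues(computeP2Acf(vs, 1)), oracle_p2_acf(v),
                 tolerance = 1e-12)
  }
})

test_that("maxLagFraction truncates the lag grid", {
  set.seed(8)
  v <- matrix(rnorm(60), 20, 3)
  v <- v / sqrt(rowSums(v^2))
  vs <- vectorSeries(1L, (0:19) * 10, v)
  acf <- computeP2Acf(vs, 0.5)
  expect_equal(length(acfLags(acf)), floor(0.5 * 19) + 1L)
  expect_equal(acfValues(acf)[1], 1)
  expect_error(computeP2Acf(vs, 0), "maxLagFraction")
})

test_that("default timescale grid spans 1 ps to 100 ns with 100 points", {
  g <- buildTimescaleGrid()
  tg <- taus(g)
  expect_length(tg, 100L)
  expect_identical(tg[1], 1e-12)
  expect_identical(tg[100], 1e-7)
  lr <- diff(log(tg))
  expect_lt(max(abs(lr - lr[1])), 1e-12)
})

test_that("small grids hit their endpoints and log midpoints", {
  g2 <- buildTimescaleGrid(2, 1e-12, 1e-7)
  expect_equal(taus(g2), c(1e-12, 1e-7))
  g3 <- buildTimescaleGrid(3, 1e-12, 1e-10)
  expect_equal(taus(g3)[2], 1e-11, tolerance = 1e-12)
  expect_error(buildTimescaleGrid(1), "n must be")
  expect_error(buildTimescaleGrid(10, -1, 1), "tauMin")
})

test_that("NNLS recovers exactly representable decays", {
  g <- buildTimescaleGrid()
  tg <- taus(g)
  lags <- seq(0, 5e4, by = 250)

  # single on-grid timescale
  acf1 <- makeAcf(1, tg[70], lags)
  sp1 <- fitExponentialSum(acf1, g)
  expect_gte(alphas(sp1)[70], 0.999)
  expect_lt(max(alphas(sp1)[-70]), 1e-6)

  # two on-grid components
  acf2 <- makeAcf(c(0.3, 0.7), c(tg[60], tg[80]), lags)
  sp2 <- fitExponentialSum(acf2, g)
  expect_equal(alphas(sp2)[60], 0.3, tolerance = 1e-6)
  expect_equal(alphas(sp2)[80], 0.7, tolerance = 1e-6)
})

test_that("a non-decaying ACF loads the slowest timescale", {
  g <- buildTimescaleGrid()
  lags <- seq(0, 5e4, by = 250)
  acf <- correlationFunction(1L, lags, rep(1, length(lags)))
  sp <- fitExponentialSum(acf, g)
  w <- alphas(sp)
  expect_equal(sum(w[-100]), 0)
  # residual equals the single-column least-squares oracle on tau_max
  A <- exp(-lags * 1e-12 / taus(g)[100])
  beta <- sum(A) / sum(A^2)
  expect_equal(fitResidual(sp), sqrt(sum((beta * A - 1)^2)),
               tolerance = 1e-9)
})

test_that("fits on noiseless grid mixtures reproduce the ACF everywhere", {
  g <- buildTimescaleGrid()
  tg <- taus(g)
  lags <- seq(0, 2e4, by = 100)
  w <- c(0.2, 0.5, 0.3)
  idx <- c(45, 65, 85)
  acf <- makeAcf(w, tg[idx], lags)
  sp <- fitExponentialSum(acf, g)
  recon <- as.numeric(exp(-outer(lags * 1e-12, 1 / tg)) %*% alphas(sp))
  expect_equal(recon, acfValues(acf), tolerance = 1e-9)
})

test_that("all-NaN correlation functions are rejected", {
  g <- buildTimescaleGrid()
  acf <- correlationFunction(1L, c(0, 10, 20), c(1, 0.5, 0.4))
  acf@values <- rep(NaN, 3)
  expect_error(fitExponentialSum(acf, g), "all-NaN")
})

test_that("spectral density is a sum of Lorentzians", {
  g <- buildTimescaleGrid()
  s5 <- single_tau_spectrum(5e-9, g)
  expect_equal(spectralDensity(s5$spectrum, 0), 2 * s5$tau)
  expect_equal(spectralDensity(s5$spectrum, 1 / s5$tau), s5$tau)

  # linearity of mixtures
  tg <- taus(g)
  a <- numeric(100)
  a[c(40, 80)] <- c(0.4, 0.6)
  sp <- new("TimescaleSpectrum", grid = g, alphas = a, fitResidual = 0)
  w <- 2 * pi * 6e8
  expect_equal(
    spectralDensity(sp, w),
    0.4 * 2 * tg[40] / (1 + (w * tg[40])^2) +
      0.6 * 2 * tg[80] / (1 + (w * tg[80])^2),
    tolerance = 1e-15
  )
  # evenness
  expect_equal(spectralDensity(sp, -w), spectralDensity(sp, w))
})

test_that("observables match the closed-form single-Lorentzian oracle", {
  g <- buildTimescaleGrid()
  for (tau in c(1e-11, 1e-9, 5e-9, 2e-8)) {
    for (field in c(600, 800, 850)) {
      s <- single_tau_spectrum(tau, g)
      got <- relaxationObservables(s$spectrum, nmrParams(field))
      want <- oracle_redfield(s$tau, field)
      expect_equal(got$t1, want$t1, tolerance = 1e-10)
      expect_equal(got$t2, want$t2, tolerance = 1e-10)
      expect_equal(got$hetnoe, want$hetnoe, tolerance = 1e-10)
    }
  }
})

test_that("extreme narrowing gives T1 = T2 and the analytic maximum NOE", {
  p <- nmrParams(600, deltaSigma = 0)
  s <- single_tau_spectrum(1e-12)
  obs <- relaxationObservables(s$spectrum, p)
  expect_equal(obs$t1 / obs$t2, 1, tolerance = 0.01)
  expect_equal(obs$hetnoe, 1 + 0.5 * p@gammaH / p@gammaN, tolerance = 0.01)
})

test_that("CSA and bond length propagate into the rates", {
  p <- nmrParams(600)
  expect_equal(p@deltaSigma, -160)
  expect_equal(p@rNH, 0.101)
  # d ~ 1/r^3
  d1 <- dipolarCoupling(p)
  d2 <- dipolarCoupling(nmrParams(600, rNH = 0.202))
  expect_equal(d1 / d2, 8, tolerance = 1e-12)
  expect_equal(
    d1,
    p@mu0 * p@hbar * p@gammaH * p@gammaN / (4 * pi * (0.101e-9)^3),
    tolerance = 1e-12
  )
  # switching off CSA lengthens T1 at slow tumbling
  s <- single_tau_spectrum(5e-9)
  with_csa <- relaxationObservables(s$spectrum, nmrParams(850))
  no_csa <- relaxationObservables(s$spectrum, nmrParams(850, deltaSigma = 0))
  expect_gt(no_csa$t1, with_csa$t1)
  expect_gt(no_csa$t2, with_csa$t2)
})

test_that("the NOE sign convention changes only the cross term", {
  s <- single_tau_spectrum(5e-9)
  minus <- relaxationObservables(s$spectrum, nmrParams(600))
  plus <- relaxationObservables(
    s$spectrum, nmrParams(600, noeSignConvention = "paper_plus")
  )
  expect_equal(minus$t1, plus$t1)
  expect_equal(minus$t2, plus$t2)
  expect_false(isTRUE(all.equal(minus$hetnoe, plus$hetnoe)))
  want <- oracle_redfield(s$tau, 600, noe_minus = FALSE)
  expect_equal(plus$hetnoe, want$hetnoe, tolerance = 1e-10)
})

test_that("dipolar-only T2 shrinks as weight moves to slower timescales", {
  g <- buildTimescaleGrid()
  p <- nmrParams(600, deltaSigma = 0)
  t2s <- sapply(seq(20, 95, by = 15), function(i) {
    a <- numeric(100)
    a[i] <- 1
    relaxationObservables(
      new("TimescaleSpectrum", grid = g, alphas = a, fitResidual = 0), p
    )$t2
  })
  expect_true(all(diff(t2s) < 0))
})

test_that("effective correlation time is the plain weighted sum", {
  g <- buildTimescaleGrid()
  s <- single_tau_spectrum(5e-9, g)
  expect_equal(effectiveTau(s$spectrum), s$tau)

  tg <- taus(g)
  a <- numeric(100)
  i1 <- which.min(abs(tg - 1e-9))
  i2 <- which.min(abs(tg - 1e-8))
  a[c(i1, i2)] <- c(0.3, 0.7)
  sp <- new("TimescaleSpectrum", grid = g, alphas = a, fitResidual = 0)
  expect_equal(effectiveTau(sp), 0.3 * tg[i1] + 0.7 * tg[i2])
  # note: NOT normalized by sum(alpha) - halving the weights halves tau_eff
  sp2 <- new("TimescaleSpectrum", grid = g, alphas = a / 2, fitResidual = 0)
  expect_equal(effectiveTau(sp2), effectiveTau(sp) / 2)

  sp0 <- new("TimescaleSpectrum", grid = g, alphas = numeric(100),
             fitResidual = 0)
  expect_equal(effectiveTau(sp0), 0)
})

test_that("averaging correlation functions is a pointwise mean", {
  lags <- seq(0, 1e4, by = 100)
  a1 <- makeAcf(1, 2e-9, lags, residueId = 4)
  a2 <- makeAcf(1, 8e-9, lags, residueId = 4)
  expect_equal(acfValues(averageAcfs(list(a1))), acfValues(a1))
  expect_equal(acfValues(averageAcfs(list(a1, a1))), acfValues(a1))
  avg <- averageAcfs(list(a1, a2))
  expect_equal(acfValues(avg), (acfValues(a1) + acfValues(a2)) / 2,
               tolerance = 1e-15)
  expect_equal(nContributing(avg), 2L)

  a3 <- makeAcf(1, 2e-9, lags, residueId = 9)
  expect_error(averageAcfs(list(a1, a3)), "different residues")
})

test_that("averaging truncates to the shortest common lag range", {
  a1 <- makeAcf(1, 2e-9, seq(0, 1e4, by = 100), residueId = 1)
  a2 <- makeAcf(1, 2e-9, seq(0, 5e3, by = 100), residueId = 1)
  avg <- averageAcfs(list(a1, a2))
  expect_length(acfLags(avg), length(acfLags(a2)))
})

test_that("timescale landscapes bin weights and conserve total mass", {
  g <- buildTimescaleGrid()
  s <- single_tau_spectrum(5e-9, g)
  edges <- c(2, 6, 12) * 1e-9
  land <- timescaleLandscape(list(r1 = s$spectrum), edges)
  expect_equal(unname(land[1, ]), c(1, 0))

  # split weight reports per-bin masses and conserves the total
  tg <- taus(g)
  a <- numeric(100)
  i1 <- which.min(abs(tg - 3e-9))
  i2 <- which.min(abs(tg - 8e-9))
  a[c(i1, i2)] <- c(0.75, 0.25)
  sp <- new("TimescaleSpectrum", grid = g, alphas = a, fitResidual = 0)
  land2 <- timescaleLandscape(list(r = sp), edges)
  expect_equal(unname(land2[1, ]), c(0.75, 0.25))
  expect_equal(sum(land2[1, ]), sum(alphas(sp)), tolerance = 1e-12)

  expect_error(timescaleLandscape(list(), edges), "empty")
  expect_error(timescaleLandscape(list(r = sp), c(4e-9, 6e-9)), "span")
})

test_that("a seeded diffusive rotor recovers its correlation time", {
  vs <- simulateIsotropicRotor(Dr = 1 / (6 * 5e-9), dtPs = 10,
                               nSteps = 100000, seed = 1)
  sp <- fitExponentialSum(computeP2Acf(vs, 0.5), buildTimescaleGrid())
  expect_equal(effectiveTau(sp), 5e-9, tolerance = 0.1)
})
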