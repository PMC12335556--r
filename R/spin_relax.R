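## Physics core: P2 autocorrelation of bond vectors, multi-exponential
## fitting on a fixed logarithmic timescale grid, spectral densities, and
## Redfield relaxation observables.

#' Second-order rotational autocorrelation of a bond vector
#'
#' Computes g(t) = < P2(cos theta) > where theta is the angle between the
#' bond vector at times t' and t' + t, averaged over every origin t'.
#' P2 is the second Legendre polynomial, 3/2 cos^2(theta) - 1/2.
#'
#' Implementation: cos^2(theta) between two unit vectors is a sum of
#' products of the six independent entries of the outer product v v^T, so
#' the all-origins average reduces to six autocorrelations computed with
#' FFTs in O(n log n). The lag-zero value is exactly 1.
#'
#' @param series a [VectorSeries-class] with at least 2 frames.
#' @param maxLagFraction maximum lag as a fraction of the series duration,
#'   in (0, 1]; default 0.5.
#' @return a [CorrelationFunction-class].
#' @export
computeP2Acf <- function(series, maxLagFraction = 0.5) {
  stopifnot(is(series, "VectorSeries"))
  v <- series@vectors
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 frames to compute a correlation function")
  if (!(maxLagFraction > 0 && maxLagFraction <= 1))
    stop("maxLagFraction must be in (0, 1]")

  # six unique entries of v v^T; cross-term weight 2
  W <- cbind(
    v[, 1]^2, v[, 2]^2, v[, 3]^2,
    v[, 1] * v[, 2], v[, 1] * v[, 3], v[, 2] * v[, 3]
  )
  wts <- c(1, 1, 1, 2, 2, 2)

  nlag <- floor(maxLagFraction * (n - 1)) + 1L
  m <- stats::nextn(2L * n)
  S <- numeric(nlag)
  for (j in seq_len(6L)) {
    f <- stats::fft(c(W[, j], numeric(m - n)))
    ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / m
    S <- S + wts[j] * ac[seq_len(nlag)]
  }
  g <- 1.5 * S / (n - seq_len(nlag) + 1L) - 0.5
  g[1] <- 1

  dt <- frameSpacing(series)
  correlationFunction(
    residueId = series@residueId,
    lags = (seq_len(nlag) - 1L) * dt,
    values = g,
    nContributing = 1L
  )
}

#' Build a logarithmic grid of candidate correlation times
#'
#' `n` timescales equidistant in log space between `tauMin` and `tauMax`,
#' endpoints included exactly. Defaults: 100 points from 1 ps to 100 ns.
#'
#' @param n number of grid points (>= 2).
#' @param tauMin,tauMax grid endpoints in seconds.
#' @return a [TimescaleGrid-class].
#' @examples
#' g <- buildTimescaleGrid()
#' range(taus(g)) # 1e-12 .. 1e-7 s
#' @export
buildTimescaleGrid <- function(n = 100L, tauMin = 1e-12, tauMax = 1e-7) {
  if (n < 2L) stop("n must be >= 2")
  if (!(tauMin > 0 && tauMax > tauMin))
    stop("need 0 < tauMin < tauMax")
  taus <- exp(seq(log(tauMin), log(tauMax), length.out = n))
  taus[1] <- tauMin
  taus[n] <- tauMax
  new("TimescaleGrid", taus = taus)
}

#' Fit a correlation function to a sum of exponential decays
#'
#' Solves `min || sum_i alpha_i exp(-t/tau_i) - g(t) ||_2` subject to
#' `alpha_i >= 0` on the fixed design matrix of grid timescales
#' (non-negative least squares). No sum constraint is imposed on the
#' weights; g(0) = 1 keeps them near unit total mass. Solved with
#' Lawson-Hanson NNLS on the full design matrix (the design is strongly
#' rank-deficient in double precision - neighbouring exponentials are
#' nearly collinear - which NNLS handles, pivoted factorizations do not).
#'
#' @param acf a [CorrelationFunction-class]; NaN lags are dropped.
#' @param grid a [TimescaleGrid-class].
#' @return a [TimescaleSpectrum-class].
#' @export
fitExponentialSum <- function(acf, grid) {
  stopifnot(is(acf, "CorrelationFunction"), is(grid, "TimescaleGrid"))
  t_s <- acf@lags * 1e-12
  g <- acf@values
  ok <- is.finite(g)
  if (!any(ok)) stop("correlation function is all-NaN")
  t_s <- t_s[ok]
  g <- g[ok]
  if (length(g) < 2L) stop("need at least 2 finite lags to fit")

  A <- exp(-outer(t_s, 1 / grid@taus))
  alphas <- pmax(pracma::lsqnonneg(A, g)$x, 0)
  resid <- sqrt(sum((A %*% alphas - g)^2))
  new("TimescaleSpectrum",
    grid = grid, alphas = as.numeric(alphas), fitResidual = resid
  )
}

#' Spectral density of a timescale spectrum
#'
#' Analytical Fourier transform of the fitted multi-exponential
#' correlation function: `J(w) = sum_i alpha_i * 2 tau_i / (1 + (w tau_i)^2)`,
#' so `J(0) = 2 sum_i alpha_i tau_i`. J is even; the magnitude of `omega`
#' is used.
#'
#' @param spectrum a [TimescaleSpectrum-class].
#' @param omega angular frequency (rad/s), may be a vector.
#' @return spectral density values in s/rad.
#' @export
spectralDensity <- function(spectrum, omega) {
  stopifnot(is(spectrum, "TimescaleSpectrum"))
  tau <- spectrum@grid@taus
  a <- spectrum@alphas
  vapply(abs(omega), function(w) {
    sum(a * 2 * tau / (1 + (w * tau)^2))
  }, numeric(1))
}

#' Dipolar coupling constant
#'
#' `d_NH = mu0 hbar gammaH gammaN / (4 pi <r_NH^3>)` in rad/s; negative
#' because the 15N gyromagnetic ratio is negative. Only its square enters
#' the relaxation rates.
#'
#' @param params an [NMRParams-class].
#' @return the coupling constant in rad/s.
#' @export
dipolarCoupling <- function(params) {
  stopifnot(is(params, "NMRParams"))
  r <- params@rNH * 1e-9
  params@mu0 * params@hbar * params@gammaH * params@gammaN / (4 * pi * r^3)
}

#' Larmor frequencies implied by an NMRParams object
#'
#' @param params an [NMRParams-class].
#' @return named numeric: `omegaH` (rad/s, positive) and `omegaN`
#'   (rad/s, negative).
#' @export
larmorFrequencies <- function(params) {
  stopifnot(is(params, "NMRParams"))
  wH <- 2 * pi * params@fieldMhz * 1e6
  c(omegaH = wH, omegaN = wH * params@gammaN / params@gammaH)
}

#' Redfield relaxation observables from a timescale spectrum
#'
#' Computes backbone 15N T1 and T2 relaxation times and the heteronuclear
#' NOE from the spectral density of a fitted timescale spectrum, using
#' the dipolar (N-H) and chemical-shift-anisotropy relaxation mechanisms:
#'
#' \deqn{1/T_1 = \frac{d^2 N_H}{20}[J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H+\omega_N)] + \frac{(\Delta\sigma\,\omega_N)^2}{15}
#'   J(\omega_N)}
#' \deqn{1/T_2 = \frac{1}{2}\frac{d^2 N_H}{20}[4J(0) +
#'   J(\omega_H-\omega_N) + 3J(\omega_N) + 6J(\omega_H) +
#'   6J(\omega_H+\omega_N)] + \frac{(\Delta\sigma\,\omega_N)^2}{90}
#'   [4J(0) + 3J(\omega_N)]}
#'
#' The NOE uses `hetNOE = 1 + (d^2 N_H / 20) C (gammaH/gammaN) T1` where
#' the cross-relaxation combination C is `6J(wH+wN) - J(wH-wN)` under the
#' default `standard_minus` convention (the only one able to produce the
#' negative NOE values of highly flexible residues) or
#' `J(wH-wN) + 6J(wH+wN)` under `paper_plus`.
#'
#' Spectral-density arguments use magnitudes of the frequency
#' combinations (J is even and `omegaN < 0`).
#'
#' @param spectrum a [TimescaleSpectrum-class].
#' @param params an [NMRParams-class].
#' @return named list with elements `t1` (s), `t2` (s), `hetnoe`.
#' @examples
#' grid <- buildTimescaleGrid()
#' sp <- new("TimescaleSpectrum", grid = grid,
#'           alphas = as.numeric(taus(grid) == taus(grid)[50]),
#'           fitResidual = 0)
#' relaxationObservables(sp, nmrParams(600))
#' @export
relaxationObservables <- function(spectrum, params) {
  stopifnot(is(spectrum, "TimescaleSpectrum"), is(params, "NMRParams"))
  w <- larmorFrequencies(params)
  wH <- w[["omegaH"]]
  wN <- w[["omegaN"]]

  J <- function(x) spectralDensity(spectrum, abs(x))
  J0 <- J(0)
  JN <- J(wN)
  JH <- J(wH)
  Jm <- J(wH - wN)
  Jp <- J(wH + wN)

  d2 <- dipolarCoupling(params)^2
  dip <- d2 * params@nH / 20
  csaw <- (params@deltaSigma * 1e-6 * wN)^2

  r1 <- dip * (Jm + 3 * JN + 6 * Jp) + csaw / 15 * JN
  r2 <- 0.5 * dip * (4 * J0 + Jm + 3 * JN + 6 * JH + 6 * Jp) +
    csaw / 90 * (4 * J0 + 3 * JN)
  if (r1 <= 0 || r2 <= 0) stop("non-positive relaxation rate")
  t1 <- 1 / r1
  t2 <- 1 / r2

  cross <- switch(params@noeSignConvention,
    standard_minus = 6 * Jp - Jm,
    paper_plus = Jm + 6 * Jp
  )
  hetnoe <- 1 + dip * cross * params@gammaH / params@gammaN * t1
  list(t1 = t1, t2 = t2, hetnoe = hetnoe)
}

#' Effective correlation time
#'
#' The integral of the fitted correlation function,
#' `tau_eff = sum_i alpha_i tau_i` (the plain weighted sum, not
#' normalized by the total weight).
#'
#' @param spectrum a [TimescaleSpectrum-class].
#' @return effective correlation time in seconds.
#' @export
effectiveTau <- function(spectrum) {
  stopifnot(is(spectrum, "TimescaleSpectrum"))
  sum(spectrum@alphas * spectrum@grid@taus)
}

#' Average correlation functions across trajectories
#'
#' Pointwise unweighted mean of correlation functions for the same
#' residue, truncated to the shortest common lag range. This is how the
#' combined ensemble's correlation functions are formed from the selected
#' simulations.
#'
#' @param acfs list of [CorrelationFunction-class] sharing residue ID and
#'   lag spacing.
#' @return a [CorrelationFunction-class] with `nContributing` equal to
#'   the sum over inputs.
#' @export
averageAcfs <- function(acfs) {
  if (!length(acfs)) stop("no correlation functions to average")
  rid <- unique(vapply(acfs, function(a) a@residueId, integer(1)))
  if (length(rid) != 1L)
    stop("cannot average correlation functions of different residues: ",
         paste(rid, collapse = ", "))
  dts <- vapply(acfs, function(a) {
    if (length(a@lags) >= 2) diff(a@lags[1:2]) else NA_real_
  }, numeric(1))
  if (any(is.finite(dts)) &&
      max(abs(dts - dts[1]), na.rm = TRUE) > 1e-9 * max(dts, na.rm = TRUE))
    stop("lag spacings differ between correlation functions")
  nmin <- min(vapply(acfs, function(a) length(a@lags), integer(1)))
  vals <- rowMeans(vapply(acfs, function(a) a@values[seq_len(nmin)],
                          numeric(nmin)))
  correlationFunction(
    residueId = rid,
    lags = acfs[[1]]@lags[seq_len(nmin)],
    values = vals,
    nContributing = sum(vapply(acfs, function(a) a@nContributing,
                               integer(1)))
  )
}

#' Bin per-residue timescale weights into a dynamic landscape
#'
#' Sums each residue's fitted weights within timescale bins
#' `[edge_k, edge_{k+1})`, producing the per-residue distribution of
#' rotational timescales used to read off, e.g., which residues are
#' dominated by overall tumbling and which by fast local motion.
#'
#' @param spectra named list of [TimescaleSpectrum-class], one per
#'   residue.
#' @param binEdges increasing bin edges in seconds; every grid timescale
#'   carrying weight must fall inside `[min(edges), max(edges))`.
#' @return numeric matrix, residues x bins; row sums equal each
#'   spectrum's total weight.
#' @export
timescaleLandscape <- function(spectra, binEdges) {
  if (!length(spectra)) stop("empty spectra list")
  if (any(diff(binEdges) <= 0)) stop("bin edges must be increasing")
  nb <- length(binEdges) - 1L
  out <- matrix(0, nrow = length(spectra), ncol = nb)
  bin_names <- paste0("[", signif(binEdges[-length(binEdges)] * 1e9, 3),
                      ",", signif(binEdges[-1] * 1e9, 3), ") ns")
  rownames(out) <- if (!is.null(names(spectra))) names(spectra) else
    as.character(seq_along(spectra))
  colnames(out) <- bin_names
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    stopifnot(is(sp, "TimescaleSpectrum"))
    tau <- sp@grid@taus
    a <- sp@alphas
    active <- a > 0
    if (any(active & (tau < binEdges[1] | tau >= binEdges[length(binEdges)])))
      stop("bin edges do not span all timescales carrying weight")
    idx <- findInterval(tau, binEdges, rightmost.closed = FALSE)
    for (b in seq_len(nb)) out[i, b] <- sum(a[idx == b])
  }
  out
}

#' Predict a relaxation profile from per-residue correlation functions
#'
#' Convenience wrapper over [fitExponentialSum()] and
#' [relaxationObservables()]: fits every correlation function on the
#' grid and back-calculates T1, T2 and hetNOE.
#'
#' @param acfs list of [CorrelationFunction-class].
#' @param params an [NMRParams-class].
#' @param grid a [TimescaleGrid-class]; default [buildTimescaleGrid()].
#' @return list with `profile` (a [RelaxationProfile-class]) and
#'   `spectra` (named list of [TimescaleSpectrum-class] keyed by residue).
#' @export
predictProfile <- function(acfs, params, grid = buildTimescaleGrid()) {
  if (!length(acfs)) stop("no correlation functions supplied")
  rids <- vapply(acfs, function(a) a@residueId, integer(1))
  spectra <- lapply(acfs, fitExponentialSum, grid = grid)
  names(spectra) <- as.character(rids)
  obs <- lapply(spectra, relaxationObservables, params = params)
  list(
    profile = relaxationProfile(
      residueIds = rids,
      t1 = vapply(obs, `[[`, numeric(1), "t1"),
      t2 = vapply(obs, `[[`, numeric(1), "t2"),
      hetnoe = vapply(obs, `[[`, numeric(1), "hetnoe"),
      fieldMhz = params@fieldMhz
    ),
    spectra = spectra
  )
}
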