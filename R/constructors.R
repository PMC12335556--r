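#' Construct a VectorSeries
#'
#' @param residueId integer residue number.
#' @param times frame times in ps, equally spaced.
#' @param vectors `n x 3` matrix of bond vectors; normalized internally.
#' @return a [VectorSeries-class].
#' @export
vectorSeries <- function(residueId, times, vectors) {
  vectors <- as.matrix(vectors)
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0)) stop("zero-length bond vector encountered")
  new("VectorSeries",
    residueId = as.integer(residueId),
    times = as.numeric(times),
    vectors = vectors / norms
  )
}

#' Construct a RelaxationProfile
#'
#' @param residueIds integer residue numbers.
#' @param t1,t2 relaxation times in seconds (NA for missing).
#' @param hetnoe heteronuclear NOE values (NA for missing).
#' @param t1Err,t2Err,noeErr optional per-residue errors.
#' @param fieldMhz 1H spectrometer frequency in MHz.
#' @return a [RelaxationProfile-class].
#' @export
relaxationProfile <- function(residueIds, t1, t2, hetnoe,
                              t1Err = NULL, t2Err = NULL, noeErr = NULL,
                              fieldMhz = 600) {
  n <- length(residueIds)
  blank <- rep(NA_real_, n)
  new("RelaxationProfile",
    residueIds = as.integer(residueIds),
    t1 = as.numeric(t1), t2 = as.numeric(t2), hetnoe = as.numeric(hetnoe),
    t1Err = if (is.null(t1Err)) blank else as.numeric(t1Err),
    t2Err = if (is.null(t2Err)) blank else as.numeric(t2Err),
    noeErr = if (is.null(noeErr)) blank else as.numeric(noeErr),
    fieldMhz = as.numeric(fieldMhz)
  )
}

#' Construct a CorrelationFunction
#'
#' @param residueId integer residue number.
#' @param lags lag times in ps, starting at 0, equally spaced.
#' @param values correlation values.
#' @param nContributing number of trajectories averaged into the curve.
#' @return a [CorrelationFunction-class].
#' @export
correlationFunction <- function(residueId, lags, values, nContributing = 1L) {
  new("CorrelationFunction",
    residueId = as.integer(residueId),
    lags = as.numeric(lags),
    values = as.numeric(values),
    nContributing = as.integer(nContributing)
  )
}

#' Construct a SAXSProfile
#'
#' @param q scattering vector values, strictly increasing.
#' @param intensity intensities (arbitrary units).
#' @param sigma optional point-wise uncertainties.
#' @return a [SAXSProfile-class].
#' @export
saxsProfile <- function(q, intensity, sigma = NULL) {
  new("SAXSProfile",
    q = as.numeric(q),
    intensity = as.numeric(intensity),
    sigma = if (is.null(sigma)) numeric(0) else as.numeric(sigma)
  )
}

#' Default physical constants for backbone 15N relaxation
#'
#' Builds an [NMRParams-class] object. Defaults: chemical shift anisotropy
#' -160 ppm, effective N-H bond length 0.101 nm, one attached proton,
#' CODATA gyromagnetic ratios for 1H and 15N, and the standard
#' cross-relaxation sign convention for the heteronuclear NOE.
#'
#' @param fieldMhz 1H spectrometer frequency in MHz.
#' @param deltaSigma 15N chemical shift anisotropy in ppm.
#' @param rNH effective N-H bond length in nm (enters as 1/r^3).
#' @param gammaH,gammaN gyromagnetic ratios in rad s^-1 T^-1.
#' @param nH number of protons bonded to the nitrogen.
#' @param noeSignConvention `"standard_minus"` (default; cross-relaxation
#'   term 6J(wH+wN) - J(wH-wN), able to produce the negative NOE of
#'   flexible residues) or `"paper_plus"` (J(wH-wN) + 6J(wH+wN)).
#' @return an [NMRParams-class].
#' @examples
#' p <- nmrParams(600)
#' dipolarCoupling(p)
#' @export
nmrParams <- function(fieldMhz = 600,
                      deltaSigma = -160,
                      rNH = 0.101,
                      gammaH = 2.6752218744e8,
                      gammaN = -2.71261804e7,
                      nH = 1,
                      noeSignConvention = c("standard_minus", "paper_plus")) {
  noeSignConvention <- match.arg(noeSignConvention)
  new("NMRParams",
    fieldMhz = as.numeric(fieldMhz),
    deltaSigma = as.numeric(deltaSigma),
    rNH = as.numeric(rNH),
    gammaH = as.numeric(gammaH),
    gammaN = as.numeric(gammaN),
    nH = as.numeric(nH),
    mu0 = 4e-7 * pi,
    hbar = 1.054571817e-34,
    noeSignConvention = noeSignConvention
  )
}
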