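#' @importFrom methods new validObject is slot setClass setValidity setMethod
#'   setGeneric show
#' @importFrom stats fft sd var approx optimize quantile rnorm runif
#' @importFrom utils head tail read.table write.table
NULL

.equal_spacing_ok <- function(x, tol = 1e-6) {
  if (length(x) < 3L) return(TRUE)
  d <- diff(x)
  span <- max(abs(d))
  if (span == 0) return(FALSE)
  max(abs(d - d[1])) <= tol * span
}

#' In-memory molecular dynamics trajectory
#'
#' Holds Cartesian coordinates for every retained frame together with the
#' atom table from the topology. Coordinates are stored in nanometres in an
#' `n_atoms x 3 x n_frames` array; frame times are in picoseconds.
#'
#' @slot coords numeric array, `n_atoms x 3 x n_frames`, nm.
#' @slot times numeric, frame times in ps, equally spaced.
#' @slot atoms data.frame with columns `eleno`, `elety`, `resno`, `resid`,
#'   `chain`.
#' @slot sourcePaths character, the files the trajectory came from.
#'
#' @seealso [loadTrajectory()], [extractNHVectors()]
#' @export
setClass("TrajectoryHandle",
  representation(
    coords = "array",
    times = "numeric",
    atoms = "data.frame",
    sourcePaths = "character"
  )
)

setValidity("TrajectoryHandle", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[3] < 1L) return("trajectory must contain at least one frame")
  if (length(object@times) != d[3])
    return("length(times) must equal the number of frames")
  if (d[3] >= 2L) {
    if (any(diff(object@times) <= 0))
      return("frame times must be strictly increasing")
    if (!.equal_spacing_ok(object@times))
      return("frame times must be equally spaced")
  }
  if (nrow(object@atoms) != d[1])
    return("atom table must have one row per atom")
  TRUE
})

#' Time series of unit bond vectors for one residue
#'
#' The backbone amide N-H (or any other) unit vector of a single residue
#' sampled at equally spaced times. This is the raw input of the
#' second-order orientational autocorrelation analysis.
#'
#' @slot residueId integer residue number.
#' @slot times numeric, ps, equally spaced.
#' @slot vectors numeric matrix `n_frames x 3`; every row has unit norm
#'   (tolerance 1e-6).
#'
#' @seealso [computeP2Acf()], [simulateIsotropicRotor()]
#' @export
setClass("VectorSeries",
  representation(
    residueId = "integer",
    times = "numeric",
    vectors = "matrix"
  )
)

setValidity("VectorSeries", function(object) {
  v <- object@vectors
  if (ncol(v) != 3L) return("vectors must have 3 columns")
  if (nrow(v) != length(object@times))
    return("vectors and times must have matching length")
  norms <- sqrt(rowSums(v^2))
  if (any(abs(norms - 1) > 1e-6))
    return("all vectors must have unit norm (|v| = 1 within 1e-6)")
  if (length(object@times) >= 3L && !.equal_spacing_ok(object@times))
    return("times must be equally spaced")
  TRUE
})

#' Per-residue spin relaxation observables
#'
#' Backbone 15N T1 and T2 relaxation times (seconds) and heteronuclear
#' NOE values per residue, either predicted from a trajectory or measured
#' experimentally. Missing values are NA, never zero. Optional per-residue
#' experimental errors ride along.
#'
#' @slot residueIds integer residue numbers (unique).
#' @slot t1,t2 numeric, seconds, positive where finite.
#' @slot hetnoe numeric, dimensionless.
#' @slot t1Err,t2Err,noeErr numeric, same length (NA when unreported).
#' @slot fieldMhz 1H spectrometer frequency in MHz.
#'
#' @seealso [readRelaxationTable()], [predictProfile()], [rmsdObservable()]
#' @export
setClass("RelaxationProfile",
  representation(
    residueIds = "integer",
    t1 = "numeric",
    t2 = "numeric",
    hetnoe = "numeric",
    t1Err = "numeric",
    t2Err = "numeric",
    noeErr = "numeric",
    fieldMhz = "numeric"
  )
)

setValidity("RelaxationProfile", function(object) {
  n <- length(object@residueIds)
  lens <- c(
    length(object@t1), length(object@t2), length(object@hetnoe),
    length(object@t1Err), length(object@t2Err), length(object@noeErr)
  )
  if (any(lens != n)) return("all observable arrays must match residueIds")
  if (anyDuplicated(object@residueIds)) return("duplicate residue IDs")
  if (any(object@t1 <= 0, na.rm = TRUE)) return("t1 must be positive")
  if (any(object@t2 <= 0, na.rm = TRUE)) return("t2 must be positive")
  if (length(object@fieldMhz) != 1L || object@fieldMhz <= 0)
    return("fieldMhz must be a single positive number")
  TRUE
})

#' Rotational correlation function of one residue
#'
#' The second-order (P2) orientational autocorrelation g(t) of a bond
#' vector, starting at lag zero, on an equally spaced lag grid in ps.
#' `nContributing` records how many trajectories were averaged into it.
#'
#' @slot residueId integer.
#' @slot lags numeric, ps, `lags[1] == 0`, strictly increasing, equal
#'   spacing.
#' @slot values numeric, dimensionless; `values[1]` in (0, 1].
#' @slot nContributing integer.
#'
#' @seealso [computeP2Acf()], [averageAcfs()], [fitExponentialSum()]
#' @export
setClass("CorrelationFunction",
  representation(
    residueId = "integer",
    lags = "numeric",
    values = "numeric",
    nContributing = "integer"
  )
)

setValidity("CorrelationFunction", function(object) {
  if (length(object@lags) != length(object@values))
    return("lags and values must have matching length")
  if (length(object@lags) < 1L) return("empty correlation function")
  if (object@lags[1] != 0) return("lags must start at 0")
  if (!(object@values[1] > 0 && object@values[1] <= 1 + 1e-9))
    return("value at lag 0 must lie in (0, 1]")
  if (length(object@lags) >= 2L && any(diff(object@lags) <= 0))
    return("lags must be strictly increasing")
  if (!.equal_spacing_ok(object@lags))
    return("lags must be equally spaced")
  if (object@nContributing < 1L)
    return("nContributing must be >= 1")
  TRUE
})

#' Logarithmic grid of candidate correlation times
#'
#' Fixed decay timescales for the multi-exponential fit, strictly
#' increasing and equidistant in log space. Stored in seconds.
#'
#' @slot taus numeric, seconds.
#'
#' @seealso [buildTimescaleGrid()], [fitExponentialSum()]
#' @export
setClass("TimescaleGrid", representation(taus = "numeric"))

setValidity("TimescaleGrid", function(object) {
  taus <- object@taus
  if (length(taus) < 2L) return("grid needs at least 2 timescales")
  if (any(taus <= 0)) return("timescales must be positive")
  if (any(diff(taus) <= 0)) return("timescales must be strictly increasing")
  lr <- diff(log(taus))
  if (max(abs(lr - lr[1])) > 1e-12 * max(abs(lr)) + 1e-12)
    return("timescales must be equidistant in log space")
  TRUE
})

#' Non-negative weights on a timescale grid
#'
#' The result of fitting a correlation function to a sum of exponential
#' decays with fixed timescales: one non-negative weight per grid point
#' plus the residual 2-norm of the fit.
#'
#' @slot grid a [TimescaleGrid-class].
#' @slot alphas numeric, non-negative, one per grid timescale.
#' @slot fitResidual numeric scalar, `||C_fit - g||_2`.
#'
#' @seealso [fitExponentialSum()], [spectralDensity()], [effectiveTau()]
#' @export
setClass("TimescaleSpectrum",
  representation(
    grid = "TimescaleGrid",
    alphas = "numeric",
    fitResidual = "numeric"
  )
)

setValidity("TimescaleSpectrum", function(object) {
  if (length(object@alphas) != length(object@grid@taus))
    return("one weight per grid timescale required")
  if (any(object@alphas < 0)) return("weights must be non-negative")
  if (length(object@fitResidual) != 1L || object@fitResidual < 0)
    return("fitResidual must be a single non-negative number")
  TRUE
})

#' Physical constants and conventions for Redfield relaxation
#'
#' Everything the Redfield rate expressions need: spectrometer field,
#' 15N chemical shift anisotropy, effective N-H bond length, gyromagnetic
#' ratios, and the sign convention used in the heteronuclear NOE
#' cross-relaxation term.
#'
#' @slot fieldMhz 1H Larmor frequency in MHz.
#' @slot deltaSigma chemical shift anisotropy in ppm (default -160).
#' @slot rNH effective N-H bond length in nm (default 0.101).
#' @slot gammaH,gammaN gyromagnetic ratios in rad s^-1 T^-1 (gammaN < 0).
#' @slot nH number of protons attached to the 15N (default 1).
#' @slot mu0 vacuum permeability, T m A^-1.
#' @slot hbar reduced Planck constant, J s.
#' @slot noeSignConvention `"standard_minus"` (default) uses the
#'   cross-relaxation combination 6J(wH+wN) - J(wH-wN); `"paper_plus"`
#'   uses J(wH-wN) + 6J(wH+wN).
#'
#' @seealso [nmrParams()], [relaxationObservables()], [dipolarCoupling()]
#' @export
setClass("NMRParams",
  representation(
    fieldMhz = "numeric",
    deltaSigma = "numeric",
    rNH = "numeric",
    gammaH = "numeric",
    gammaN = "numeric",
    nH = "numeric",
    mu0 = "numeric",
    hbar = "numeric",
    noeSignConvention = "character"
  )
)

setValidity("NMRParams", function(object) {
  if (object@fieldMhz <= 0) return("fieldMhz must be positive")
  if (!(object@gammaN < 0 && object@gammaH > 0))
    return("expected gammaN < 0 < gammaH")
  if (object@rNH <= 0) return("rNH must be positive")
  if (object@nH < 1) return("nH must be >= 1")
  if (!object@noeSignConvention %in% c("standard_minus", "paper_plus"))
    return("noeSignConvention must be 'standard_minus' or 'paper_plus'")
  TRUE
})

#' Small-angle X-ray scattering profile
#'
#' A scattering curve I(q) with optional point-wise uncertainties. q units
#' are whatever the input files use (crysol convention: inverse Angstrom).
#'
#' @slot q numeric, strictly increasing, non-negative.
#' @slot intensity numeric, finite, arbitrary units.
#' @slot sigma numeric, same length as q, or length 0 when absent.
#'
#' @seealso [readSAXSProfile()], [fitScaleOffset()], [normalizeProfile()]
#' @export
setClass("SAXSProfile",
  representation(q = "numeric", intensity = "numeric", sigma = "numeric")
)

setValidity("SAXSProfile", function(object) {
  if (length(object@q) != length(object@intensity))
    return("q and intensity must have matching length")
  if (length(object@sigma) && length(object@sigma) != length(object@q))
    return("sigma must be empty or match q")
  if (any(object@q < 0)) return("q must be non-negative")
  if (length(object@q) >= 2L && any(diff(object@q) <= 0))
    return("q must be strictly increasing")
  if (any(!is.finite(object@intensity)))
    return("intensities must be finite")
  TRUE
})

#' Result of fitting a computed SAXS profile to experiment
#'
#' Linear scale/offset fit of a computed curve to experimental data inside
#' a q window, plus min-max normalized versions of both curves and the
#' RMSE quality score (raw-fitted by default, normalized also reported).
#'
#' @slot scale,offset fitted linear parameters.
#' @slot fitted [SAXSProfile-class], `scale * I_comp + offset` on the
#'   common window grid.
#' @slot normalizedExp,normalizedFit min-max normalized profiles.
#' @slot rmse RMSE between experimental and fitted intensities.
#' @slot rmseNormalized RMSE between the normalized profiles.
#'
#' @seealso [fitScaleOffset()]
#' @export
setClass("SAXSFitResult",
  representation(
    scale = "numeric",
    offset = "numeric",
    fitted = "SAXSProfile",
    normalizedExp = "SAXSProfile",
    normalizedFit = "SAXSProfile",
    rmse = "numeric",
    rmseNormalized = "numeric"
  )
)

setValidity("SAXSFitResult", function(object) {
  if (object@rmse < 0) return("rmse must be non-negative")
  TRUE
})

#' Ranking of candidate simulations against experiment
#'
#' Per-simulation, per-observable RMSD ratios ("comparison numbers":
#' each simulation's RMSD divided by the smallest RMSD for that
#' observable), the selection threshold, the simulations passing the
#' threshold for all three observables simultaneously, and the best
#' simulation per observable.
#'
#' @slot rmsd data.frame: `sim`, `rmsd_t1`, `rmsd_t2`, `rmsd_noe`,
#'   `n_t1`, `n_t2`, `n_noe`.
#' @slot ratios data.frame: `sim`, `ratio_t1`, `ratio_t2`, `ratio_noe`.
#' @slot threshold numeric, comparison-number cutoff (default 1.5).
#' @slot selectedIds character, simulations with all ratios < threshold.
#' @slot bestPerObservable named character, best simulation for each
#'   observable.
#'
#' @seealso [comparisonNumbers()], [selectSimulations()],
#'   [combineEnsemble()]
#' @export
setClass("SelectionResult",
  representation(
    rmsd = "data.frame",
    ratios = "data.frame",
    threshold = "numeric",
    selectedIds = "character",
    bestPerObservable = "character"
  )
)

setValidity("SelectionResult", function(object) {
  rc <- c("ratio_t1", "ratio_t2", "ratio_noe")
  if (!all(c("sim", rc) %in% names(object@ratios)))
    return("ratios must have columns sim, ratio_t1, ratio_t2, ratio_noe")
  rat <- as.matrix(object@ratios[rc])
  if (any(rat < 1 - 1e-9, na.rm = TRUE))
    return("comparison numbers must be >= 1")
  if (!all(object@selectedIds %in% object@ratios$sim))
    return("selectedIds must be known simulations")
  TRUE
})

setMethod("show", "TrajectoryHandle", function(object) {
  d <- dim(object@coords)
  cat(sprintf(
    "TrajectoryHandle: %d atoms, %d frames, dt = %g ps\n",
    d[1], d[3], if (d[3] >= 2) diff(object@times[1:2]) else NA_real_
  ))
  cat(sprintf(
    "  residues: %d   time range: %g..%g ps\n",
    length(unique(paste(object@atoms$chain, object@atoms$resno))),
    min(object@times), max(object@times)
  ))
})

setMethod("show", "VectorSeries", function(object) {
  cat(sprintf(
    "VectorSeries: residue %d, %d frames, dt = %g ps\n",
    object@residueId, nrow(object@vectors),
    if (length(object@times) >= 2) diff(object@times[1:2]) else NA_real_
  ))
})

setMethod("show", "RelaxationProfile", function(object) {
  cat(sprintf(
    "RelaxationProfile: %d residues at %g MHz\n",
    length(object@residueIds), object@fieldMhz
  ))
  cat(sprintf(
    "  finite values: T1 %d, T2 %d, hetNOE %d\n",
    sum(is.finite(object@t1)), sum(is.finite(object@t2)),
    sum(is.finite(object@hetnoe))
  ))
})

setMethod("show", "CorrelationFunction", function(object) {
  cat(sprintf(
    "CorrelationFunction: residue %d, %d lags (0..%g ps), %d trajectories\n",
    object@residueId, length(object@lags), max(object@lags),
    object@nContributing
  ))
})

setMethod("show", "TimescaleGrid", function(object) {
  cat(sprintf(
    "TimescaleGrid: %d points, %g ps .. %g ns (log-equidistant)\n",
    length(object@taus), object@taus[1] * 1e12,
    object@taus[length(object@taus)] * 1e9
  ))
})

setMethod("show", "TimescaleSpectrum", function(object) {
  nz <- sum(object@alphas > 0)
  cat(sprintf(
    "TimescaleSpectrum: %d/%d active weights, sum(alpha) = %.4f, residual %.3g\n",
    nz, length(object@alphas), sum(object@alphas), object@fitResidual
  ))
})

setMethod("show", "NMRParams", function(object) {
  cat(sprintf(
    "NMRParams: %g MHz, dSigma = %g ppm, rNH = %g nm, NOE sign '%s'\n",
    object@fieldMhz, object@deltaSigma, object@rNH,
    object@noeSignConvention
  ))
})

setMethod("show", "SAXSProfile", function(object) {
  cat(sprintf(
    "SAXSProfile: %d points, q = %.4g..%.4g%s\n",
    length(object@q), min(object@q), max(object@q),
    if (length(object@sigma)) ", with uncertainties" else ""
  ))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf(
    "SelectionResult: %d simulations, threshold %g, %d selected\n",
    nrow(object@ratios), object@threshold, length(object@selectedIds)
  ))
  if (length(object@selectedIds))
    cat("  selected:", paste(object@selectedIds, collapse = ", "), "\n")
})
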