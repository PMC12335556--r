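## SAXS channel: read computed/experimental profiles, ensemble-average,
## fit scale and offset inside a q window, normalize, score by RMSE.

#' Read a SAXS profile
#'
#' Understands crysol-style `.int`/`.fit` files (a title line followed by
#' numeric columns; the first two are q and total intensity) and generic
#' 2-3 column text (`q I [sigma]`, `#`-comments allowed).
#'
#' @param path input file.
#' @return a [SAXSProfile-class].
#' @export
readSAXSProfile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*#", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  numeric_row <- vapply(parts, function(p) {
    length(p) >= 2 && !anyNA(suppressWarnings(as.numeric(p[1:2])))
  }, logical(1))
  parts <- parts[numeric_row]
  if (!length(parts)) stop("no numeric data rows in ", path)
  q <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  i <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  sg <- vapply(parts, function(p) {
    if (length(p) >= 3) suppressWarnings(as.numeric(p[3])) else NA_real_
  }, numeric(1))
  has_sigma <- all(is.finite(sg)) &&
    max(vapply(parts, length, integer(1))) == 3L
  saxsProfile(q, i, if (has_sigma) sg else NULL)
}

#' Write a SAXS profile as generic text
#'
#' @param profile a [SAXSProfile-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSAXSProfile <- function(profile, path) {
  stopifnot(is(profile, "SAXSProfile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# q I [sigma]", con)
  if (length(profile@sigma)) {
    writeLines(sprintf("%.17g %.17g %.17g", profile@q, profile@intensity,
                       profile@sigma), con)
  } else {
    writeLines(sprintf("%.17g %.17g", profile@q, profile@intensity), con)
  }
  invisible(path)
}

#' Average per-frame SAXS profiles
#'
#' Pointwise mean of intensities over frames; all profiles must share an
#' identical q grid (no interpolation is attempted).
#'
#' @param profiles list of [SAXSProfile-class].
#' @return a [SAXSProfile-class].
#' @export
averageProfiles <- function(profiles) {
  if (!length(profiles)) stop("no profiles to average")
  q0 <- profiles[[1]]@q
  for (p in profiles) {
    if (length(p@q) != length(q0) || any(p@q != q0))
      stop("mismatched q grids; profiles must share an identical grid")
  }
  im <- rowMeans(vapply(profiles, function(p) p@intensity,
                        numeric(length(q0))))
  saxsProfile(q0, im)
}

#' Min-max normalize a SAXS profile
#'
#' `I_norm = (I - I_min) / (I_max - I_min)`; the minimum maps to 0 and
#' the maximum to 1.
#'
#' @param profile a [SAXSProfile-class]; constant profiles are an error.
#' @return a [SAXSProfile-class] with intensities in `[0, 1]`.
#' @export
normalizeProfile <- function(profile) {
  stopifnot(is(profile, "SAXSProfile"))
  i <- profile@intensity
  rng <- range(i)
  if (rng[2] <= rng[1])
    stop("constant profile: zero intensity range, cannot normalize")
  saxsProfile(profile@q, (i - rng[1]) / (rng[2] - rng[1]))
}

#' RMSE between two profiles on a common q grid
#'
#' `RMSE = sqrt(mean((I_exp - I_fit)^2))`.
#'
#' @param exp,fit [SAXSProfile-class] objects of equal length.
#' @return non-negative scalar.
#' @export
profileRmse <- function(exp, fit) {
  if (length(exp@intensity) != length(fit@intensity))
    stop("profiles differ in length")
  sqrt(mean((exp@intensity - fit@intensity)^2))
}

#' Fit a computed SAXS profile to experiment by scale and offset
#'
#' Minimizes `sum (I_exp - scale * I_comp - offset)^2` over the q window
#' `[qmin, qmax]` (points outside the window never influence the fit).
#' The model is linear in both parameters, so the Levenberg-Marquardt
#' iteration this fit emulates converges to the closed-form linear
#' least-squares solution, which is what is computed. The computed
#' profile is linearly interpolated onto the experimental q grid when the
#' grids differ.
#'
#' @param computed ensemble-averaged computed [SAXSProfile-class].
#' @param experimental experimental [SAXSProfile-class].
#' @param qmin,qmax fit window in the q units of the inputs (defaults
#'   0.01 and 0.3).
#' @return a [SAXSFitResult-class]; `rmse` is computed on the raw fitted
#'   intensities, `rmseNormalized` on the min-max normalized curves.
#' @export
fitScaleOffset <- function(computed, experimental, qmin = 0.01, qmax = 0.3) {
  stopifnot(is(computed, "SAXSProfile"), is(experimental, "SAXSProfile"))
  qe <- experimental@q
  win <- qe >= qmin & qe <= qmax
  if (sum(win) < 2L)
    stop("fewer than 2 experimental q points inside [", qmin, ", ",
         qmax, "]")
  qw <- qe[win]
  ie <- experimental@intensity[win]
  if (min(qw) < min(computed@q) || max(qw) > max(computed@q))
    stop("computed profile does not cover the fit window")
  ic <- stats::approx(computed@q, computed@intensity, xout = qw)$y

  X <- cbind(ic, 1)
  beta <- qr.solve(X, ie)
  scale <- beta[1]
  offset <- beta[2]
  ifit <- scale * ic + offset

  fitted <- saxsProfile(qw, ifit)
  exp_win <- saxsProfile(qw, ie,
                         if (length(experimental@sigma))
                           experimental@sigma[win] else NULL)
  nexp <- normalizeProfile(exp_win)
  nfit <- normalizeProfile(fitted)
  new("SAXSFitResult",
    scale = unname(scale), offset = unname(offset),
    fitted = fitted,
    normalizedExp = nexp, normalizedFit = nfit,
    rmse = profileRmse(exp_win, fitted),
    rmseNormalized = profileRmse(nexp, nfit)
  )
}

#' Coarse Debye-formula scattering profile over C-alpha pseudo-atoms
#'
#' `I(q) = sum_ij sin(q r_ij) / (q r_ij)` with unit form factors over one
#' pseudo-atom per residue. This is a qualitative, self-contained
#' calculator for exercising the fitting machinery on synthetic
#' structures; it is not quantitative (no real form factors, no
#' excluded-volume or hydration-shell terms) and is no substitute for a
#' dedicated scattering calculator.
#'
#' @param ca `n x 3` matrix of coordinates in nm.
#' @param q scattering vector values in inverse Angstrom.
#' @return a [SAXSProfile-class].
#' @export
debyeProfile <- function(ca, q) {
  ca <- as.matrix(ca)
  stopifnot(ncol(ca) == 3L)
  r <- as.matrix(stats::dist(ca * 10))  # nm -> Angstrom
  i <- vapply(q, function(qq) {
    if (qq == 0) return(nrow(ca)^2)
    x <- qq * r
    s <- sin(x) / x
    diag(s) <- 1
    sum(s)
  }, numeric(1))
  saxsProfile(q, i)
}
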