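## Conformational ensemble characterization: radius of gyration,
## backbone orientational correlation maps, average minimum-distance
## maps, and principal component analysis of C-alpha fluctuations.

.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974
)

.guess_masses <- function(elety) {
  el <- substr(gsub("[^A-Za-z].*", "", elety), 1, 1)
  m <- .atomic_masses[el]
  m[is.na(m)] <- 1
  unname(m)
}

.coord_array <- function(x) {
  if (is(x, "TrajectoryHandle")) return(x@coords)
  x <- as.array(x)
  stopifnot(length(dim(x)) == 3L, dim(x)[2] == 3L)
  x
}

#' Mass-weighted radius of gyration per frame
#'
#' `Rg = sqrt(sum_i m_i ||r_i - r_com||^2 / sum_i m_i)` for every frame.
#'
#' @param frames a [TrajectoryHandle-class] or an
#'   `n_atoms x 3 x n_frames` coordinate array in nm.
#' @param masses atomic masses; when NULL and a trajectory is given,
#'   guessed from atom names, otherwise unit masses.
#' @return numeric vector of Rg values in nm, one per frame.
#' @export
radiusOfGyration <- function(frames, masses = NULL) {
  if (is.null(masses)) {
    masses <- if (is(frames, "TrajectoryHandle"))
      .guess_masses(frames@atoms$elety)
    else rep(1, dim(.coord_array(frames))[1])
  }
  xyz <- .coord_array(frames)
  if (any(masses <= 0)) stop("masses must be positive")
  mtot <- sum(masses)
  if (mtot <= 0) stop("zero total mass")
  apply(xyz, 3, function(fr) {
    com <- colSums(fr * masses) / mtot
    sqrt(sum(masses * rowSums(sweep(fr, 2, com)^2)) / mtot)
  })
}

#' Histogram of a radius-of-gyration distribution
#'
#' Density-normalized histogram with Freedman-Diaconis bin width by
#' default.
#'
#' @param rg numeric vector of Rg values (nm).
#' @param binWidth optional bin width in nm.
#' @return list with `mids`, `density`, `breaks`, `mean`.
#' @export
rgHistogram <- function(rg, binWidth = NULL) {
  if (is.null(binWidth)) {
    iqr <- stats::IQR(rg)
    binWidth <- if (iqr > 0) 2 * iqr / length(rg)^(1 / 3) else
      max(diff(range(rg)), 1e-3) / 10
  }
  breaks <- seq(min(rg) - binWidth / 2, max(rg) + binWidth,
                by = binWidth)
  h <- graphics::hist(rg, breaks = breaks, plot = FALSE)
  list(mids = h$mids, density = h$density, breaks = h$breaks,
       mean = mean(rg))
}

#' Backbone orientational correlation map
#'
#' For consecutive C-alpha positions, forms the normalized connecting
#' vectors `v_i = unit(CA_{i+1} - CA_i)` in every frame and returns the
#' time-averaged dot products `<v_i . v_j>`. Positive or negative entries
#' indicate correlated or anti-correlated segment orientations; fully
#' random relative orientations average to zero. The diagonal is exactly
#' 1.
#'
#' @param ca a [TrajectoryHandle-class] (its `CA` atoms are used) or an
#'   `n_ca x 3 x n_frames` array of C-alpha coordinates.
#' @return `(n_ca - 1) x (n_ca - 1)` symmetric matrix; index i labels the
#'   vector starting at the i-th residue.
#' @export
orientationCorrelationMap <- function(ca) {
  if (is(ca, "TrajectoryHandle")) {
    idx <- which(ca@atoms$elety == "CA")
    if (length(idx) < 3L) stop("need at least 3 C-alpha atoms")
    xyz <- ca@coords[idx, , , drop = FALSE]
  } else {
    xyz <- .coord_array(ca)
    if (dim(xyz)[1] < 3L) stop("need at least 3 C-alpha positions")
  }
  n <- dim(xyz)[1]
  nf <- dim(xyz)[3]
  nv <- n - 1L
  acc <- matrix(0, nv, nv)
  for (f in seq_len(nf)) {
    fr <- matrix(xyz[, , f], nrow = n, ncol = 3)
    d <- fr[-1, , drop = FALSE] - fr[-n, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    if (any(len == 0))
      stop("coincident consecutive C-alpha positions in frame ", f)
    v <- d / len
    acc <- acc + tcrossprod(v)
  }
  m <- acc / nf
  diag(m) <- 1
  m
}

#' Average minimum inter-residue distance map
#'
#' At frames sampled every `interval` ps, computes for each residue pair
#' the minimum distance over all atom pairs (all atoms of each residue),
#' then averages over the sampled frames.
#'
#' @param traj a [TrajectoryHandle-class].
#' @param interval sampling interval in ps (default 1000 = 1 ns); must be
#'   at least the frame spacing.
#' @return symmetric residue x residue matrix in nm with zero diagonal.
#' @export
minDistanceMap <- function(traj, interval = 1000) {
  stopifnot(is(traj, "TrajectoryHandle"))
  dt <- frameSpacing(traj)
  if (is.finite(dt) && interval < dt)
    stop("interval (", interval, " ps) shorter than frame spacing (",
         dt, " ps)")
  step <- if (is.finite(dt)) max(1L, round(interval / dt)) else 1L
  frames <- seq(1L, frameCount(traj), by = step)

  resno <- traj@atoms$resno
  resn <- sort(unique(resno))
  nres <- length(resn)
  idx <- lapply(resn, function(r) which(resno == r))

  acc <- matrix(0, nres, nres)
  for (f in frames) {
    fr <- traj@coords[, , f]
    if (is.null(dim(fr))) fr <- matrix(fr, ncol = 3)
    dm <- as.matrix(stats::dist(fr))
    for (i in seq_len(nres - 1L)) {
      for (j in seq((i + 1L), nres)) {
        md <- min(dm[idx[[i]], idx[[j]]])
        acc[i, j] <- acc[i, j] + md
        acc[j, i] <- acc[j, i] + md
      }
    }
  }
  m <- acc / length(frames)
  dimnames(m) <- list(resn, resn)
  m
}

.kabsch <- function(P, Q) {
  # rotation matrix aligning centered P onto centered Q
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

.superpose_to <- function(xyz, ref) {
  # xyz: n x 3 x f; ref: n x 3. Least-squares fit of every frame onto ref.
  refc <- sweep(ref, 2, colMeans(ref))
  out <- xyz
  for (f in seq_len(dim(xyz)[3])) {
    fr <- xyz[, , f]
    frc <- sweep(fr, 2, colMeans(fr))
    R <- .kabsch(frc, refc)
    out[, , f] <- sweep(frc %*% t(R), 2, colMeans(ref), `+`)
  }
  out
}

#' Principal component analysis of C-alpha fluctuations
#'
#' Concatenates the C-alpha coordinates of all input trajectories,
#' least-squares superposes every frame on the mean structure (computed
#' after an initial superposition on the first frame, then refit once),
#' forms the covariance matrix of the 3N coordinates, and projects each
#' trajectory onto the first two eigenvectors.
#'
#' @param trajectories named list of [TrajectoryHandle-class] or of
#'   `n_ca x 3 x n_frames` C-alpha coordinate arrays with a consistent
#'   atom count.
#' @return list with `eigenvalues` (non-increasing, nm^2),
#'   `eigenvectors` (3N x 3N, columns), `projections` (named list of
#'   `n_frames x 2` matrices), and `mean` (the reference structure).
#' @export
pcaEnsemble <- function(trajectories) {
  if (!length(trajectories)) stop("no trajectories supplied")
  arrs <- lapply(trajectories, function(tr) {
    if (is(tr, "TrajectoryHandle")) {
      idx <- which(tr@atoms$elety == "CA")
      if (!length(idx)) idx <- seq_len(nrow(tr@atoms))
      tr@coords[idx, , , drop = FALSE]
    } else .coord_array(tr)
  })
  ns <- vapply(arrs, function(a) dim(a)[1], integer(1))
  if (length(unique(ns)) != 1L)
    stop("inconsistent C-alpha counts across trajectories: ",
         paste(ns, collapse = ", "))
  n <- ns[1]
  lens <- vapply(arrs, function(a) dim(a)[3], integer(1))
  all_xyz <- array(0, dim = c(n, 3, sum(lens)))
  off <- 0L
  for (a in arrs) {
    all_xyz[, , off + seq_len(dim(a)[3])] <- a
    off <- off + dim(a)[3]
  }
  if (dim(all_xyz)[3] < 2L) stop("need at least 2 frames in total")

  fitted <- .superpose_to(all_xyz, all_xyz[, , 1])
  mref <- apply(fitted, c(1, 2), mean)
  fitted <- .superpose_to(all_xyz, mref)
  mref <- apply(fitted, c(1, 2), mean)

  nf <- dim(fitted)[3]
  X <- t(matrix(fitted, nrow = 3L * n, ncol = nf))  # frames x 3N
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / nf
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)

  proj_all <- Xc %*% eig$vectors[, 1:2, drop = FALSE]
  ids <- names(trajectories)
  if (is.null(ids)) ids <- as.character(seq_along(trajectories))
  projections <- list()
  off <- 0L
  for (k in seq_along(lens)) {
    projections[[ids[k]]] <- proj_all[off + seq_len(lens[k]), , drop = FALSE]
    off <- off + lens[k]
  }
  list(
    eigenvalues = ev, eigenvectors = eig$vectors,
    projections = projections, mean = mref
  )
}

#' Equally spaced frame subsample
#'
#' Picks `k` equally spaced frame indices from a trajectory, e.g. for
#' snapshot overlays rendered by external tools.
#'
#' @param traj a [TrajectoryHandle-class].
#' @param k number of frames to keep.
#' @return integer frame indices of length `k`.
#' @export
subsampleFrames <- function(traj, k) {
  n <- frameCount(traj)
  if (k < 1L || k > n) stop("k must be between 1 and the frame count")
  unique(round(seq(1, n, length.out = k)))
}
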