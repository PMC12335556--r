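## Seeded synthetic generators: multi-exponential correlation functions,
## isotropic rotational diffusion, planted-truth selection fixtures, and
## two-domain bead ensembles. Each generator draws from its own
## seed-derived stream so adding one never perturbs the others.

.gen_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + offset
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthesize a multi-exponential correlation function
#'
#' `g(t) = sum_i w_i exp(-t / tau_i)` on a lag grid, with optional
#' additive Gaussian noise (the lag-zero value is kept exact so the
#' curve remains a valid correlation function).
#'
#' @param weights non-negative weights, summing to about 1.
#' @param tausS decay times in seconds, positive.
#' @param timeGridPs lag times in ps, starting at 0, equally spaced.
#' @param noiseSigma standard deviation of additive noise (default 0).
#' @param seed integer seed.
#' @param residueId residue label for the result.
#' @return a [CorrelationFunction-class].
#' @examples
#' acf <- makeAcf(c(0.3, 0.7), c(1e-9, 1e-8), seq(0, 5e4, by = 250))
#' @export
makeAcf <- function(weights, tausS, timeGridPs, noiseSigma = 0, seed = 1,
                    residueId = 1L) {
  if (noiseSigma < 0) stop("noiseSigma must be non-negative")
  if (any(tausS <= 0)) stop("decay times must be positive")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 0.2)
    warning("weights sum to ", signif(sum(weights), 4),
            "; expected approximately 1")
  t_s <- timeGridPs * 1e-12
  g <- as.numeric(exp(-outer(t_s, 1 / tausS)) %*% weights)
  if (noiseSigma > 0) {
    noise <- .with_seed(.gen_seed(seed, 101L),
                        rnorm(length(g), sd = noiseSigma))
    noise[1] <- 0
    g <- g + noise
  }
  correlationFunction(residueId, timeGridPs, g, 1L)
}

#' Simulate isotropic rotational diffusion of a unit vector
#'
#' Evolves a unit vector by small random rotations: each step rotates by
#' an angle `sqrt(4 D_r dt) |N(0,1)|` about an axis drawn uniformly in
#' the plane perpendicular to the current vector, so the full step angle
#' displaces the vector (an axis with a component along the vector would
#' waste part of the rotation and realize a smaller diffusion
#' coefficient). In the small-step limit this is isotropic rotational
#' diffusion with coefficient `D_r`, whose second-order orientational
#' autocorrelation decays exponentially with `tau_2 = 1 / (6 D_r)`. A
#' warning is issued (and the simulation proceeds) when the mean squared
#' step angle `4 D_r dt` exceeds 0.1, outside the discretization's
#' validity.
#'
#' @param Dr rotational diffusion coefficient in 1/s.
#' @param dtPs time step in ps.
#' @param nSteps number of frames to generate.
#' @param seed integer seed.
#' @param residueId residue label.
#' @return a [VectorSeries-class] of `nSteps` frames.
#' @examples
#' vs <- simulateIsotropicRotor(Dr = 1 / (6 * 5e-9), dtPs = 10,
#'                              nSteps = 2000, seed = 7)
#' @export
simulateIsotropicRotor <- function(Dr, dtPs, nSteps, seed = 1,
                                   residueId = 1L) {
  if (Dr <= 0 || dtPs <= 0) stop("Dr and dtPs must be positive")
  msa <- 4 * Dr * dtPs * 1e-12
  if (msa > 0.1)
    warning("mean squared step angle 4*Dr*dt = ", signif(msa, 3),
            " is not << 1; diffusion discretization inaccurate")
  v <- matrix(0, nSteps, 3)
  v[1, ] <- c(0, 0, 1)
  .with_seed(.gen_seed(seed, 211L), {
    raw <- matrix(rnorm(3 * (nSteps - 1)), ncol = 3)
    ang <- sqrt(msa) * abs(rnorm(nSteps - 1))
    cur <- v[1, ]
    for (k in seq_len(nSteps - 1)) {
      # project the random direction into the tangent plane of cur
      a <- raw[k, ] - sum(raw[k, ] * cur) * cur
      a <- a / sqrt(sum(a * a))
      ca <- cos(ang[k])
      sa <- sin(ang[k])
      # Rodrigues rotation of cur about axis a
      cur <- cur * ca + c(
        a[2] * cur[3] - a[3] * cur[2],
        a[3] * cur[1] - a[1] * cur[3],
        a[1] * cur[2] - a[2] * cur[1]
      ) * sa + a * sum(a * cur) * (1 - ca)
      cur <- cur / sqrt(sum(cur^2))
      v[k + 1, ] <- cur
    }
  })
  vectorSeries(residueId, (seq_len(nSteps) - 1) * dtPs, v)
}

#' Planted-truth selection fixture
#'
#' Builds `nSims` candidate simulations, each a set of per-residue
#' two-component correlation functions with a distinct timescale mixture,
#' and generates the "experimental" relaxation table from the truth
#' simulation's correlation functions through the forward model (fit on
#' the grid, Redfield observables), optionally perturbed by relative
#' Gaussian noise. With zero noise the truth simulation reproduces the
#' experimental table exactly, so all its comparison numbers are 1.
#'
#' @param nSims number of candidate simulations.
#' @param truthIndex 1-based index of the simulation the experimental
#'   data derive from.
#' @param noiseSigma relative noise on the experimental observables
#'   (e.g. 0.02 for 2 percent).
#' @param seed integer seed.
#' @param nResidues residues per simulation.
#' @param params an [NMRParams-class] (default 600 MHz).
#' @param grid a [TimescaleGrid-class].
#' @param lagMaxPs,lagStepPs lag grid of the generated correlation
#'   functions.
#' @return list with `acfs` (per-sim, per-residue correlation function
#'   store), `exp` (the [RelaxationProfile-class]), `truth` (the truth
#'   simulation's ID), `params`, `grid`.
#' @export
makeSelectionFixture <- function(nSims = 5L, truthIndex = 3L,
                                 noiseSigma = 0, seed = 1,
                                 nResidues = 6L,
                                 params = nmrParams(600),
                                 grid = buildTimescaleGrid(),
                                 lagMaxPs = 5e4, lagStepPs = 250) {
  if (truthIndex < 1L || truthIndex > nSims)
    stop("truthIndex must be in 1..nSims")
  tg <- grid@taus
  n <- length(tg)
  lags <- seq(0, lagMaxPs, by = lagStepPs)
  sim_ids <- paste0("sim", seq_len(nSims))

  # distinct mixtures: one slow component (ns range) and one fast
  # component (tens of ps), both on the grid, shifting with sim index
  acfs <- list()
  for (s in seq_len(nSims)) {
    slow_i <- min(n - 2L, round(0.68 * n) + 2L * s)
    per_res <- list()
    for (r in seq_len(nResidues)) {
      fast_i <- max(2L, round(0.35 * n) + r)
      w_slow <- 0.55 + 0.05 * s + 0.01 * r
      per_res[[as.character(r)]] <- makeAcf(
        weights = c(w_slow, 1 - w_slow),
        tausS = c(tg[slow_i], tg[fast_i]),
        timeGridPs = lags,
        residueId = r
      )
    }
    acfs[[sim_ids[s]]] <- per_res
  }

  truth_pred <- predictProfile(acfs[[truthIndex]], params, grid)$profile
  t1 <- truth_pred@t1
  t2 <- truth_pred@t2
  noe <- truth_pred@hetnoe
  if (noiseSigma > 0) {
    eps <- .with_seed(.gen_seed(seed, 307L),
                      matrix(rnorm(3 * nResidues, sd = noiseSigma),
                             ncol = 3))
    t1 <- t1 * (1 + eps[, 1])
    t2 <- t2 * (1 + eps[, 2])
    noe <- noe + eps[, 3] * abs(noe)
  }
  exp_profile <- relaxationProfile(
    residueIds = truth_pred@residueIds,
    t1 = t1, t2 = t2, hetnoe = noe,
    fieldMhz = params@fieldMhz
  )
  list(
    acfs = acfs, exp = exp_profile, truth = sim_ids[truthIndex],
    params = params, grid = grid
  )
}

#' Analytic mean squared radius of gyration of an ideal chain
#'
#' For a freely jointed chain of `nBeads` beads with bond length `bond`,
#' `<Rg^2> = bond^2 (n^2 - 1) / (6 n)`.
#'
#' @param nBeads number of beads.
#' @param bond bond length in nm.
#' @return `<Rg^2>` in nm^2.
#' @export
idealChainRg2 <- function(nBeads, bond = 0.38) {
  bond^2 * (nBeads^2 - 1) / (6 * nBeads)
}

#' Two-domain bead ensemble with a flexible linker
#'
#' Generates frames of a toy protein made of rigid rod-shaped "domains"
#' (beads on a straight line, internal geometry frozen) joined by a
#' freely jointed linker whose bond directions are redrawn every frame.
#' Each domain is rigidly rotated by an independent uniform random
#' rotation per frame. Frames are independent draws from the
#' conformational ensemble (no temporal correlation), which is what the
#' frame-averaged characterization analyses need. With a single domain
#' and no linker every frame is a rigid rotation of the same rod, so the
#' radius of gyration is constant. With 1-bead domains the molecule is a
#' freely jointed chain and the ensemble-mean squared radius of gyration
#' approaches [idealChainRg2()].
#'
#' @param nFrames number of frames.
#' @param domainSizes integer vector of beads per rigid domain.
#' @param linkerLength number of linker beads between consecutive
#'   domains (0 joins the domains directly).
#' @param bond bead spacing in nm (default 0.38, a C-alpha virtual
#'   bond).
#' @param seed integer seed.
#' @return a [TrajectoryHandle-class] with one `CA` pseudo-atom per bead
#'   at 10 ps nominal frame spacing.
#' @export
makeBeadEnsemble <- function(nFrames, domainSizes = c(5L, 5L),
                             linkerLength = 10L, bond = 0.38, seed = 1) {
  if (any(domainSizes < 1L)) stop("domain sizes must be >= 1")
  if (linkerLength < 0L) stop("linkerLength must be >= 0")
  nd <- length(domainSizes)
  nlink <- if (nd >= 2L) linkerLength * (nd - 1L) else 0L
  nbead <- sum(domainSizes) + nlink

  rand_rot <- function() {
    m <- matrix(rnorm(9), 3, 3)
    q <- qr(m)
    R <- qr.Q(q)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
  }
  rand_dir <- function() {
    d <- rnorm(3)
    d / sqrt(sum(d^2))
  }

  coords <- array(0, dim = c(nbead, 3, nFrames))
  .with_seed(.gen_seed(seed, 401L), {
    for (f in seq_len(nFrames)) {
      pos <- matrix(0, nbead, 3)
      cursor <- c(0, 0, 0)
      i <- 0L
      for (d in seq_len(nd)) {
        ndb <- domainSizes[d]
        rod <- outer(seq_len(ndb) - 1, c(bond, 0, 0))  # straight rod
        R <- rand_rot()
        rod <- rod %*% t(R)
        if (d > 1L || i > 0L) {
          cursor <- cursor + bond * rand_dir()
        }
        rod <- sweep(rod, 2, cursor, `+`)
        pos[i + seq_len(ndb), ] <- rod
        i <- i + ndb
        cursor <- rod[ndb, ]
        if (d < nd) {
          for (l in seq_len(linkerLength)) {
            cursor <- cursor + bond * rand_dir()
            i <- i + 1L
            pos[i, ] <- cursor
          }
        }
      }
      coords[, , f] <- pos
    }
  })
  atoms <- data.frame(
    eleno = seq_len(nbead), elety = "CA",
    resno = seq_len(nbead), resid = "ALA", chain = "A"
  )
  new("TrajectoryHandle",
    coords = coords, times = (seq_len(nFrames) - 1) * 10,
    atoms = atoms, sourcePaths = character(0)
  )
}
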