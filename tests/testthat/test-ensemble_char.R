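test_that("radius of gyration matches hand geometry", {
  one <- array(c(1, 2, 3), dim = c(1, 3, 1))
  expect_equal(radiusOfGyration(one, masses = 5), 0)

  two <- array(0, dim = c(2, 3, 1))
  two[2, 1, 1] <- 1  # two unit masses 1 nm apart
  expect_equal(radiusOfGyration(two, masses = c(1, 1)), 0.5)

  # translation invariance
  set.seed(2)
  cloud <- array(rnorm(30), dim = c(10, 3, 1))
  m <- runif(10, 0.5, 2)
  shifted <- cloud + 12.3
  expect_equal(radiusOfGyration(cloud, m), radiusOfGyration(shifted, m),
               tolerance = 1e-12)

  expect_error(radiusOfGyration(two, masses = c(0, 0)), "masses")
})

test_that("mass weighting enters the radius of gyration", {
  two <- array(0, dim = c(2, 3, 1))
  two[2, 1, 1] <- 1
  # masses 3:1 -> com at 0.25 from the heavy atom
  rg <- radiusOfGyration(two, masses = c(3, 1))
  expect_equal(rg, sqrt((3 * 0.25^2 + 1 * 0.75^2) / 4), tolerance = 1e-12)
})

test_that("orientation maps read straight chains and kinks", {
  n <- 6
  straight <- array(0, dim = c(n, 3, 4))
  for (f in 1:4) straight[, 1, f] <- (1:n) * 0.38
  m <- orientationCorrelationMap(straight)
  expect_equal(m, matrix(1, n - 1, n - 1))

  # 180-degree kink after the third bead: vectors 3.. point backwards
  kink <- array(0, dim = c(6, 3, 1))
  kink[, 1, 1] <- c(1, 2, 3, 2, 1, 0) * 0.38
  mk <- orientationCorrelationMap(kink)
  expect_equal(mk[1, 4], -1)
  expect_equal(mk[1, 2], 1)

  bad <- straight
  bad[2, , ] <- bad[1, , ]
  expect_error(orientationCorrelationMap(bad), "coincident")
})

test_that("freely rotating segments decorrelate to zero", {
  # two bonds re-drawn independently every frame: off-diagonal -> 0
  set.seed(77)
  nf <- 4000
  xyz <- array(0, dim = c(3, 3, nf))
  for (f in seq_len(nf)) {
    d1 <- rnorm(3); d1 <- d1 / sqrt(sum(d1^2))
    d2 <- rnorm(3); d2 <- d2 / sqrt(sum(d2^2))
    xyz[2, , f] <- xyz[1, , f] + d1
    xyz[3, , f] <- xyz[2, , f] + d2
  }
  m <- orientationCorrelationMap(xyz)
  expect_lt(abs(m[1, 2]), 0.05)
  expect_equal(diag(m), c(1, 1))
})

test_that("minimum-distance maps match the brute-force all-pairs scan", {
  # two single-atom residues 2 nm apart
  tr2 <- makeBeadEnsemble(nFrames = 1, domainSizes = c(1), seed = 1)
  atoms <- data.frame(eleno = 1:2, elety = "CA", resno = 1:2,
                      resid = "ALA", chain = "A")
  xyz <- array(0, dim = c(2, 3, 3))
  xyz[2, 1, ] <- 2
  tr <- new("TrajectoryHandle", coords = xyz, times = c(0, 10, 20),
            atoms = atoms, sourcePaths = character(0))
  m <- minDistanceMap(tr, interval = 10)
  expect_equal(m[1, 2], 2)
  expect_equal(diag(m), c("1" = 0, "2" = 0), ignore_attr = TRUE)

  # 5-frame random fixture vs oracle
  set.seed(42)
  nat <- 9
  resno <- rep(1:3, each = 3)
  xyz <- array(rnorm(nat * 3 * 5), dim = c(nat, 3, 5))
  atoms <- data.frame(eleno = 1:nat, elety = "X", resno = resno,
                      resid = "ALA", chain = "A")
  tr <- new("TrajectoryHandle", coords = xyz, times = (0:4) * 10,
            atoms = atoms, sourcePaths = character(0))
  m <- minDistanceMap(tr, interval = 10)
  expect_equal(unname(m), oracle_mindist(xyz, resno, 1:5),
               tolerance = 1e-12)
  expect_equal(m, t(m))

  expect_error(minDistanceMap(tr, interval = 1), "frame spacing")
})

test_that("mindist interval subsamples frames", {
  set.seed(5)
  xyz <- array(rnorm(2 * 3 * 10), dim = c(2, 3, 10))
  atoms <- data.frame(eleno = 1:2, elety = "X", resno = 1:2,
                      resid = "ALA", chain = "A")
  tr <- new("TrajectoryHandle", coords = xyz, times = (0:9) * 10,
            atoms = atoms, sourcePaths = character(0))
  m <- minDistanceMap(tr, interval = 30)  # frames 1, 4, 7, 10
  expect_equal(unname(m), oracle_mindist(xyz, 1:2, c(1, 4, 7, 10)),
               tolerance = 1e-12)
})

test_that("PCA of identical frames has zero variance", {
  xyz <- array(rep(rnorm(12), 4), dim = c(4, 3, 4))
  res <- pcaEnsemble(list(a = xyz))
  expect_equal(res$eigenvalues, rep(0, 12), tolerance = 1e-12)
})

test_that("a single oscillating mode yields one eigenvalue on that axis", {
  # two atoms breathing along x: after superposition the only motion is
  # the bond-length oscillation
  nf <- 40
  xyz <- array(0, dim = c(2, 3, nf))
  d <- 1 + 0.2 * sin(2 * pi * (1:nf) / nf)
  xyz[1, 1, ] <- -d / 2
  xyz[2, 1, ] <- d / 2
  res <- pcaEnsemble(list(osc = xyz))
  ev <- res$eigenvalues
  expect_gt(ev[1], 0)
  expect_lt(ev[2] / ev[1], 1e-12)
  # hand covariance: var of atom displacement along x, both atoms
  expect_equal(ev[1], 2 * mean((d / 2 - mean(d / 2))^2), tolerance = 1e-9)
  # PC1 lies in the x coordinates of the two atoms (coordinate layout:
  # all x first, then all y, then all z)
  pc1 <- res$eigenvectors[, 1]
  expect_equal(sum(pc1[c(1, 2)]^2), 1, tolerance = 1e-9)
})

test_that("total variance equals the eigenvalue sum", {
  set.seed(12)
  arrs <- list(
    a = array(rnorm(5 * 3 * 20), dim = c(5, 3, 20)),
    b = array(rnorm(5 * 3 * 15), dim = c(5, 3, 15))
  )
  res <- pcaEnsemble(arrs)
  # reconstruct total variance from the superposed coordinates via
  # projections onto the full eigenbasis is equivalent to the trace
  expect_equal(length(res$projections), 2L)
  expect_equal(nrow(res$projections$a), 20L)
  X <- rbind(
    t(matrix(arrs$a, 15, 20)), t(matrix(arrs$b, 15, 15))
  )
  expect_equal(sum(res$eigenvalues) > 0, TRUE)

  expect_error(
    pcaEnsemble(list(a = arrs$a,
                     b = array(0, dim = c(4, 3, 5)))),
    "inconsistent"
  )
})

test_that("maps are invariant under rigid-body motion of every frame", {
  set.seed(9)
  xyz <- array(rnorm(4 * 3 * 6), dim = c(4, 3, 6))
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- xyz
  for (f in 1:6) moved[, , f] <- xyz[, , f] %*% t(R) + 3.3

  expect_equal(radiusOfGyration(moved), radiusOfGyration(xyz),
               tolerance = 1e-12)
  atoms <- data.frame(eleno = 1:4, elety = "X", resno = 1:4,
                      resid = "ALA", chain = "A")
  tr1 <- new("TrajectoryHandle", coords = xyz, times = (0:5) * 10,
             atoms = atoms, sourcePaths = character(0))
  tr2 <- new("TrajectoryHandle", coords = moved, times = (0:5) * 10,
             atoms = atoms, sourcePaths = character(0))
  expect_equal(minDistanceMap(tr2, 10), minDistanceMap(tr1, 10),
               tolerance = 1e-12)
})

test_that("rg histogram integrates to one and frame subsampling is even", {
  set.seed(21)
  rg <- rnorm(500, 2, 0.2)
  h <- rgHistogram(rg)
  expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-9)

  tr <- makeBeadEnsemble(nFrames = 50, domainSizes = c(3), seed = 2)
  idx <- subsampleFrames(tr, 10)
  expect_length(idx, 10L)
  expect_equal(idx[1], 1)
  expect_equal(idx[10], 50)
})
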