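# Independent oracles, coded directly from the physics (kept free of any
# package internals so they can vouch for the implementation).

# Closed-form Redfield observables for a single-Lorentzian spectral
# density J(w) = 2 tau / (1 + (w tau)^2).
oracle_redfield <- function(tau, field_mhz, delta_sigma_ppm = -160,
                            r_nh_nm = 0.101, n_h = 1,
                            gamma_h = 2.6752218744e8,
                            gamma_n = -2.71261804e7,
                            noe_minus = TRUE) {
  w_h <- 2 * pi * field_mhz * 1e6
  w_n <- w_h * gamma_n / gamma_h
  J <- function(w) 2 * tau / (1 + (abs(w) * tau)^2)
  mu0 <- 4e-7 * pi
  hbar <- 1.054571817e-34
  d <- mu0 * hbar * gamma_h * gamma_n / (4 * pi * (r_nh_nm * 1e-9)^3)
  dip <- d^2 * n_h / 20
  csa <- (delta_sigma_ppm * 1e-6 * w_n)^2
  r1 <- dip * (J(w_h - w_n) + 3 * J(w_n) + 6 * J(w_h + w_n)) +
    csa / 15 * J(w_n)
  r2 <- 0.5 * dip * (4 * J(0) + J(w_h - w_n) + 3 * J(w_n) +
                       6 * J(w_h) + 6 * J(w_h + w_n)) +
    csa / 90 * (4 * J(0) + 3 * J(w_n))
  t1 <- 1 / r1
  cross <- if (noe_minus) 6 * J(w_h + w_n) - J(w_h - w_n) else
    J(w_h - w_n) + 6 * J(w_h + w_n)
  list(t1 = t1, t2 = 1 / r2,
       hetnoe = 1 + dip * cross * gamma_h / gamma_n * t1)
}

# Brute-force all-origins P2 autocorrelation (double loop).
oracle_p2_acf <- function(v, nlag = nrow(v)) {
  n <- nrow(v)
  sapply(0:(nlag - 1), function(k) {
    mean(sapply(1:(n - k), function(t0) {
      1.5 * sum(v[t0, ] * v[t0 + k, ])^2 - 0.5
    }))
  })
}

# Brute-force minimum-distance map: all atom pairs, all sampled frames.
oracle_mindist <- function(coords, resno, frames) {
  resn <- sort(unique(resno))
  nres <- length(resn)
  m <- matrix(0, nres, nres)
  for (f in frames) {
    for (i in seq_len(nres - 1)) {
      for (j in (i + 1):nres) {
        ai <- which(resno == resn[i])
        aj <- which(resno == resn[j])
        best <- Inf
        for (a in ai) for (b in aj) {
          d <- sqrt(sum((coords[a, , f] - coords[b, , f])^2))
          if (d < best) best <- d
        }
        m[i, j] <- m[i, j] + best
        m[j, i] <- m[j, i] + best
      }
    }
  }
  m / length(frames)
}

# Single-tau spectrum on the nearest grid point; returns the spectrum and
# the exact grid tau it landed on.
single_tau_spectrum <- function(tau, grid = buildTimescaleGrid()) {
  tg <- taus(grid)
  i <- which.min(abs(tg - tau))
  a <- numeric(length(tg))
  a[i] <- 1
  list(
    spectrum = new("TimescaleSpectrum", grid = grid, alphas = a,
                   fitResidual = 0),
    tau = tg[i]
  )
}

# Minimal multi-model PDB writer for hand-built fixtures. atoms: a
# data.frame with elety, resno, resid; coords: n_atoms x 3 x n_frames in
# Angstrom.
write_fixture_pdb <- function(path, atoms, coords) {
  con <- file(path, "w")
  on.exit(close(con))
  nf <- dim(coords)[3]
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    for (a in seq_len(nrow(atoms))) {
      writeLines(sprintf(
        "ATOM  %5d  %-3s %-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        a, atoms$elety[a], atoms$resid[a], atoms$resno[a],
        coords[a, 1, f], coords[a, 2, f], coords[a, 3, f]
      ), con)
    }
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  path
}

# A 3-residue peptide fixture with N, H, CA per residue (no H on request),
# frames rigidly translated so vectors are constant.
make_peptide_fixture <- function(path, n_frames = 3, proline_at = NULL) {
  resids <- rep("ALA", 3)
  if (!is.null(proline_at)) resids[proline_at] <- "PRO"
  rows <- list()
  for (r in 1:3) {
    rows[[length(rows) + 1]] <- data.frame(elety = "N", resno = r,
                                           resid = resids[r])
    if (resids[r] != "PRO")
      rows[[length(rows) + 1]] <- data.frame(elety = "H", resno = r,
                                             resid = resids[r])
    rows[[length(rows) + 1]] <- data.frame(elety = "CA", resno = r,
                                           resid = resids[r])
  }
  atoms <- do.call(rbind, rows)
  base <- matrix(0, nrow(atoms), 3)
  for (a in seq_len(nrow(atoms))) {
    r <- atoms$resno[a]
    base[a, ] <- switch(atoms$elety[a],
      N = c(3.8 * r, 0, 0),
      H = c(3.8 * r, 0, 1.01),
      CA = c(3.8 * r + 1.5, 0, 0)
    )
  }
  coords <- array(0, dim = c(nrow(atoms), 3, n_frames))
  for (f in seq_len(n_frames))
    coords[, , f] <- sweep(base, 2, c(0.5 * (f - 1), 0, 0), `+`)
  write_fixture_pdb(path, atoms, coords)
  atoms
}
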