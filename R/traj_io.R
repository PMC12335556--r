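## Trajectory and text-format I/O. Heavy-format parsing (PDB, DCD) is
## delegated to bio3d; this layer adapts it to TrajectoryHandle and keeps
## units consistent (nm, ps).

.read_frames <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) {
    pdb <- tryCatch(
      bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
      error = function(e) stop("unreadable PDB file '", path, "': ",
                               conditionMessage(e))
    )
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    list(xyz = xyz, atoms = pdb$atom)
  } else if (ext == "dcd") {
    xyz <- tryCatch(
      bio3d::read.dcd(path, verbose = FALSE),
      error = function(e) stop("unreadable DCD file '", path, "': ",
                               conditionMessage(e))
    )
    list(xyz = unclass(xyz), atoms = NULL)
  } else {
    stop("unsupported trajectory format '.", ext,
         "' (supported: multi-model PDB, DCD)")
  }
}

#' Load a trajectory with its topology
#'
#' Reads a topology (PDB) and one or more trajectory files (multi-model
#' PDB or DCD), concatenates their frames, assigns equally spaced frame
#' times, and drops every frame before `skipTime` (an equilibration
#' period excluded from all downstream analyses).
#'
#' Coordinates are converted from the file Angstrom convention to nm.
#'
#' @param topologyPath PDB file providing the atom table. If
#'   `trajectoryPaths` is NULL its models are used as the frames.
#' @param trajectoryPaths character vector of trajectory files.
#' @param skipTime equilibration time to discard, ps; frames with
#'   `t >= skipTime` are retained (default 0).
#' @param dt frame spacing in ps for formats that carry no timestamps
#'   (default 10).
#' @return a [TrajectoryHandle-class].
#' @examples
#' tf <- tempfile(fileext = ".pdb")
#' tr <- makeBeadEnsemble(nFrames = 4, domainSizes = c(3), seed = 1)
#' writeTrajectoryPDB(tr, tf)
#' loadTrajectory(tf)
#' @export
loadTrajectory <- function(topologyPath, trajectoryPaths = NULL,
                           skipTime = 0, dt = 10) {
  if (dt <= 0) stop("dt must be positive")
  top <- .read_frames(topologyPath)
  if (is.null(top$atoms)) stop("topology must be a PDB file")
  atoms <- top$atoms[, c("eleno", "elety", "resno", "resid", "chain")]
  atoms$resno <- as.integer(atoms$resno)
  natoms <- nrow(atoms)

  if (is.null(trajectoryPaths)) {
    xyz <- top$xyz
    paths <- topologyPath
  } else {
    frames <- lapply(trajectoryPaths, .read_frames)
    xyz <- do.call(rbind, lapply(frames, `[[`, "xyz"))
    paths <- c(topologyPath, trajectoryPaths)
  }
  if (ncol(xyz) != 3L * natoms)
    stop("topology atom count (", natoms,
         ") does not match trajectory coordinates (",
         ncol(xyz) / 3, " atoms)")

  nframes <- nrow(xyz)
  times <- (seq_len(nframes) - 1) * dt
  keep <- times >= skipTime
  if (!any(keep))
    stop("skipTime (", skipTime, " ps) >= trajectory length (",
         times[nframes] + dt, " ps): no frames left")
  xyz <- xyz[keep, , drop = FALSE]
  times <- times[keep]

  # frames x 3N -> atoms x 3 x frames, Angstrom -> nm
  coords <- aperm(
    array(t(xyz) / 10, dim = c(3L, natoms, nrow(xyz))),
    c(2L, 1L, 3L)
  )
  new("TrajectoryHandle",
    coords = coords, times = times, atoms = atoms,
    sourcePaths = as.character(paths)
  )
}

#' Write a trajectory as a multi-model PDB
#'
#' Companion writer to [loadTrajectory()]; emits one MODEL per frame with
#' coordinates converted from nm back to Angstrom.
#'
#' @param traj a [TrajectoryHandle-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrajectoryPDB <- function(traj, path) {
  stopifnot(is(traj, "TrajectoryHandle"))
  atoms <- traj@atoms
  con <- file(path, "w")
  on.exit(close(con))
  nframes <- frameCount(traj)
  for (f in seq_len(nframes)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj@coords[, , f, drop = FALSE] * 10
    lines <- sprintf(
      "ATOM  %5d %-4s %-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      atoms$eleno,
      ifelse(nchar(atoms$elety) < 4, paste0(" ", atoms$elety), atoms$elety),
      atoms$resid, atoms$resno,
      xyz[, 1, 1], xyz[, 2, 1], xyz[, 3, 1]
    )
    writeLines(lines, con)
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Extract per-residue amide N-H unit vectors
#'
#' For every selected residue, computes the unit vector from the backbone
#' nitrogen to its amide hydrogen in every frame. By default prolines and
#' the first residue of each chain are excluded: neither carries an amide
#' hydrogen (prolines) or a well-defined one (free N-terminus).
#'
#' @param traj a [TrajectoryHandle-class].
#' @param residues optional integer vector of residue numbers to extract;
#'   requesting a residue with no amide hydrogen is an error.
#' @param excludeProline,excludeFirst apply the default mask (TRUE).
#' @param hNames atom names accepted as the amide hydrogen.
#' @return list of [VectorSeries-class], one per retained residue.
#' @export
extractNHVectors <- function(traj, residues = NULL,
                             excludeProline = TRUE, excludeFirst = TRUE,
                             hNames = c("H", "HN")) {
  stopifnot(is(traj, "TrajectoryHandle"))
  atoms <- traj@atoms
  explicit <- !is.null(residues)

  info <- unique(atoms[, c("chain", "resno", "resid")])
  info <- info[order(info$chain, info$resno), ]
  cand <- info
  if (!explicit) {
    if (excludeFirst) {
      first <- !duplicated(cand$chain)
      cand <- cand[!first, , drop = FALSE]
    }
    if (excludeProline)
      cand <- cand[cand$resid != "PRO", , drop = FALSE]
  } else {
    cand <- cand[cand$resno %in% residues, , drop = FALSE]
    if (!all(residues %in% cand$resno))
      stop("residues not in topology: ",
           paste(setdiff(residues, cand$resno), collapse = ", "))
  }

  out <- list()
  for (k in seq_len(nrow(cand))) {
    rno <- cand$resno[k]
    ch <- cand$chain[k]
    sel <- atoms$resno == rno & atoms$chain == ch
    iN <- which(sel & atoms$elety == "N")
    iH <- which(sel & atoms$elety %in% hNames)
    if (length(iN) != 1L || length(iH) < 1L) {
      if (explicit)
        stop("residue ", rno, " (", cand$resid[k],
             ") has no amide N-H pair")
      next
    }
    iH <- iH[1]
    v <- t(traj@coords[iH, , ] - traj@coords[iN, , ])
    if (frameCount(traj) == 1L) v <- matrix(v, nrow = 1)
    out[[length(out) + 1L]] <- vectorSeries(rno, traj@times, v)
  }
  out
}

.parse_unit <- function(colname) {
  m <- regmatches(colname, regexec("\\[([^]]+)\\]", colname))[[1]]
  if (length(m) < 2) return(1)
  switch(tolower(m[2]),
    "s" = 1, "ms" = 1e-3, "us" = 1e-6, "ns" = 1e-9,
    stop("unparseable unit '", m[2], "' in column '", colname, "'")
  )
}

#' Read a per-residue relaxation table
#'
#' Parses whitespace- or comma-separated tables with a residue column and
#' T1/T2/hetNOE columns (plus optional error columns). Units are declared
#' in the header as `T1[s]` or `T1[ms]`; seconds by default. Missing
#' entries (empty, `nan`, `NA`) become NA, never zero.
#'
#' Recognized headers: `# residue T1[s] T2[s] hetNOE [T1_err T2_err
#' NOE_err]` (whitespace dialect) or a CSV header line such as
#' `res,T1,T2,NOE`. A `# field_mhz <value>` comment sets the field.
#'
#' @param path input file.
#' @param dialect `"auto"` (default), `"whitespace"` or `"csv"`.
#' @param fieldMhz spectrometer field, used when the file does not
#'   declare one.
#' @return a [RelaxationProfile-class].
#' @export
readRelaxationTable <- function(path, dialect = c("auto", "whitespace", "csv"),
                                fieldMhz = 600) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]

  fm <- grep("^#\\s*field_mhz", lines, value = TRUE)
  if (length(fm))
    fieldMhz <- as.numeric(sub("^#\\s*field_mhz\\s+", "", fm[1]))

  comment <- grepl("^\\s*#", lines)
  header_line <- NULL
  body <- lines[!comment]
  if (dialect == "auto")
    dialect <- if (any(grepl(",", body))) "csv" else "whitespace"

  if (dialect == "csv") {
    header_line <- body[1]
    body <- body[-1]
    cols <- trimws(strsplit(header_line, ",")[[1]])
    split_fun <- function(l) trimws(strsplit(l, ",", fixed = TRUE)[[1]])
  } else {
    hdr <- grep("^#\\s*residue", lines, value = TRUE)
    if (!length(hdr))
      stop("no '# residue ...' header found in whitespace table")
    cols <- strsplit(sub("^#\\s*", "", hdr[1]), "\\s+")[[1]]
    split_fun <- function(l) strsplit(trimws(l), "\\s+")[[1]]
  }

  low <- tolower(cols)
  i_res <- which(low %in% c("residue", "res", "resid", "resno"))
  i_t1 <- which(startsWith(low, "t1") & !grepl("err", low))
  i_t2 <- which(startsWith(low, "t2") & !grepl("err", low))
  i_noe <- which(grepl("noe", low) & !grepl("err", low))
  i_t1e <- which(startsWith(low, "t1") & grepl("err", low))
  i_t2e <- which(startsWith(low, "t2") & grepl("err", low))
  i_noee <- which(grepl("noe", low) & grepl("err", low))
  if (!length(i_res))
    stop("relaxation table needs a residue column")
  if (!length(i_t1) && !length(i_t2) && !length(i_noe))
    stop("relaxation table needs at least one observable column")

  num <- function(x) {
    x[x %in% c("", "nan", "NaN", "NA", "na", "-")] <- NA
    suppressWarnings(as.numeric(x))
  }
  fields <- lapply(body, split_fun)
  get_col <- function(i, scale = 1) {
    if (!length(i)) return(rep(NA_real_, length(fields)))
    vapply(fields, function(f) {
      if (length(f) >= i[1]) num(f[i[1]]) else NA_real_
    }, numeric(1)) * scale
  }

  res <- get_col(i_res)
  if (anyDuplicated(res[!is.na(res)]))
    stop("duplicate residue IDs in relaxation table")
  relaxationProfile(
    residueIds = res,
    t1 = get_col(i_t1, if (length(i_t1)) .parse_unit(cols[i_t1[1]]) else 1),
    t2 = get_col(i_t2, if (length(i_t2)) .parse_unit(cols[i_t2[1]]) else 1),
    hetnoe = get_col(i_noe),
    t1Err = get_col(i_t1e, if (length(i_t1e)) .parse_unit(cols[i_t1e[1]]) else 1),
    t2Err = get_col(i_t2e, if (length(i_t2e)) .parse_unit(cols[i_t2e[1]]) else 1),
    noeErr = get_col(i_noee),
    fieldMhz = fieldMhz
  )
}

#' Write a relaxation table
#'
#' Emits the whitespace dialect understood by [readRelaxationTable()]:
#' `# residue T1[s] T2[s] hetNOE T1_err T2_err NOE_err`, full double
#' precision, NA as `nan`.
#'
#' @param profile a [RelaxationProfile-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRelaxationTable <- function(profile, path) {
  stopifnot(is(profile, "RelaxationProfile"))
  fmt <- function(x) ifelse(is.na(x), "nan", sprintf("%.17g", x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# field_mhz %.17g", profile@fieldMhz), con)
  writeLines("# residue T1[s] T2[s] hetNOE T1_err T2_err NOE_err", con)
  writeLines(paste(
    profile@residueIds,
    fmt(profile@t1), fmt(profile@t2), fmt(profile@hetnoe),
    fmt(profile@t1Err), fmt(profile@t2Err), fmt(profile@noeErr)
  ), con)
  invisible(path)
}

#' Read a two-column xvg correlation function file
#'
#' Grace-format files as produced by trajectory analysis tools: lines
#' starting with `#` or `@` are comments, then two numeric columns
#' (time in ps, correlation value).
#'
#' @param path input file.
#' @return list with numeric `times` (ps) and `values`.
#' @export
readXvgAcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*[#@]", lines)]
  if (!length(lines)) stop("no data rows in xvg file ", path)
  parts <- strsplit(trimws(lines), "\\s+")
  times <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  values <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  if (any(is.na(times)) || any(is.na(values)))
    stop("non-numeric data in xvg file ", path)
  if (any(diff(times) <= 0))
    stop("non-monotonic times in xvg file ", path)
  list(times = times, values = values)
}

#' Write an xvg correlation function file
#'
#' @param times lag times in ps.
#' @param values correlation values.
#' @param path output file.
#' @param title optional title comment.
#' @return `path`, invisibly.
#' @export
writeXvgAcf <- function(times, values, path, title = "rotational ACF") {
  stopifnot(length(times) == length(values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("@    title \"%s\"", title),
    "@    xaxis  label \"Time (ps)\"",
    "@    yaxis  label \"C(t)\""
  ), con)
  writeLines(sprintf("%.17g %.17g", times, values), con)
  invisible(path)
}
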