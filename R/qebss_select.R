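## Quality evaluation and selection: per-observable RMSD against
## experiment, comparison numbers, threshold selection, and construction
## of the combined ensemble from averaged correlation functions.

.obs_slot <- c(t1 = "t1", t2 = "t2", noe = "hetnoe")

#' Residue-averaged RMSD between predicted and experimental observables
#'
#' Root-mean-square deviation over residues present and finite in both
#' profiles, in the native units of the observable (seconds for T1/T2,
#' dimensionless for hetNOE). Experimental errors are not used as
#' weights. Residues of the simulated profile absent from the
#' experimental table are dropped (their count is reported via
#' `n_used`).
#'
#' @param sim,exp [RelaxationProfile-class] objects, matched by residue
#'   number.
#' @param observable `"t1"`, `"t2"` or `"noe"`.
#' @return list with `rmsd` and `n_used` (number of residues compared).
#' @export
rmsdObservable <- function(sim, exp, observable = c("t1", "t2", "noe")) {
  observable <- match.arg(observable)
  slot_name <- .obs_slot[[observable]]
  s <- slot(sim, slot_name)
  e <- slot(exp, slot_name)
  m <- match(exp@residueIds, sim@residueIds)
  ok <- !is.na(m) & is.finite(e) & is.finite(s[m])
  if (!any(ok))
    stop("no residues with finite ", observable,
         " values in both profiles")
  d <- s[m[ok]] - e[ok]
  list(rmsd = sqrt(mean(d^2)), n_used = sum(ok))
}

#' RMSD table for a set of candidate simulations
#'
#' @param sims named list of predicted [RelaxationProfile-class], one per
#'   simulation.
#' @param exp experimental [RelaxationProfile-class].
#' @return data.frame with one row per simulation: `sim`, `rmsd_t1`,
#'   `rmsd_t2`, `rmsd_noe`, `n_t1`, `n_t2`, `n_noe`.
#' @export
rmsdTable <- function(sims, exp) {
  if (!length(sims)) stop("no simulations supplied")
  ids <- names(sims)
  if (is.null(ids)) ids <- as.character(seq_along(sims))
  rows <- lapply(seq_along(sims), function(i) {
    r <- lapply(c("t1", "t2", "noe"), function(ob) {
      tryCatch(rmsdObservable(sims[[i]], exp, ob),
               error = function(e) list(rmsd = NA_real_, n_used = 0L))
    })
    data.frame(
      sim = ids[i],
      rmsd_t1 = r[[1]]$rmsd, rmsd_t2 = r[[2]]$rmsd, rmsd_noe = r[[3]]$rmsd,
      n_t1 = r[[1]]$n_used, n_t2 = r[[2]]$n_used, n_noe = r[[3]]$n_used
    )
  })
  do.call(rbind, rows)
}

#' Comparison numbers from an RMSD table
#'
#' For each observable, divides every simulation's RMSD by the smallest
#' RMSD for that observable across all simulations, so the best
#' simulation per observable scores exactly 1.0.
#'
#' @param table data.frame as produced by [rmsdTable()].
#' @param threshold comparison-number cutoff carried into the result
#'   (default 1.5, i.e. 150 percent of the best RMSD).
#' @return a [SelectionResult-class] with ratios and the per-observable
#'   best simulations filled in; `selectedIds` is populated by
#'   [selectSimulations()].
#' @export
comparisonNumbers <- function(table, threshold = 1.5) {
  req <- c("sim", "rmsd_t1", "rmsd_t2", "rmsd_noe")
  if (!all(req %in% names(table)))
    stop("RMSD table must have columns ", paste(req, collapse = ", "))
  ratios <- data.frame(sim = table$sim)
  best <- character(0)
  for (ob in c("t1", "t2", "noe")) {
    col <- table[[paste0("rmsd_", ob)]]
    if (all(is.na(col)))
      stop("all RMSDs are NaN for observable ", ob)
    mn <- min(col, na.rm = TRUE)
    ratios[[paste0("ratio_", ob)]] <- if (mn == 0)
      ifelse(col == 0, 1, Inf) else col / mn
    best[ob] <- as.character(table$sim[which.min(col)])
  }
  new("SelectionResult",
    rmsd = table, ratios = ratios, threshold = threshold,
    selectedIds = character(0), bestPerObservable = best
  )
}

#' Select simulations whose comparison numbers all beat the threshold
#'
#' A simulation is selected only when its T1, T2 AND hetNOE comparison
#' numbers are all strictly below the threshold - a simulation that is
#' best for one observable can still be rejected on another. The
#' selection may be empty.
#'
#' @param result a [SelectionResult-class] from [comparisonNumbers()].
#' @param threshold cutoff, must be > 1; default the threshold stored in
#'   `result` (1.5 unless overridden).
#' @return the [SelectionResult-class] with `selectedIds` filled in.
#' @export
selectSimulations <- function(result, threshold = result@threshold) {
  stopifnot(is(result, "SelectionResult"))
  if (threshold <= 1)
    stop("threshold must be > 1 (a threshold <= 1 would reject even ",
         "the best simulation in general)")
  r <- result@ratios
  pass <- r$ratio_t1 < threshold & r$ratio_t2 < threshold &
    r$ratio_noe < threshold
  pass[is.na(pass)] <- FALSE
  result@selectedIds <- as.character(r$sim[pass])
  result@threshold <- threshold
  validObject(result)
  result
}

#' Combine selected simulations into a quality-evaluated ensemble
#'
#' For every residue, averages the correlation functions of the selected
#' simulations, refits the timescale spectra, back-calculates the
#' relaxation observables, and (when an experimental profile is given)
#' recomputes the ensemble RMSDs against experiment.
#'
#' @param selectedIds character vector of simulation IDs (non-empty).
#' @param acfStore named list (per simulation) of named lists (per
#'   residue) of [CorrelationFunction-class].
#' @param params an [NMRParams-class].
#' @param grid a [TimescaleGrid-class].
#' @param exp optional experimental [RelaxationProfile-class] for
#'   ensemble RMSDs.
#' @return list with `acfs` (per-residue averaged correlation
#'   functions), `spectra`, `profile` (ensemble
#'   [RelaxationProfile-class]) and, if `exp` was given, `rmsd` (one-row
#'   data.frame).
#' @export
combineEnsemble <- function(selectedIds, acfStore,
                            params, grid = buildTimescaleGrid(),
                            exp = NULL) {
  if (!length(selectedIds))
    stop("empty selection: no simulation passed the threshold; ",
         "consider reviewing the comparison-number threshold")
  missing_ids <- setdiff(selectedIds, names(acfStore))
  if (length(missing_ids))
    stop("no correlation functions stored for: ",
         paste(missing_ids, collapse = ", "))
  store <- acfStore[selectedIds]
  res_names <- Reduce(intersect, lapply(store, names))
  if (!length(res_names))
    stop("selected simulations share no residues")

  acfs <- lapply(res_names, function(rn) {
    averageAcfs(lapply(store, `[[`, rn))
  })
  names(acfs) <- res_names
  pred <- predictProfile(acfs, params, grid)
  out <- list(acfs = acfs, spectra = pred$spectra, profile = pred$profile)
  if (!is.null(exp))
    out$rmsd <- rmsdTable(list(ensemble = pred$profile), exp)
  out
}
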