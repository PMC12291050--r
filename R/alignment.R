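#' Order runs for sequential alignment
#'
#' Runs are merged in descending order of identification count (rows in the
#' filtered run table), starting from the largest run. Ties break
#' lexicographically on run id so the merge order is deterministic.
#'
#' @param runs named list of per-run observation tables.
#' @return character vector of run ids, alignment order.
#' @export
order_runs <- function(runs) {
  if (!is.list(runs) || length(runs) == 0L) stop("order_runs: no runs")
  counts <- vapply(runs, nrow, integer(1))
  ids <- names(runs)
  ids[order(-counts, ids, method = "radix")]
}

#' Estimate the additive CCS offset of one run against the aligned reference
#'
#' Fits the intercept-only model y = x + b for one charge state, where y is
#' the reference CCS of a shared peptidoform-charge pair and x the incoming
#' run's CCS for that pair (its highest-intensity observation when the run
#' holds several candidate conformers of the ion). b is by default the
#' median of the pairwise differences y - x, robust against occasional
#' conformer mismatches contaminating the pairs; the mean is available for
#' strictly Gaussian settings.
#'
#' @param incoming per-run observation table.
#' @param reference aligned dataset as built by \code{\link{align_all}}, or
#'   any data.frame with columns \code{peptidoform}, \code{charge},
#'   \code{ref_ccs}.
#' @param charge charge state to estimate for.
#' @param estimator "median" (default) or "mean".
#' @return list with \code{run_id}, \code{charge}, \code{b},
#'   \code{n_overlap}, and \code{usable} (FALSE when no pairs overlap).
#' @export
estimate_offset <- function(incoming, reference, charge,
                            estimator = c("median", "mean")) {
  estimator <- match.arg(estimator)
  ref <- if (inherits(reference, "ccs_aligned")) reference$reference
         else data.table::as.data.table(reference)
  z <- as.integer(charge)
  inc <- data.table::as.data.table(incoming)[charge == z]
  ## one x per ion: the highest-intensity candidate (NA intensity ranks last)
  inc <- inc[order(-data.table::fifelse(is.na(intensity), -Inf, intensity),
                   ccs)][, .SD[1L], by = .(peptidoform, charge)]
  pairs <- merge(inc, ref[charge == z, .(peptidoform, charge, ref_ccs)],
                 by = c("peptidoform", "charge"))
  n <- nrow(pairs)
  if (n == 0L) {
    return(list(run_id = if (nrow(inc)) inc$run_id[1L] else NA_character_,
                charge = z, b = 0, n_overlap = 0L, usable = FALSE))
  }
  d <- pairs$ref_ccs - pairs$ccs
  b <- if (estimator == "median") stats::median(d) else mean(d)
  list(run_id = inc$run_id[1L], charge = z, b = b, n_overlap = n,
       usable = TRUE)
}

#' Align CCS values across runs by greedy accretion
#'
#' Starting from the run with the most identifications, each remaining run
#' (in \code{\link{order_runs}} order) is compared to the growing aligned
#' set. A run sharing fewer than \code{min_overlap} distinct
#' peptidoform-charge pairs with the aligned set is skipped. Otherwise a
#' charge-specific additive offset b (y = x + b) is estimated per charge
#' state and applied to every observation of that charge in the run before
#' merging. For each ion the aligned set keeps the highest-intensity
#' identification as its alignment reference while retaining all aligned
#' observations.
#'
#' The overlap gate counts distinct (peptidoform, charge) pairs summed over
#' charges. Charges with fewer than \code{min_pairs_per_charge} shared pairs
#' fall back to b = 0 (recorded with \code{usable = FALSE}) to avoid wild
#' offsets from sparse charge states.
#'
#' @param runs named list of per-run observation tables (already passed
#'   through \code{\link{filter_identified}}).
#' @param min_overlap minimum shared pair count to merge a run (default 100).
#' @param estimator offset estimator, "median" or "mean".
#' @param min_pairs_per_charge minimum pairs for a per-charge offset
#'   (default 10).
#' @return object of class \code{ccs_aligned}: list with
#'   \describe{
#'     \item{observations}{data.table of all retained observations with
#'       aligned \code{ccs} (and original values in \code{ccs_raw}).}
#'     \item{reference}{per-ion reference table (\code{peptidoform},
#'       \code{charge}, \code{ref_ccs}, \code{ref_intensity}).}
#'     \item{offsets}{audit table (\code{run_id}, \code{charge}, \code{b},
#'       \code{n_overlap}, \code{usable}).}
#'     \item{skipped_runs}{data.table (\code{run_id}, \code{reason}).}
#'   }
#' @export
align_all <- function(runs, min_overlap = 100L,
                      estimator = c("median", "mean"),
                      min_pairs_per_charge = 10L) {
  estimator <- match.arg(estimator)
  ord <- order_runs(runs)
  offsets <- list()
  skipped <- list()
  obs_acc <- list()

  seed <- data.table::copy(runs[[ord[1L]]])
  seed[, ccs_raw := ccs]
  obs_acc[[ord[1L]]] <- seed
  reference <- build_reference(seed)

  for (rid in ord[-1L]) {
    run <- data.table::copy(runs[[rid]])
    run[, ccs_raw := ccs]
    ## overlap: distinct (peptidoform, charge) pairs shared with aligned set
    run_ions <- unique(run[, .(peptidoform, charge)])
    shared <- merge(run_ions, reference[, .(peptidoform, charge)],
                    by = c("peptidoform", "charge"))
    if (nrow(shared) < min_overlap) {
      skipped[[rid]] <- data.table::data.table(
        run_id = rid,
        reason = sprintf("overlap %d < %d", nrow(shared), min_overlap))
      next
    }
    for (z in sort(unique(run$charge))) {
      off <- estimate_offset(run, reference, z, estimator)
      if (!off$usable || off$n_overlap < min_pairs_per_charge) {
        off$b <- 0
        off$usable <- FALSE
      }
      offsets[[length(offsets) + 1L]] <- off
      run[charge == z, ccs := ccs + off$b]
    }
    obs_acc[[rid]] <- run
    reference <- update_reference(reference, run)
  }

  observations <- data.table::rbindlist(obs_acc)
  structure(list(
    observations = observations,
    reference = reference,
    offsets = if (length(offsets)) data.table::rbindlist(
      lapply(offsets, data.table::as.data.table)) else
      data.table::data.table(run_id = character(0), charge = integer(0),
                             b = numeric(0), n_overlap = integer(0),
                             usable = logical(0)),
    skipped_runs = if (length(skipped)) data.table::rbindlist(skipped) else
      data.table::data.table(run_id = character(0), reason = character(0))
  ), class = "ccs_aligned")
}

## per-ion reference = highest-intensity identification (NA ranks last,
## ties broken by lower CCS for determinism)
build_reference <- function(obs) {
  obs[order(-data.table::fifelse(is.na(intensity), -Inf, intensity), ccs),
      .(ref_ccs = ccs[1L], ref_intensity = intensity[1L]),
      by = .(peptidoform, charge)]
}

update_reference <- function(reference, new_obs) {
  cand <- new_obs[, .(peptidoform, charge, ref_ccs = ccs,
                      ref_intensity = intensity)]
  build_reference(data.table::rbindlist(list(
    reference[, .(peptidoform, charge, ccs = ref_ccs,
                  intensity = ref_intensity)],
    cand[, .(peptidoform, charge, ccs = ref_ccs, intensity = ref_intensity)]
  )))
}

#' @export
print.ccs_aligned <- function(x, ...) {
  cat("Aligned CCS dataset\n")
  cat("  observations:", nrow(x$observations), "\n")
  cat("  reference ions:", nrow(x$reference), "\n")
  cat("  merged runs:", length(unique(x$observations$run_id)), "\n")
  cat("  skipped runs:", nrow(x$skipped_runs), "\n")
  invisible(x)
}
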