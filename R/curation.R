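#' Curation configuration
#'
#' @param tau relative CCS tolerance defining distinct conformers
#'   (default 0.02, i.e. the 2\% rule).
#' @param min_run_support minimum number of distinct runs in which a
#'   conformer must recur (default 2, "identified in multiple runs").
#' @param max_charge maximum retained charge state (default 4; 5+ and 6+
#'   ions are excluded before classification).
#' @param denom denominator convention for the relative difference:
#'   "min" (conservative, default) or "mean".
#' @param within_run_rep within-run cluster representative:
#'   "intensity_weighted" mean (default) or plain "mean".
#' @return list of class \code{curation_config}.
#' @export
curation_config <- function(tau = 0.02, min_run_support = 2L,
                            max_charge = 4L,
                            denom = c("min", "mean"),
                            within_run_rep = c("intensity_weighted", "mean")) {
  stopifnot(tau > 0, tau < 1, min_run_support >= 2L)
  structure(list(tau = tau, min_run_support = as.integer(min_run_support),
                 max_charge = as.integer(max_charge),
                 denom = match.arg(denom),
                 within_run_rep = match.arg(within_run_rep)),
            class = "curation_config")
}

#' Relative CCS difference
#'
#' \code{|a - b| / min(a, b)} by default (symmetric, conservative); the
#' "mean" convention divides by \code{(a + b)/2}. Vectorized.
#'
#' @param a,b positive CCS values (recycled).
#' @param denom "min" or "mean".
#' @return nonnegative fraction(s).
#' @export
relative_difference <- function(a, b, denom = c("min", "mean")) {
  denom <- match.arg(denom)
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0))
    stop("relative_difference: inputs must be finite and positive")
  d <- if (denom == "min") pmin(a, b) else (a + b) / 2
  abs(a - b) / d
}

#' Split one ion's observations within one run into conformer candidates
#'
#' Observations are sorted ascending by CCS and clustered in a single
#' greedy pass: an observation joins the open cluster iff its relative
#' difference to the cluster's running (unweighted) mean is at most
#' \code{tau}, otherwise it opens a new cluster. Each cluster is summarized
#' by an intensity-weighted mean CCS (falling back to the plain mean when
#' all intensities are missing).
#'
#' @param ccs numeric vector of CCS values for one ion in one run.
#' @param intensity matching intensity vector (NA allowed).
#' @param cfg \code{\link{curation_config}}.
#' @return data.table with one row per candidate: \code{ccs} (the
#'   representative), \code{n_members}, sorted ascending by \code{ccs}.
#' @export
split_within_run <- function(ccs, intensity = NULL,
                             cfg = curation_config()) {
  stopifnot(length(ccs) >= 1L)
  if (is.null(intensity)) intensity <- rep(NA_real_, length(ccs))
  o <- order(ccs)
  ccs <- ccs[o]; intensity <- intensity[o]
  cl <- greedy_cluster_1d(ccs, cfg$tau, cfg$denom)
  reps <- vapply(split(seq_along(ccs), cl), function(idx) {
    w <- intensity[idx]
    if (cfg$within_run_rep == "intensity_weighted" && any(!is.na(w)) &&
        sum(w, na.rm = TRUE) > 0) {
      w[is.na(w)] <- 0
      sum(ccs[idx] * w) / sum(w)
    } else mean(ccs[idx])
  }, numeric(1))
  ns <- as.integer(table(cl))
  data.table::data.table(ccs = unname(reps), n_members = ns)
}

## greedy single-pass 1-d clustering of ascending values against the
## running unweighted cluster mean; returns integer cluster labels
greedy_cluster_1d <- function(x, tau, denom = "min") {
  n <- length(x)
  lab <- integer(n)
  lab[1L] <- 1L
  cl_sum <- x[1L]; cl_n <- 1L; k <- 1L
  if (n > 1L) for (i in 2:n) {
    m <- cl_sum / cl_n
    if (relative_difference(x[i], m, denom) <= tau) {
      lab[i] <- k; cl_sum <- cl_sum + x[i]; cl_n <- cl_n + 1L
    } else {
      k <- k + 1L; lab[i] <- k; cl_sum <- x[i]; cl_n <- 1L
    }
  }
  lab
}

#' Match one ion's per-run conformer candidates across runs
#'
#' Candidates from all runs are processed in ascending CCS order; each
#' joins the nearest existing cluster whose running mean lies within
#' \code{tau} and that does not yet contain a candidate from the same run,
#' otherwise it opens a new cluster. When a run contributes two candidates
#' both within \code{tau} of one cluster, the nearer (processed first in
#' ascending order) stays and the other opens a new cluster; such events
#' are flagged in the \code{crowded} attribute.
#'
#' @param candidates data.table with columns \code{run_id}, \code{ccs}
#'   (one row per within-run candidate of a single ion).
#' @param cfg \code{\link{curation_config}}.
#' @return data.table with one row per cross-run cluster: \code{mean_ccs}
#'   (unweighted mean over members), \code{run_support} (distinct runs),
#'   \code{n_members}, list-column \code{members} (data.table run_id, ccs),
#'   sorted ascending by \code{mean_ccs}.
#' @export
match_across_runs <- function(candidates, cfg = curation_config()) {
  cand <- data.table::as.data.table(candidates)
  stopifnot(nrow(cand) >= 1L, all(c("run_id", "ccs") %in% names(cand)))
  cand <- cand[order(ccs, run_id)]
  n <- nrow(cand)
  lab <- integer(n)
  sums <- numeric(0); cnts <- integer(0)
  runs_in <- list()
  crowded <- FALSE
  for (i in seq_len(n)) {
    x <- cand$ccs[i]; r <- cand$run_id[i]
    best <- 0L; bestd <- Inf
    for (k in seq_along(sums)) {
      m <- sums[k] / cnts[k]
      if (relative_difference(x, m, cfg$denom) <= cfg$tau) {
        if (r %in% runs_in[[k]]) { crowded <- TRUE; next }
        d <- abs(x - m)
        if (d < bestd) { bestd <- d; best <- k }
      }
    }
    if (best == 0L) {
      sums <- c(sums, x); cnts <- c(cnts, 1L)
      runs_in[[length(sums)]] <- r
      lab[i] <- length(sums)
    } else {
      sums[best] <- sums[best] + x; cnts[best] <- cnts[best] + 1L
      runs_in[[best]] <- c(runs_in[[best]], r)
      lab[i] <- best
    }
  }
  out <- cand[, .(mean_ccs = mean(ccs),
                  run_support = data.table::uniqueN(run_id),
                  n_members = .N,
                  members = list(data.table::data.table(run_id = run_id,
                                                        ccs = ccs))),
              by = .(cluster = lab)][order(mean_ccs)]
  out[, cluster := NULL]
  data.table::setattr(out, "crowded", crowded)
  out
}

#' Classify one ion's cross-run conformer clusters
#'
#' An ion whose charge exceeds \code{max_charge} is discarded. Clusters
#' with \code{run_support < min_run_support} are non-recurrent. The ion is
#' labeled \code{multi} when at least two recurrent clusters remain (their
#' sorted means become the record's CCS values; non-recurrent clusters are
#' dropped); \code{uni} when there is exactly one cluster overall and every
#' member pair lies within \code{tau}; otherwise it is discarded —
#' conformers seen only between runs (never recurring) place the ion in
#' neither dataset. Adjacent recurrent clusters whose means fall within
#' \code{tau} of each other are merged before labeling so that multi
#' records keep strictly separated CCS values.
#'
#' @param clusters output of \code{\link{match_across_runs}}.
#' @param ion list or one-row data.frame with \code{peptidoform},
#'   \code{charge}.
#' @param cfg \code{\link{curation_config}}.
#' @return one-row data.table (\code{peptidoform}, \code{charge},
#'   list-columns \code{ccs_values}, \code{supports}, \code{label}) or
#'   NULL when the ion is discarded.
#' @export
classify_ion <- function(clusters, ion, cfg = curation_config()) {
  z <- as.integer(ion$charge)
  if (z > cfg$max_charge) return(NULL)
  cl <- data.table::as.data.table(clusters)
  rec <- cl[run_support >= cfg$min_run_support]
  if (nrow(rec) >= 2L) {
    ## merge adjacent recurrent clusters closer than tau (rare; keeps the
    ## multi invariant: adjacent gaps strictly exceed tau)
    mm <- rec$mean_ccs; ss <- rec$run_support; nn <- rec$n_members
    i <- 1L
    while (i < length(mm)) {
      if (relative_difference(mm[i], mm[i + 1L], cfg$denom) <= cfg$tau) {
        w <- nn[i] + nn[i + 1L]
        mm[i] <- (mm[i] * nn[i] + mm[i + 1L] * nn[i + 1L]) / w
        ss[i] <- max(ss[i], ss[i + 1L]); nn[i] <- w
        mm <- mm[-(i + 1L)]; ss <- ss[-(i + 1L)]; nn <- nn[-(i + 1L)]
      } else i <- i + 1L
    }
    if (length(mm) >= 2L) {
      return(data.table::data.table(
        peptidoform = ion$peptidoform, charge = z,
        ccs_values = list(mm), supports = list(as.integer(ss)),
        label = "multi"))
    }
    ## collapsed to one cluster: fall through to the uni criterion below
    cl <- data.table::data.table(mean_ccs = mm, run_support = ss,
                                 n_members = nn,
                                 members = list(data.table::rbindlist(
                                   cl$members)))
  }
  if (nrow(cl) == 1L) {
    mem <- cl$members[[1L]]
    rng <- range(mem$ccs)
    if (relative_difference(rng[1L], rng[2L], cfg$denom) <= cfg$tau) {
      return(data.table::data.table(
        peptidoform = ion$peptidoform, charge = z,
        ccs_values = list(cl$mean_ccs),
        supports = list(as.integer(cl$run_support)),
        label = "uni"))
    }
  }
  NULL
}

#' Curate an aligned dataset into uni- and multiconformer records
#'
#' For every peptidoform-charge pair: observations are split into within-run
#' conformer candidates per run (\code{\link{split_within_run}}), the
#' candidates are matched across runs (\code{\link{match_across_runs}}), and
#' the resulting clusters are classified (\code{\link{classify_ion}}).
#' Deterministic given identical input.
#'
#' @param aligned \code{ccs_aligned} object from \code{\link{align_all}}, or
#'   a data.frame of observations with \code{peptidoform}, \code{charge},
#'   \code{run_id}, \code{ccs}, \code{intensity}.
#' @param cfg \code{\link{curation_config}}.
#' @return list with data.tables \code{multi}, \code{uni} (curated records)
#'   and \code{discarded} (peptidoform, charge, reason).
#' @export
curate <- function(aligned, cfg = curation_config()) {
  obs <- if (inherits(aligned, "ccs_aligned")) aligned$observations
         else data.table::as.data.table(aligned)
  stopifnot(all(c("peptidoform", "charge", "run_id", "ccs") %in% names(obs)))
  if (!"intensity" %in% names(obs)) obs$intensity <- NA_real_
  data.table::setorder(obs, peptidoform, charge, run_id, ccs)

  ## within-run candidates for every (ion, run)
  cand <- obs[, split_within_run(ccs, intensity, cfg),
              by = .(peptidoform, charge, run_id)]

  multi <- list(); uni <- list(); disc <- list()
  ions <- split(cand, by = c("peptidoform", "charge"), sorted = TRUE)
  for (one in ions) {
    ion <- list(peptidoform = one$peptidoform[1L], charge = one$charge[1L])
    if (ion$charge > cfg$max_charge) {
      disc[[length(disc) + 1L]] <- data.table::data.table(
        peptidoform = ion$peptidoform, charge = ion$charge,
        reason = "charge")
      next
    }
    clusters <- match_across_runs(one[, .(run_id, ccs)], cfg)
    rec <- classify_ion(clusters, ion, cfg)
    if (is.null(rec)) {
      disc[[length(disc) + 1L]] <- data.table::data.table(
        peptidoform = ion$peptidoform, charge = ion$charge,
        reason = "ambiguous")
    } else if (rec$label == "multi") {
      multi[[length(multi) + 1L]] <- rec
    } else {
      uni[[length(uni) + 1L]] <- rec
    }
  }
  empty <- data.table::data.table(peptidoform = character(0),
                                  charge = integer(0), ccs_values = list(),
                                  supports = list(), label = character(0))
  list(
    multi = if (length(multi)) data.table::rbindlist(multi) else empty,
    uni = if (length(uni)) data.table::rbindlist(uni) else empty,
    discarded = if (length(disc)) data.table::rbindlist(disc) else
      data.table::data.table(peptidoform = character(0),
                             charge = integer(0), reason = character(0))
  )
}

#' Physicochemical characterization of curated subsets
#'
#' Summarizes, per subset: sequence length distribution, charge
#' distribution, the fraction of sequences containing at least one proline,
#' the mean per-peptide proline frequency (prolines / length), and the
#' per-residue relative abundance. For multiconformer records the absolute
#' CCS difference between adjacent conformers is tabulated per charge.
#'
#' @param multi,uni curated record tables (list-column \code{ccs_values}).
#' @return list with elements \code{multi} and \code{uni} (each a list of
#'   summaries) and \code{delta_ccs} (data.table charge, delta for multi).
#' @export
characterize <- function(multi, uni) {
  summarize_subset <- function(rec) {
    if (nrow(rec) == 0L) stop("characterize: empty record set")
    seqs <- strip_mods(rec$peptidoform)
    lens <- nchar(seqs)
    pro <- vapply(strsplit(seqs, ""), function(a) sum(a == "P"), numeric(1))
    aa <- table(factor(unlist(strsplit(seqs, "")), levels = AA_LETTERS))
    list(
      n = nrow(rec),
      length_summary = summary(lens),
      mean_length = mean(lens),
      charge_table = table(rec$charge),
      mean_charge = mean(rec$charge),
      proline_presence = mean(pro > 0),
      proline_frequency = mean(pro / lens),
      residue_abundance = stats::setNames(as.numeric(aa) / sum(aa),
                                          AA_LETTERS)
    )
  }
  deltas <- if (nrow(multi)) data.table::rbindlist(lapply(
    seq_len(nrow(multi)), function(i) {
      v <- sort(multi$ccs_values[[i]])
      if (length(v) < 2L) return(NULL)
      data.table::data.table(charge = multi$charge[i], delta = diff(v))
    })) else data.table::data.table(charge = integer(0), delta = numeric(0))
  list(multi = summarize_subset(multi), uni = summarize_subset(uni),
       delta_ccs = deltas)
}

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Strip bracketed modifications from peptidoform strings
#'
#' @param x peptidoform character vector (bracket notation).
#' @return bare sequence strings.
#' @export
strip_mods <- function(x) gsub("\\[[^]]*\\]", "", x)
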