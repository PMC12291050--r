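## Physical constants (SI)
.ELEMENTARY_CHARGE <- 1.602176634e-19   # C
.BOLTZMANN <- 1.380649e-23              # J/K
.DALTON <- 1.66053906660e-27            # kg
.LOSCHMIDT <- 2.6867811e25              # m^-3, gas number density at STP

#' Mobility conversion context
#'
#' Holds the physical quantities entering the low-field Mason-Schamp
#' conversion between inverse reduced mobility (1/K0) and CCS: the
#' precursor m/z and charge, the buffer gas mass (N2 by default), and the
#' effective temperature. The reduced mass is derived from
#' \code{mz * charge} and the gas mass unless given explicitly.
#'
#' @param mz precursor mass-to-charge ratio (Th).
#' @param charge integer charge state z.
#' @param gas_mass buffer gas molecular mass in Da (default N2, 28.0134).
#' @param temperature drift gas temperature in K (default 305).
#' @param reduced_mass optional explicit reduced mass in Da.
#' @return list of class \code{mobility_context}.
#' @export
mobility_context <- function(mz, charge, gas_mass = 28.0134,
                             temperature = 305, reduced_mass = NULL) {
  stopifnot(mz > 0, charge >= 1, gas_mass > 0, temperature > 0)
  m_ion <- mz * charge
  mu <- if (is.null(reduced_mass)) m_ion * gas_mass / (m_ion + gas_mass)
        else reduced_mass
  structure(list(mz = mz, charge = as.integer(charge), gas_mass = gas_mass,
                 temperature = temperature, reduced_mass = mu),
            class = "mobility_context")
}

## Mason-Schamp prefactor: CCS [Å^2] = prefactor * inv_k0 [V s / cm^2]
mason_schamp_factor <- function(ctx) {
  mu_kg <- ctx$reduced_mass * .DALTON
  ccs_m2_per_inv_k0_si <- (3 * ctx$charge * .ELEMENTARY_CHARGE) /
    (16 * .LOSCHMIDT) *
    sqrt(2 * pi / (mu_kg * .BOLTZMANN * ctx$temperature))
  ## 1 V s/cm^2 = 1e4 V s/m^2 ; m^2 -> Å^2 is 1e20
  ccs_m2_per_inv_k0_si * 1e4 * 1e20
}

#' Convert inverse reduced ion mobility to CCS (Mason-Schamp, low field)
#'
#' CCS = (3 z e / 16 N0) sqrt(2 pi / (mu kB T)) / K0, with N0 the gas
#' number density at standard conditions and mu the ion-gas reduced mass.
#' Exact inverse of \code{\link{mobility_from_ccs}}.
#'
#' @param inv_k0 inverse reduced mobility, V s / cm^2 (positive).
#' @param ctx \code{\link{mobility_context}}.
#' @return CCS in Å^2.
#' @export
ccs_from_mobility <- function(inv_k0, ctx) {
  if (any(!is.finite(inv_k0)) || any(inv_k0 <= 0))
    stop("inv_k0 must be positive and finite")
  mason_schamp_factor(ctx) * inv_k0
}

#' @rdname ccs_from_mobility
#' @param ccs CCS in Å^2 (positive).
#' @export
mobility_from_ccs <- function(ccs, ctx) {
  if (any(!is.finite(ccs)) || any(ccs <= 0))
    stop("ccs must be positive and finite")
  ccs / mason_schamp_factor(ctx)
}

#' Construct a mobilogram object
#'
#' @param axis strictly monotone numeric grid, either 1/K0 (V s/cm^2) or
#'   CCS (Å^2).
#' @param intensity nonnegative intensity vector, same length as axis.
#' @param ion optional list with \code{peptidoform}, \code{charge}.
#' @param axis_kind "ccs" or "inv_k0".
#' @return list of class \code{mobilogram}.
#' @export
mobilogram <- function(axis, intensity, ion = NULL,
                       axis_kind = c("ccs", "inv_k0")) {
  axis_kind <- match.arg(axis_kind)
  stopifnot(length(axis) == length(intensity), length(axis) >= 3L)
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0))) stop("axis must be strictly monotone")
  if (any(intensity < 0)) stop("intensity must be nonnegative")
  if (any(d < 0)) { axis <- rev(axis); intensity <- rev(intensity) }
  structure(list(ion = ion, axis = axis, intensity = intensity,
                 axis_kind = axis_kind), class = "mobilogram")
}

#' Peak-picking parameters
#'
#' @param window moving-average smoothing window, grid points (odd; 5).
#' @param min_prominence minimum peak prominence as a fraction of the
#'   maximum smoothed intensity (0.05).
#' @param min_separation minimum apex separation in grid points (3).
#' @return list of class \code{peak_params}.
#' @export
peak_params <- function(window = 5L, min_prominence = 0.05,
                        min_separation = 3L) {
  stopifnot(window >= 1L, window %% 2L == 1L, min_prominence >= 0,
            min_separation >= 1L)
  structure(list(window = as.integer(window),
                 min_prominence = min_prominence,
                 min_separation = as.integer(min_separation)),
            class = "peak_params")
}

moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  k <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## prominence of a local maximum at index i: height minus the higher of the
## two valley floors between i and the nearest strictly higher ground (or
## the signal edge) on each side
peak_prominence <- function(y, i) {
  h <- y[i]
  left <- if (i > 1L) {
    seg <- y[(i - 1L):1L]
    higher <- which(seg > h)
    if (length(higher)) min(seg[seq_len(higher[1L])]) else min(seg)
  } else h
  right <- if (i < length(y)) {
    seg <- y[(i + 1L):length(y)]
    higher <- which(seg > h)
    if (length(higher)) min(seg[seq_len(higher[1L])]) else min(seg)
  } else h
  h - max(left, right)
}

#' Pick peaks in an extracted ion mobilogram
#'
#' The intensity trace is smoothed with a centered moving average, local
#' maxima are located, maxima closer than \code{min_separation} grid points
#' are merged (keeping the higher apex), maxima with prominence below
#' \code{min_prominence} of the smoothed maximum are dropped, and finally
#' peaks with relative height below \code{rel_threshold} are discarded.
#' Positions and relative heights are invariant to positive scaling of the
#' intensity trace.
#'
#' @param m \code{\link{mobilogram}}.
#' @param rel_threshold minimum apex intensity relative to the highest peak,
#'   in (0, 1].
#' @param params \code{\link{peak_params}}.
#' @return data.table of class-tagged peaks: \code{position} (axis units),
#'   \code{intensity} (smoothed apex height), \code{rel_height}; sorted by
#'   position. Empty for an all-zero trace.
#' @export
pick_peaks <- function(m, rel_threshold = 0.10, params = peak_params()) {
  stopifnot(inherits(m, "mobilogram"),
            rel_threshold > 0, rel_threshold <= 1)
  y <- moving_average(m$intensity, params$window)
  empty <- data.table::data.table(position = numeric(0),
                                  intensity = numeric(0),
                                  rel_height = numeric(0))
  if (max(y) <= 0) return(empty)
  n <- length(y)
  ## local maxima; plateaus keep their first index
  is_max <- c(FALSE, diff(y) > 0) & c(y[-n] >= y[-1L], FALSE)
  ## also admit a rising plateau end: y[i] > y[i-1] & y[i] >= y[i+1] covers it
  idx <- which(is_max)
  if (!length(idx)) {
    idx <- which.max(y)  # monotone trace: single apex at the crest
  }
  ## enforce minimum separation, keeping higher apexes first
  idx <- idx[order(-y[idx], idx)]
  kept <- integer(0)
  for (i in idx) {
    if (all(abs(i - kept) >= params$min_separation)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  prom <- vapply(kept, function(i) peak_prominence(y, i), numeric(1))
  kept <- kept[prom >= params$min_prominence * max(y)]
  if (!length(kept)) return(empty)
  rel <- y[kept] / max(y[kept])
  keep2 <- rel >= rel_threshold
  data.table::data.table(position = m$axis[kept[keep2]],
                         intensity = y[kept[keep2]],
                         rel_height = rel[keep2])
}

#' Fraction of mobilograms with two or more surviving peaks
#'
#' @param mobilograms list of \code{\link{mobilogram}} objects.
#' @param rel_threshold relative intensity threshold for secondary peaks.
#' @param params \code{\link{peak_params}}.
#' @return fraction in [0, 1].
#' @export
multimodal_fraction <- function(mobilograms, rel_threshold = 0.10,
                                params = peak_params()) {
  stopifnot(length(mobilograms) >= 1L)
  counts <- vapply(mobilograms, function(m)
    nrow(pick_peaks(m, rel_threshold, params)), integer(1))
  mean(counts >= 2L)
}

#' Rate of peak intensity order reversal between technical replicates
#'
#' For ions whose mobilograms are bimodal in both replicates at the working
#' threshold, peaks are matched across replicates by nearest position
#' within a relative tolerance \code{tau}; a reversal is counted when the
#' intensity rank order of the matched peak pair differs between the
#' replicates. The optional \code{secondary_cap} excludes ions whose
#' secondary peak reaches that relative height in either replicate
#' (near-equal-intensity pairs reverse by chance).
#'
#' @param rep_a,rep_b named lists of \code{\link{mobilogram}}s (matched by
#'   name).
#' @param rel_threshold working threshold for bimodality (default 0.25).
#' @param secondary_cap optional fraction; ions with secondary relative
#'   height >= cap in either replicate are excluded.
#' @param tau relative position tolerance for matching peaks (default 0.02,
#'   the conformer tolerance).
#' @param params \code{\link{peak_params}}.
#' @return list: \code{rate} (NA when no common bimodal ions),
#'   \code{n_bimodal}, \code{n_reversed}.
#' @export
order_reversal_rate <- function(rep_a, rep_b, rel_threshold = 0.25,
                                secondary_cap = NULL, tau = 0.02,
                                params = peak_params()) {
  common <- intersect(names(rep_a), names(rep_b))
  n_bi <- 0L; n_rev <- 0L
  for (key in common) {
    pa <- pick_peaks(rep_a[[key]], rel_threshold, params)
    pb <- pick_peaks(rep_b[[key]], rel_threshold, params)
    if (nrow(pa) != 2L || nrow(pb) != 2L) next
    if (!is.null(secondary_cap) &&
        (min(pa$rel_height) >= secondary_cap ||
         min(pb$rel_height) >= secondary_cap)) next
    ## match by nearest position within tau (both sorted by position)
    reldiff <- abs(pa$position - pb$position) / pmin(pa$position, pb$position)
    if (any(reldiff > tau)) next
    n_bi <- n_bi + 1L
    ord_a <- order(pa$intensity)
    ord_b <- order(pb$intensity)
    if (!identical(ord_a, ord_b)) n_rev <- n_rev + 1L
  }
  list(rate = if (n_bi > 0L) n_rev / n_bi else NA_real_,
       n_bimodal = n_bi, n_reversed = n_rev)
}

#' Annotate observed IM peaks with the nearest model prediction
#'
#' Each observed apex (in CCS space) is paired with whichever of the two
#' predicted conformer CCS values lies closer; equidistant peaks break the
#' tie toward the smaller prediction.
#'
#' @param peaks \code{\link{pick_peaks}} output with positions in Å^2.
#' @param pair numeric length-2 prediction (small, large) or a one-row
#'   prediction table with \code{ccs_small}, \code{ccs_large}.
#' @return data.table: \code{position}, \code{nearest_prediction},
#'   \code{abs_error}; empty for an empty peak set.
#' @export
nearest_prediction_annotation <- function(peaks, pair) {
  if (is.data.frame(pair)) pair <- c(pair$ccs_small[1L], pair$ccs_large[1L])
  pair <- sort(as.numeric(pair))
  if (nrow(peaks) == 0L)
    return(data.table::data.table(position = numeric(0),
                                  nearest_prediction = numeric(0),
                                  abs_error = numeric(0)))
  d1 <- abs(peaks$position - pair[1L])
  d2 <- abs(peaks$position - pair[2L])
  nearest <- ifelse(d1 <= d2, pair[1L], pair[2L])  # tie -> smaller
  data.table::data.table(position = peaks$position,
                         nearest_prediction = nearest,
                         abs_error = pmin(d1, d2))
}
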