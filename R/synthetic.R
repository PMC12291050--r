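## Approximate amino acid van der Waals volumes (Å^3), used only to give
## the planted CCS surface a realistic composition dependence.
RESIDUE_VOLUMES <- c(
  A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5, E = 138.4,
  Q = 143.8, G = 60.1, H = 153.2, I = 166.7, L = 166.7, K = 168.6,
  M = 162.9, F = 189.9, P = 112.7, S = 89.0, T = 116.1, W = 227.8,
  Y = 193.6, V = 140.0)

## Background amino acid frequencies (rough vertebrate proteome averages).
AA_FREQS <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.053, C = 0.018, E = 0.062,
  Q = 0.041, G = 0.074, H = 0.026, I = 0.045, L = 0.091, K = 0.058,
  M = 0.023, F = 0.040, P = 0.056, S = 0.081, T = 0.056, V = 0.064,
  W = 0.013, Y = 0.033)

#' Planted base CCS surface for synthetic peptide ions
#'
#' Deterministic closed form used by the cohort generator; it is NOT a
#' model of peptide physics, only a smooth, strictly positive, learnable
#' surface with realistic magnitudes and charge dependence:
#'
#' \deqn{CCS(V, z) = 0.21 V + 25 z + 2 \sqrt{V} + 65}
#'
#' where V is the summed residue volume (Å^3) of the bare sequence and z
#' the charge. Reference point: for the sequence \code{"GAGAGAGAGAGA"}
#' (V = 892.2) at z = 2, CCS = 65 + 0.21*892.2 + 50 + 2*sqrt(892.2)
#' = 362.1014... Å^2. Appending any residue strictly increases the value.
#'
#' @param peptidoform peptidoform string (modifications are ignored by the
#'   surface; they only perturb the encoding).
#' @param charge charge state.
#' @return base CCS in Å^2.
#' @export
true_ccs <- function(peptidoform, charge) {
  seqs <- strip_mods(peptidoform)
  v <- vapply(strsplit(seqs, ""), function(a)
    sum(RESIDUE_VOLUMES[a]), numeric(1))
  if (any(is.na(v))) stop("true_ccs: unknown residue in sequence")
  0.21 * v + 25 * charge + 2 * sqrt(v) + 65
}

#' Cohort generator configuration
#'
#' Defaults describe the simulated world used throughout validation:
#' 5000 peptides of length 7-30 drawn from background amino acid
#' frequencies, charges 1-4 skewed toward 2+/3+ (and upward for longer
#' peptides), a logistic multiconformer probability (about 5\% on average)
#' boosted by length, charge and proline presence, conformer CCS deltas
#' uniform between 2.5\% and a charge-dependent upper bound (5/7/8.5/10\%
#' for z = 1..4, wider for higher charges), 10 runs with per-(run, charge)
#' Gaussian CCS offsets (sd 2 Å^2), 0.3\% relative CCS noise, 30\%
#' observation dropout, and log-normal intensities.
#'
#' @param n_peptides number of distinct peptidoform-charge ions.
#' @param length_range min/max sequence length.
#' @param n_runs number of simulated LC-IM-MS/MS runs.
#' @param multiconf_base_logodds intercept of the multiconformer logit.
#' @param multiconf_len_coef,multiconf_charge_coef,multiconf_pro_coef
#'   log-odds boosts per length z-score, per charge above 2, and for
#'   proline presence.
#' @param delta_lower lower bound of the conformer delta (relative).
#' @param delta_upper_by_charge upper bounds for z = 1..4.
#' @param offset_sd sd of the planted per-(run, charge) offsets, Å^2.
#' @param ccs_noise_sd relative Gaussian CCS noise per observation.
#' @param dropout probability an ion is unobserved in a given run.
#' @param msms_type_probs probabilities of evidence Type values
#'   MULTI-MSMS / MSMS / MULTI-MATCH.
#' @param oxidation_prob probability a methionine-containing peptide
#'   carries one oxidation.
#' @param seed mandatory RNG seed.
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(n_peptides = 5000L, length_range = c(7L, 30L),
                             n_runs = 10L,
                             multiconf_base_logodds = -3.4,
                             multiconf_len_coef = 0.35,
                             multiconf_charge_coef = 0.6,
                             multiconf_pro_coef = 0.45,
                             delta_lower = 0.025,
                             delta_upper_by_charge = c(0.05, 0.07, 0.085, 0.10),
                             offset_sd = 2.0,
                             ccs_noise_sd = 0.003,
                             dropout = 0.30,
                             msms_type_probs = c(0.90, 0.05, 0.05),
                             oxidation_prob = 0.08,
                             seed = NULL) {
  if (is.null(seed)) stop("generator_config: seed is mandatory")
  stopifnot(n_peptides >= 1L, length_range[1] >= 2L,
            delta_lower > 0, all(delta_upper_by_charge > delta_lower),
            dropout >= 0, dropout < 1, ccs_noise_sd >= 0,
            abs(sum(msms_type_probs) - 1) < 1e-9)
  structure(as.list(environment()), class = "generator_config")
}

sample_peptides <- function(cfg) {
  lens <- sample(cfg$length_range[1]:cfg$length_range[2], cfg$n_peptides,
                 replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(names(AA_FREQS), L, replace = TRUE, prob = AA_FREQS),
          collapse = ""), character(1))
  ## sporadic methionine oxidation, in bracket notation
  has_m <- grepl("M", seqs)
  oxidize <- has_m & stats::runif(cfg$n_peptides) < cfg$oxidation_prob
  peptidoforms <- seqs
  peptidoforms[oxidize] <- vapply(seqs[oxidize], function(s) {
    pos <- regexpr("M", s)[[1]]
    paste0(substr(s, 1, pos), "[Oxidation]", substr(s, pos + 1, nchar(s)))
  }, character(1))
  ## charge skewed to 2+/3+, longer peptides toward higher charge
  lmid <- mean(cfg$length_range)
  charges <- vapply(lens, function(L) {
    w <- c(0.05, 0.55, 0.30, 0.10) * exp(0.06 * (L - lmid) * ((1:4) - 2))
    sample(1:4, 1L, prob = w / sum(w))
  }, integer(1))
  data.table::data.table(peptidoform = peptidoforms, charge = charges,
                         length = lens)
}

#' Generate a synthetic multi-run evidence cohort with planted ground truth
#'
#' Implements the simulated world described in
#' \code{\link{generator_config}}: each ion gets a base CCS from
#' \code{\link{true_ccs}}; multiconformer ions (logistic probability
#' boosted by length, charge and proline presence) get extra conformers at
#' successive relative deltas; every run applies its planted per-charge
#' additive offset, relative Gaussian CCS noise, observation dropout and
#' log-normal intensities; rows carry MaxQuant-style Type values. Output is
#' byte-identical for identical seeds.
#'
#' @param cfg \code{\link{generator_config}}.
#' @return list with
#'   \describe{
#'     \item{runs}{named list of per-run observation tables (internal
#'       dialect, as from \code{\link{read_evidence}}).}
#'     \item{evidence}{single data.table in MaxQuant evidence columns,
#'       suitable for \code{\link{write_evidence}}.}
#'     \item{truth}{list: \code{ions} (peptidoform, charge, multi flag,
#'       list-column \code{conformer_ccs} in the offset-free frame),
#'       \code{offsets} (run_id, charge, b_true).}
#'   }
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)

  ions <- sample_peptides(cfg)
  ions <- unique(ions, by = c("peptidoform", "charge"))
  n <- nrow(ions)

  ## planted multiconformer structure
  len_z <- (ions$length - mean(ions$length)) / stats::sd(ions$length)
  has_pro <- grepl("P", strip_mods(ions$peptidoform))
  logit <- cfg$multiconf_base_logodds + cfg$multiconf_len_coef * len_z +
    cfg$multiconf_charge_coef * (ions$charge - 2L) +
    cfg$multiconf_pro_coef * as.numeric(has_pro)
  p_multi <- 1 / (1 + exp(-logit))
  is_multi <- stats::runif(n) < p_multi
  n_conf <- ifelse(is_multi,
                   sample(2:6, n, replace = TRUE,
                          prob = c(0.90, 0.06, 0.02, 0.01, 0.01)), 1L)
  base <- true_ccs(ions$peptidoform, ions$charge)
  upper <- cfg$delta_upper_by_charge[pmin(ions$charge, 4L)]
  conformer_ccs <- lapply(seq_len(n), function(i) {
    k <- n_conf[i]
    if (k == 1L) return(base[i])
    deltas <- stats::runif(k - 1L, cfg$delta_lower, upper[i])
    base[i] * cumprod(c(1, 1 + deltas))
  })
  ## per-ion conformer intensity weights (primary first, fixed across runs)
  weights <- lapply(n_conf, function(k)
    if (k == 1L) 1 else c(1, stats::runif(k - 1L, 0.25, 0.85)))
  base_intensity <- stats::rlnorm(n, meanlog = 13, sdlog = 1)

  run_ids <- sprintf("run_%02d", seq_len(cfg$n_runs))
  offsets <- data.table::CJ(run_id = run_ids, charge = 1:4)
  offsets[, b_true := stats::rnorm(.N, 0, cfg$offset_sd)]

  rows <- vector("list", cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) {
    seen <- stats::runif(n) >= cfg$dropout
    idx <- which(seen)
    if (!length(idx)) next
    reps <- n_conf[idx]
    ii <- rep(idx, reps)
    ccs_true <- unlist(conformer_ccs[idx])
    w <- unlist(weights[idx])
    off <- offsets[run_id == run_ids[r]][match(ions$charge[ii], charge),
                                         b_true]
    m <- length(ii)
    ccs_obs <- ccs_true * (1 + stats::rnorm(m, 0, cfg$ccs_noise_sd)) + off
    intens <- base_intensity[ii] * w * stats::rlnorm(m, 0, 0.25)
    type <- sample(c("MULTI-MSMS", "MSMS", "MULTI-MATCH"), m, replace = TRUE,
                   prob = cfg$msms_type_probs)
    rows[[r]] <- data.table::data.table(
      peptidoform = ions$peptidoform[ii], charge = ions$charge[ii],
      run_id = run_ids[r], ccs = ccs_obs, intensity = intens,
      has_msms = type != "MULTI-MATCH",
      has_ms1_feature = type != "MSMS",
      type = type)
  }
  obs <- data.table::rbindlist(rows)
  runs <- split(obs[, !"type"], by = "run_id", sorted = TRUE)

  evidence <- data.table::data.table(
    `Modified sequence` = to_maxquant_modseq(obs$peptidoform),
    Charge = obs$charge, CCS = obs$ccs, Intensity = obs$intensity,
    `Raw file` = obs$run_id, Type = obs$type)

  list(runs = runs, evidence = evidence,
       truth = list(
         ions = data.table::data.table(
           peptidoform = ions$peptidoform, charge = ions$charge,
           multi = is_multi, n_conformers = n_conf,
           conformer_ccs = conformer_ccs, base_ccs = base),
         offsets = offsets))
}

#' Convert internal bracket peptidoforms to MaxQuant underscore notation
#'
#' @param x peptidoform character vector.
#' @return MaxQuant-style modified sequences, e.g.
#'   \code{"_AM(Oxidation (M))K_"}.
#' @export
to_maxquant_modseq <- function(x) {
  out <- gsub("\\[Oxidation\\]", "(Oxidation (M))", x)
  out <- gsub("\\[([^]]*)\\]", "(\\1)", out)
  paste0("_", out, "_")
}

#' Write an evidence table to TSV in MaxQuant column layout
#'
#' @param evidence data.table as produced by \code{\link{generate_cohort}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_evidence <- function(evidence, path) {
  data.table::fwrite(evidence, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Mobilogram generator configuration
#'
#' Defaults emulate extracted ion mobilograms of tryptic peptide ions on a
#' CCS grid: Gaussian peaks of width sigma = 3 Å^2 sampled every 0.5 Å^2,
#' 30\% of ions bimodal with apex separation 5-10 sigma, secondary peaks at
#' 30-90\% relative height, a 2\% additive noise floor, and replicate pairs
#' sharing peak positions with a 35\% chance that the two peaks' intensity
#' order is swapped in the second replicate.
#'
#' @param n_ions number of simulated precursors.
#' @param bimodal_fraction fraction of ions with two conformers.
#' @param sigma Gaussian peak sd, Å^2.
#' @param grid_step CCS grid spacing, Å^2.
#' @param sep_sigma_range apex separation range, in units of sigma.
#' @param secondary_height_range relative height range of the second peak.
#' @param noise_sd additive noise sd as a fraction of the main apex.
#' @param swap_prob probability the intensity order reverses in replicate B.
#' @param ccs_range range of main apex positions, Å^2.
#' @param seed mandatory RNG seed.
#' @return list of class \code{mobilogram_config}.
#' @export
mobilogram_config <- function(n_ions = 200L, bimodal_fraction = 0.30,
                              sigma = 3.0, grid_step = 0.5,
                              sep_sigma_range = c(5, 10),
                              secondary_height_range = c(0.30, 0.90),
                              noise_sd = 0.02, swap_prob = 0.35,
                              ccs_range = c(350, 800), seed = NULL) {
  if (is.null(seed)) stop("mobilogram_config: seed is mandatory")
  stopifnot(n_ions >= 1L, bimodal_fraction >= 0, bimodal_fraction <= 1,
            sigma > 0, grid_step > 0, noise_sd >= 0,
            swap_prob >= 0, swap_prob <= 1)
  structure(as.list(environment()), class = "mobilogram_config")
}

#' Generate synthetic Gaussian-mixture mobilogram replicate pairs
#'
#' @param cfg \code{\link{mobilogram_config}}.
#' @return list with named lists \code{rep_a}, \code{rep_b} of
#'   \code{\link{mobilogram}}s and a \code{truth} data.table (ion key,
#'   bimodal flag, planted centers/heights per replicate, swap flag).
#' @export
generate_mobilograms <- function(cfg) {
  stopifnot(inherits(cfg, "mobilogram_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  rep_a <- list(); rep_b <- list(); truth <- vector("list", cfg$n_ions)
  for (i in seq_len(cfg$n_ions)) {
    key <- sprintf("ion_%04d", i)
    bimodal <- stats::runif(1) < cfg$bimodal_fraction
    c1 <- stats::runif(1, cfg$ccs_range[1], cfg$ccs_range[2])
    if (bimodal) {
      sep <- stats::runif(1, cfg$sep_sigma_range[1],
                          cfg$sep_sigma_range[2]) * cfg$sigma
      centers <- c(c1, c1 + sep)
      h2 <- stats::runif(1, cfg$secondary_height_range[1],
                         cfg$secondary_height_range[2])
      heights_a <- c(1, h2)
      swapped <- stats::runif(1) < cfg$swap_prob
      heights_b <- if (swapped) rev(heights_a) else heights_a
    } else {
      centers <- c1; heights_a <- 1; heights_b <- 1; swapped <- FALSE
    }
    lo <- min(centers) - 8 * cfg$sigma
    hi <- max(centers) + 8 * cfg$sigma
    axis <- seq(lo, hi, by = cfg$grid_step)
    trace <- function(heights) {
      y <- rowSums(vapply(seq_along(centers), function(k)
        heights[k] * exp(-(axis - centers[k])^2 / (2 * cfg$sigma^2)),
        numeric(length(axis))))
      y <- y + stats::rnorm(length(axis), 0, cfg$noise_sd * max(heights))
      pmax(y, 0)
    }
    rep_a[[key]] <- mobilogram(axis, trace(heights_a), ion = list(key = key))
    rep_b[[key]] <- mobilogram(axis, trace(heights_b), ion = list(key = key))
    truth[[i]] <- data.table::as.data.table(list(
      key = key, bimodal = bimodal,
      centers = list(centers), heights_a = list(heights_a),
      heights_b = list(heights_b), swapped = swapped))
  }
  list(rep_a = rep_a, rep_b = rep_b, truth = data.table::rbindlist(truth))
}
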