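test_that("Mason-Schamp conversion round-trips and scales as expected", {
  ctx <- mobility_context(mz = 500, charge = 2L)
  for (x in c(300, 600, 1000)) {
    expect_equal(ccs_from_mobility(mobility_from_ccs(x, ctx), ctx), x,
                 tolerance = 1e-9)
  }
  # CCS strictly increases with 1/K0
  grid <- seq(0.6, 1.8, by = 0.1)
  expect_true(all(diff(ccs_from_mobility(grid, ctx)) > 0))
  # doubling z at fixed 1/K0 and reduced mass doubles the CCS
  ctx1 <- mobility_context(mz = 500, charge = 1L, reduced_mass = 27)
  ctx2 <- mobility_context(mz = 250, charge = 2L, reduced_mass = 27)
  expect_equal(ccs_from_mobility(1.2, ctx2), 2 * ccs_from_mobility(1.2, ctx1))
  # a tryptic 2+ peptide at 1/K0 around 1 V s/cm^2 lands in the
  # physically plausible few-hundred Å^2 range
  ccs <- ccs_from_mobility(1.0, mobility_context(mz = 600, charge = 2L))
  expect_gt(ccs, 300); expect_lt(ccs, 700)
  expect_error(ccs_from_mobility(-1, ctx), "positive")
  expect_error(mobility_from_ccs(0, ctx), "positive")
})

gaussian_xim <- function(centers, heights, sigma = 3, step = 0.5,
                         noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  axis <- seq(min(centers) - 10 * sigma, max(centers) + 10 * sigma,
              by = step)
  y <- rowSums(vapply(seq_along(centers), function(k)
    heights[k] * exp(-(axis - centers[k])^2 / (2 * sigma^2)),
    numeric(length(axis))))
  if (noise > 0) y <- pmax(y + rnorm(length(axis), 0, noise), 0)
  mobilogram(axis, y)
}

test_that("pick_peaks finds planted Gaussian apexes", {
  m1 <- gaussian_xim(500, 1)
  p1 <- pick_peaks(m1, 0.10)
  expect_equal(nrow(p1), 1L)
  expect_lt(abs(p1$position - 500), 0.5 + 1e-9)  # within one grid step
  # two equal Gaussians 6 sigma apart
  m2 <- gaussian_xim(c(500, 518), c(1, 1))
  p2 <- pick_peaks(m2, 0.10)
  expect_equal(nrow(p2), 2L)
  expect_lt(max(abs(sort(p2$position) - c(500, 518))), 0.5 + 1e-9)
  # a 5% secondary peak disappears at the 10% threshold
  m3 <- gaussian_xim(c(500, 530), c(1, 0.05))
  expect_equal(nrow(pick_peaks(m3, 0.10)), 1L)
  # ... and survives a permissive threshold with loose prominence
  p3 <- pick_peaks(m3, 0.01, peak_params(min_prominence = 0.01))
  expect_equal(nrow(p3), 2L)
  # all-zero trace: empty peak set
  expect_equal(nrow(pick_peaks(mobilogram(1:10, rep(0, 10)), 0.1)), 0L)
})

test_that("pick_peaks is scale invariant and one peak has rel_height 1", {
  m <- gaussian_xim(c(450, 480), c(1, 0.6), noise = 0.01, seed = 2)
  p <- pick_peaks(m, 0.10)
  m10 <- mobilogram(m$axis, m$intensity * 137.5)
  p10 <- pick_peaks(m10, 0.10)
  expect_equal(p$position, p10$position)
  expect_equal(p$rel_height, p10$rel_height, tolerance = 1e-12)
  expect_equal(sum(p$rel_height == 1), 1L)
  expect_true(all(p$rel_height > 0 & p$rel_height <= 1))
})

test_that("peak count is non-increasing in threshold and prominence", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(1:3, 1)
    centers <- 450 + cumsum(c(0, runif(k - 1, 15, 40)))
    heights <- c(1, runif(k - 1, 0.2, 0.9))
    m <- gaussian_xim(centers, heights, noise = 0.02, seed = 100 + i)
    counts <- vapply(c(0.10, 0.25, 0.75), function(t)
      nrow(pick_peaks(m, t)), integer(1))
    expect_true(all(diff(counts) <= 0))
    proms <- vapply(c(0.02, 0.05, 0.2), function(pr)
      nrow(pick_peaks(m, 0.05, peak_params(min_prominence = pr))),
      integer(1))
    expect_true(all(diff(proms) <= 0))
  }
})

test_that("multimodal_fraction recovers the planted bimodal rate", {
  cfg <- mobilogram_config(n_ions = 300L, bimodal_fraction = 0.30,
                           swap_prob = 0, noise_sd = 0.01, seed = 17L)
  sim <- generate_mobilograms(cfg)
  f <- multimodal_fraction(sim$rep_a, 0.10)
  expect_lt(abs(f - 0.30), 3 * sqrt(0.3 * 0.7 / 300))
  # all unimodal
  cfg0 <- mobilogram_config(n_ions = 50L, bimodal_fraction = 0,
                            seed = 18L)
  expect_equal(multimodal_fraction(generate_mobilograms(cfg0)$rep_a, 0.10), 0)
  # non-increasing over the threshold sweep
  fr <- vapply(c(0.10, 0.25, 0.75), function(t)
    multimodal_fraction(sim$rep_a, t), numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("order_reversal_rate measures planted intensity swaps", {
  # identical replicates: rate 0
  cfg0 <- mobilogram_config(n_ions = 80L, bimodal_fraction = 0.5,
                            swap_prob = 0, noise_sd = 0, seed = 23L)
  sim0 <- generate_mobilograms(cfg0)
  r0 <- order_reversal_rate(sim0$rep_a, sim0$rep_a)
  expect_equal(r0$rate, 0)
  expect_gt(r0$n_bimodal, 10L)
  # constructed swap: rate 1
  a <- list(x = gaussian_xim(c(500, 520), c(1, 0.6)))
  b <- list(x = gaussian_xim(c(500, 520), c(0.6, 1)))
  expect_equal(order_reversal_rate(a, b)$rate, 1)
  # planted 35% swaps recovered within binomial error
  cfg <- mobilogram_config(n_ions = 400L, bimodal_fraction = 0.5,
                           swap_prob = 0.35,
                           secondary_height_range = c(0.35, 0.90),
                           noise_sd = 0.01, seed = 29L)
  sim <- generate_mobilograms(cfg)
  rv <- order_reversal_rate(sim$rep_a, sim$rep_b, rel_threshold = 0.25)
  expect_gt(rv$n_bimodal, 100L)
  expect_lt(abs(rv$rate - 0.35), 3 * sqrt(0.35 * 0.65 / rv$n_bimodal) + 0.02)
  # no common bimodal ions: undefined, reported as NA
  una <- list(x = gaussian_xim(500, 1))
  expect_true(is.na(order_reversal_rate(una, una)$rate))
  # capping near-equal secondary peaks excludes likely chance reversals
  rv_cap <- order_reversal_rate(sim$rep_a, sim$rep_b, rel_threshold = 0.25,
                                secondary_cap = 0.90)
  expect_lte(rv_cap$n_bimodal, rv$n_bimodal)
})

test_that("nearest_prediction_annotation assigns the closer prediction", {
  peaks <- data.table::data.table(position = c(577, 605),
                                  intensity = c(1, 0.8),
                                  rel_height = c(1, 0.8))
  ann <- nearest_prediction_annotation(peaks, c(575, 606))
  expect_equal(ann$nearest_prediction, c(575, 606))
  expect_equal(ann$abs_error, c(2, 1))
  # single peak picks the min-distance prediction
  one <- peaks[1]
  ann1 <- nearest_prediction_annotation(one, c(570, 580))
  expect_equal(ann1$nearest_prediction, 580)
  # equidistant ties break toward the smaller prediction
  tie <- data.table::data.table(position = 575, intensity = 1,
                                rel_height = 1)
  annt <- nearest_prediction_annotation(tie, c(570, 580))
  expect_equal(annt$nearest_prediction, 570)
  # empty peak set gives empty annotation
  expect_equal(nrow(nearest_prediction_annotation(peaks[0], c(1, 2))), 0L)
})
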