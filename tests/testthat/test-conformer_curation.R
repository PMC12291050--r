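test_that("relative_difference follows the min-denominator convention", {
  expect_equal(relative_difference(500, 500), 0)
  expect_equal(relative_difference(500, 512), 0.024)
  expect_equal(relative_difference(512, 500), 0.024)  # symmetric
  # the two IM features of the motivating example are distinct at tau 0.02
  expect_equal(relative_difference(577, 605), 28 / 577, tolerance = 1e-12)
  expect_gt(relative_difference(577, 605), 0.02)
  expect_error(relative_difference(-1, 500), "positive")
  expect_equal(relative_difference(500, 512, denom = "mean"), 12 / 506)
})

test_that("split_within_run reproduces the greedy running-mean rule", {
  cfg <- curation_config(within_run_rep = "mean")
  expect_equal(split_within_run(500, cfg = cfg)$ccs, 500)
  # 503 joins 500 (0.006); 515 vs mean 501.5 is 0.0269 -> splits
  out <- split_within_run(c(500, 503, 515), cfg = cfg)
  expect_equal(out$ccs, c(501.5, 515))
  expect_equal(out$n_members, c(2L, 1L))
  # 508 joins 500 (0.016, mean 504); 516 vs 504 is 0.0238 -> splits
  out2 <- split_within_run(c(500, 508, 516), cfg = cfg)
  expect_equal(out2$ccs, c(504, 516))
  # intensity-weighted representative
  cfgw <- curation_config()
  outw <- split_within_run(c(500, 504), intensity = c(3e6, 1e6), cfg = cfgw)
  expect_equal(outw$ccs, 501)
})

test_that("match_across_runs pairs candidates within tau across runs", {
  cfg <- curation_config()
  one <- match_across_runs(
    data.table::data.table(run_id = "A", ccs = 500), cfg)
  expect_equal(nrow(one), 1L)
  expect_equal(one$run_support, 1L)

  two <- match_across_runs(data.table::data.table(
    run_id = c("A", "A", "B", "B"), ccs = c(500, 520, 501, 519)), cfg)
  expect_equal(two$mean_ccs, c(500.5, 519.5))
  expect_equal(two$run_support, c(2L, 2L))

  lop <- match_across_runs(data.table::data.table(
    run_id = c("A", "A", "B"), ccs = c(500, 520, 500)), cfg)
  expect_equal(lop$run_support, c(2L, 1L))
})

test_that("classify_ion applies recurrence, uni and charge rules", {
  cfg <- curation_config()
  ion <- list(peptidoform = "AAK", charge = 2L)
  mk <- function(run_ccs) match_across_runs(run_ccs, cfg)
  # two recurrent clusters -> multi with sorted means
  cl <- mk(data.table::data.table(
    run_id = c("A", "B", "C", "A", "B"), ccs = c(500, 500, 500, 521, 521)))
  rec <- classify_ion(cl, ion, cfg)
  expect_equal(rec$label, "multi")
  expect_equal(rec$ccs_values[[1]], c(500, 521))
  expect_equal(rec$supports[[1]], c(3L, 2L))
  # one cluster, all runs within tau -> uni
  clu <- mk(data.table::data.table(run_id = LETTERS[1:5],
                                   ccs = c(500, 501, 502, 500.5, 501.5)))
  recu <- classify_ion(clu, ion, cfg)
  expect_equal(recu$label, "uni")
  # supports {4, 1}: non-recurrent extra cluster -> neither dataset
  cla <- mk(data.table::data.table(
    run_id = c("A", "B", "C", "D", "A"), ccs = c(500, 500, 500, 500, 530)))
  expect_null(classify_ion(cla, ion, cfg))
  # charge above the cap is discarded before anything else
  expect_null(classify_ion(clu, list(peptidoform = "AAK", charge = 5L), cfg))
})

test_that("curate recovers planted conformer structure", {
  cfg <- generator_config(n_peptides = 700L, seed = 21L)
  sim <- generate_cohort(cfg)
  cur <- curate(align_all(filter_identified(sim$runs)))
  truth <- sim$truth$ions
  merged <- merge(truth,
                  data.table::rbindlist(list(cur$multi, cur$uni)),
                  by = c("peptidoform", "charge"), all.x = TRUE)
  called_multi <- !is.na(merged$label) & merged$label == "multi"
  sens <- mean(called_multi[merged$multi])
  spec <- mean(!called_multi[!merged$multi])
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
  # no ion in both outputs
  both <- merge(cur$multi[, .(peptidoform, charge)],
                cur$uni[, .(peptidoform, charge)],
                by = c("peptidoform", "charge"))
  expect_equal(nrow(both), 0L)
  # multi records: strictly ascending values with adjacent gaps > tau
  for (v in cur$multi$ccs_values) {
    expect_true(all(diff(v) > 0))
    expect_true(all(relative_difference(v[-length(v)], v[-1]) > 0.02))
  }
})

test_that("curate handles degenerate inputs and many-conformer ions", {
  # single-run input: everything uni with support 1
  obs <- make_obs(c("AAK", "CCK"), 2L, "r1", c(400, 500), intensity = 1e6)
  cur <- curate(obs)
  expect_equal(nrow(cur$uni), 2L)
  expect_equal(cur$uni$supports[[1]], 1L)
  expect_equal(nrow(cur$multi), 0L)

  # planted 6-conformer ion is recovered with 6 CCS values
  base <- 450
  vals <- base * cumprod(c(1, rep(1.05, 5)))
  obs6 <- data.table::rbindlist(lapply(c("r1", "r2", "r3"), function(r)
    make_obs(rep("WWWK", 6), 2L, r, vals, intensity = 1e6)))
  cur6 <- curate(obs6)
  expect_equal(nrow(cur6$multi), 1L)
  expect_length(cur6$multi$ccs_values[[1]], 6L)
})

test_that("greedy clustering equals the exhaustive oracle on small cases", {
  set.seed(42)
  n_checked <- 0L
  for (i in 1:150) {
    inst <- random_cluster_instance(n_obs = sample(2:6, 1L))
    x <- sort(inst$x)
    greedy <- labels_to_partition(conformerCCS:::greedy_cluster_1d(x, 0.02))
    oracle <- oracle_cluster(x, 0.02)
    if (is.null(oracle)) next  # no feasible partition at this tau
    n_checked <- n_checked + 1L
    expect_identical(greedy, oracle)
  }
  expect_gt(n_checked, 100L)
})

test_that("cross-run greedy matching equals the run-constrained oracle", {
  set.seed(43)
  cfg <- curation_config()
  for (i in 1:120) {
    n_runs <- sample(2:4, 1L)
    inst <- random_cluster_instance(n_obs = sample(3:6, 1L),
                                    n_runs = n_runs)
    cand <- data.table::data.table(run_id = inst$run_ids, ccs = inst$x)
    got <- match_across_runs(cand, cfg)
    got_part <- lapply(got$members, function(m) sort(m$ccs))
    o <- order(inst$x, inst$run_ids)
    oracle <- oracle_cluster(inst$x[o], 0.02, run_ids = inst$run_ids[o])
    if (is.null(oracle)) next
    oracle_part <- lapply(oracle, function(idx) sort(inst$x[o][idx]))
    expect_identical(got_part, oracle_part)
  }
})

test_that("shrinking tau never decreases the within-run cluster count", {
  set.seed(7)
  for (i in 1:40) {
    x <- sort(runif(sample(2:8, 1L), 400, 700))
    taus <- c(0.05, 0.02, 0.01, 0.005)
    counts <- vapply(taus, function(tau)
      max(conformerCCS:::greedy_cluster_1d(x, tau)), numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("characterize reports the planted physicochemical contrasts", {
  expect_equal(sum(strsplit("PAPTIDE", "")[[1]] == "P") / 7, 2 / 7)
  rec <- data.table::data.table(
    peptidoform = "PAPTIDE", charge = 2L,
    ccs_values = list(c(500, 512)), supports = list(c(2L, 2L)),
    label = "multi")
  uni <- data.table::data.table(
    peptidoform = c("AAAAK", "CCCCK"), charge = c(2L, 2L),
    ccs_values = list(400, 500), supports = list(3L, 3L),
    label = "uni")
  ch <- characterize(rec, uni)
  expect_equal(ch$multi$proline_frequency, 2 / 7)
  expect_equal(ch$delta_ccs$delta, 12)
  expect_equal(ch$uni$proline_presence, 0)

  # synthetic cohort: multis planted longer, higher-charged, proline-richer
  cfg <- generator_config(n_peptides = 2500L, n_runs = 6L, seed = 31L)
  sim <- generate_cohort(cfg)
  cur <- curate(align_all(filter_identified(sim$runs)))
  chs <- characterize(cur$multi, cur$uni)
  expect_gt(chs$multi$mean_length, chs$uni$mean_length)
  expect_gt(chs$multi$mean_charge, chs$uni$mean_charge)
  expect_gt(chs$multi$proline_presence, chs$uni$proline_presence)
})
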