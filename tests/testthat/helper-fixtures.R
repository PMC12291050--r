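# shared fixtures: tiny observation tables built in code

make_obs <- function(peptidoform, charge, run_id, ccs,
                     intensity = NA_real_, has_msms = TRUE,
                     has_ms1_feature = TRUE) {
  data.table::data.table(peptidoform = peptidoform,
                         charge = as.integer(charge),
                         run_id = run_id, ccs = ccs,
                         intensity = intensity,
                         has_msms = has_msms,
                         has_ms1_feature = has_ms1_feature)
}

# a set of runs sharing `n_shared` ions, with optional per-charge shifts
# applied to each run and optional relative Gaussian noise
make_shifted_runs <- function(n_shared = 150L, charges = c(2L, 3L),
                              shifts = list(), noise_sd = 0,
                              seed = 1L) {
  set.seed(seed)
  seqs <- replicate(n_shared, paste(sample(LETTERS[LETTERS %in%
    c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
      "Q", "R", "S", "T", "V", "W", "Y")], 10, replace = TRUE),
    collapse = ""))
  z <- charges[sample.int(length(charges), n_shared, replace = TRUE)]
  base <- true_ccs(seqs, z)
  runs <- list()
  run_names <- names(shifts)
  if (is.null(run_names)) run_names <- paste0("R", seq_along(shifts))
  for (i in seq_along(shifts)) {
    sh <- shifts[[i]]  # named numeric: charge -> additive shift
    off <- sh[as.character(z)]
    off[is.na(off)] <- 0
    ccs <- base * (1 + stats::rnorm(n_shared, 0, noise_sd)) + off
    runs[[run_names[i]]] <- make_obs(seqs, z, run_names[i], ccs,
                                     intensity = stats::runif(n_shared,
                                                              1e5, 1e7))
  }
  runs
}

# write a minimal MaxQuant-style evidence TSV, returns the path
write_tiny_evidence <- function(dir = tempdir(),
                                raw_files = c("a", "a", "b"),
                                type = rep("MULTI-MSMS", length(raw_files)),
                                ccs = rep(500, length(raw_files))) {
  path <- tempfile("evid", tmpdir = dir, fileext = ".tsv")
  dt <- data.table::data.table(
    `Modified sequence` = rep("_PEPTIDEK_", length(raw_files)),
    Charge = 2L, CCS = ccs, Intensity = 1e6,
    `Raw file` = raw_files, Type = type)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  path
}
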