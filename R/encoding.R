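## Atomic composition of amino acid residues (residue = amino acid - H2O),
## channels C, H, N, O, S, P. Standard proteinogenic residue formulas.
RESIDUE_ATOMS <- local({
  m <- rbind(
    A = c(3,  5, 1, 1, 0, 0),
    R = c(6, 12, 4, 1, 0, 0),
    N = c(4,  6, 2, 2, 0, 0),
    D = c(4,  5, 1, 3, 0, 0),
    C = c(3,  5, 1, 1, 1, 0),
    E = c(5,  7, 1, 3, 0, 0),
    Q = c(5,  8, 2, 2, 0, 0),
    G = c(2,  3, 1, 1, 0, 0),
    H = c(6,  7, 3, 1, 0, 0),
    I = c(6, 11, 1, 1, 0, 0),
    L = c(6, 11, 1, 1, 0, 0),
    K = c(6, 12, 2, 1, 0, 0),
    M = c(5,  9, 1, 1, 1, 0),
    F = c(9,  9, 1, 1, 0, 0),
    P = c(5,  7, 1, 1, 0, 0),
    S = c(3,  5, 1, 2, 0, 0),
    T = c(4,  7, 1, 2, 0, 0),
    W = c(11, 10, 2, 1, 0, 0),
    Y = c(9,  9, 1, 2, 0, 0),
    V = c(5,  9, 1, 1, 0, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S", "P")
  m
})

## Elemental deltas of supported modifications (same channels).
MOD_ATOMS <- rbind(
  Oxidation       = c(0, 0, 0, 1, 0, 0),
  Carbamidomethyl = c(2, 3, 1, 1, 0, 0),
  Acetyl          = c(2, 2, 0, 1, 0, 0),
  Phospho         = c(0, 1, 0, 3, 0, 1),
  None            = c(0, 0, 0, 0, 0, 0)  # zero-mass tag, a no-op
)
colnames(MOD_ATOMS) <- colnames(RESIDUE_ATOMS)

#' Tokenize a peptidoform string into residues and attached modifications
#'
#' @param peptidoform bracket-notation peptidoform, e.g.
#'   \code{"AM[Oxidation]K"}. A leading \code{"[Mod]-"} or \code{"[Mod]"}
#'   before the first residue attaches to position 1 (N-terminal tag).
#' @return list with character vectors \code{residues} and \code{mods}
#'   (one slot per residue, \code{NA} when unmodified).
#' @export
tokenize_peptidoform <- function(peptidoform) {
  stopifnot(is.character(peptidoform), length(peptidoform) == 1L,
            nzchar(peptidoform))
  s <- gsub("\\]-", "]", peptidoform)
  toks <- regmatches(s, gregexpr("\\[[^]]*\\]|.", s))[[1]]
  residues <- character(0); mods <- character(0); pending <- NA_character_
  for (t in toks) {
    if (startsWith(t, "[")) {
      mod <- substr(t, 2L, nchar(t) - 1L)
      if (length(residues) == 0L) pending <- mod
      else {
        if (!is.na(mods[length(mods)]))
          stop("multiple modifications on one residue in: ", peptidoform)
        mods[length(mods)] <- mod
      }
    } else {
      residues <- c(residues, t)
      mods <- c(mods, NA_character_)
      if (!is.na(pending)) { mods[1L] <- pending; pending <- NA_character_ }
    }
  }
  if (length(residues) == 0L) stop("no residues in peptidoform: ", peptidoform)
  list(residues = residues, mods = mods)
}

#' Encode a peptide ion at atomic-composition level
#'
#' Builds a positional composition matrix (one row per sequence position,
#' channels C, H, N, O, S, P) from standard residue formulas with
#' modification deltas added at the modified position, plus a global
#' feature vector (total composition including the terminal H2O, sequence
#' length, charge one-hot over 1..6). Padding rows beyond the sequence
#' length are all-zero. The column sums of the positional matrix equal the
#' molecular composition minus the terminal water (H2O is accounted only in
#' the global totals).
#'
#' @param peptidoform peptidoform string in bracket notation.
#' @param charge integer charge state in 1..6.
#' @param max_len padded sequence length (default 60).
#' @return list of class \code{encoded_peptide} with
#'   \code{positional_composition} (\code{max_len x 6} matrix) and
#'   \code{global_features} (named numeric vector).
#' @export
encode_peptide <- function(peptidoform, charge, max_len = 60L) {
  tok <- tokenize_peptidoform(peptidoform)
  n <- length(tok$residues)
  if (n > max_len) stop("sequence length ", n, " exceeds max_len ", max_len)
  unknown <- setdiff(tok$residues, rownames(RESIDUE_ATOMS))
  if (length(unknown))
    stop("unknown residue token(s): ", paste(unknown, collapse = ", "))
  pos <- matrix(0, nrow = max_len, ncol = ncol(RESIDUE_ATOMS),
                dimnames = list(NULL, colnames(RESIDUE_ATOMS)))
  pos[seq_len(n), ] <- RESIDUE_ATOMS[tok$residues, , drop = FALSE]
  modded <- which(!is.na(tok$mods))
  for (i in modded) {
    mod <- tok$mods[i]
    if (!mod %in% rownames(MOD_ATOMS))
      stop("unknown modification token: ", mod)
    pos[i, ] <- pos[i, ] + MOD_ATOMS[mod, ]
  }
  z <- as.integer(charge)
  if (is.na(z) || z < 1L || z > 6L) stop("charge must be in 1..6")
  total <- colSums(pos) + c(C = 0, H = 2, N = 0, O = 1, S = 0, P = 0) # + H2O
  glob <- c(total, length = n,
            stats::setNames(as.numeric(seq_len(6L) == z),
                            paste0("z", 1:6)))
  structure(list(positional_composition = pos, global_features = glob),
            class = "encoded_peptide")
}

#' Feature matrix for the CCS regression model
#'
#' Flattens encodings into the model input: total atomic composition (6),
#' sequence length, charge one-hot (6), and residue counts over the 20
#' proteinogenic amino acids. The planted synthetic CCS surface and real
#' peptide CCS are both smooth in these coordinates.
#'
#' @param ions data.frame with columns \code{peptidoform}, \code{charge}.
#' @param max_len padding length passed to \code{\link{encode_peptide}}.
#' @return numeric matrix, one row per ion.
#' @export
featurize_ions <- function(ions, max_len = 60L) {
  ions <- data.table::as.data.table(ions)
  n <- nrow(ions)
  feat <- matrix(0, nrow = n, ncol = 6L + 1L + 6L + 20L)
  colnames(feat) <- c(colnames(RESIDUE_ATOMS), "length", paste0("z", 1:6),
                      AA_LETTERS)
  for (i in seq_len(n)) {
    enc <- encode_peptide(ions$peptidoform[i], ions$charge[i], max_len)
    seqs <- strip_mods(ions$peptidoform[i])
    counts <- table(factor(strsplit(seqs, "")[[1]], levels = AA_LETTERS))
    feat[i, ] <- c(enc$global_features, as.numeric(counts))
  }
  feat
}
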