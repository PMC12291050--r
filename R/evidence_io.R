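#' Default column mapping for MaxQuant-style evidence tables
#'
#' Maps internal field names to the column headers expected in the input
#' TSV. Override individual entries to ingest other dialects.
#'
#' @return Named character vector (internal name -> column header).
#' @export
evidence_columns <- function() {
  c(peptidoform = "Modified sequence",
    charge      = "Charge",
    ccs         = "CCS",
    intensity   = "Intensity",
    run_id      = "Raw file",
    type        = "Type")
}

#' Default identification-type flag mapping
#'
#' MaxQuant's evidence \code{Type} column encodes how a feature was
#' identified. \code{"MULTI-MSMS"} denotes an MS/MS-identified distinct MS1
#' feature and is the only default type passing the identification filter;
#' \code{"MSMS"} lacks an MS1 feature and \code{"MULTI-MATCH"} lacks an
#' MS/MS spectrum (match-between-runs).
#'
#' @return data.frame with columns \code{type}, \code{has_msms},
#'   \code{has_ms1_feature}.
#' @export
evidence_type_map <- function() {
  data.frame(
    type            = c("MULTI-MSMS", "MSMS", "MULTI-MATCH", "MULTI-SECPEP"),
    has_msms        = c(TRUE, TRUE, FALSE, TRUE),
    has_ms1_feature = c(TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Normalize a modified peptide sequence to the internal peptidoform string
#'
#' Accepts MaxQuant underscore-delimited notation with parenthesized
#' modifications (e.g. \code{"_AM(Oxidation (M))K_"} or \code{"_AM(ox)K_"})
#' and plain ProForma-like bracket notation (\code{"AM[Oxidation]K"}).
#' Output uses bracket notation with canonical modification names.
#'
#' @param x character vector of modified sequences.
#' @return character vector of normalized peptidoforms.
#' @export
parse_modseq <- function(x) {
  stopifnot(is.character(x))
  out <- gsub("^_|_$", "", x)
  ## MaxQuant short codes and verbose labels -> canonical names.
  ## Replace outer-level parenthesized groups (possibly containing one
  ## nested level, as in "(Oxidation (M))") with [canonical].
  canon <- c(ox = "Oxidation", ac = "Acetyl", ph = "Phospho",
             cm = "Carbamidomethyl", ca = "Carbamidomethyl")
  rewrite_one <- function(s) {
    if (!grepl("(", s, fixed = TRUE)) return(s)
    chars <- strsplit(s, "")[[1]]
    res <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      ch <- chars[i]
      if (ch == "(") {
        depth <- 1L; j <- i
        while (depth > 0L && j < length(chars)) {
          j <- j + 1L
          if (chars[j] == "(") depth <- depth + 1L
          if (chars[j] == ")") depth <- depth - 1L
        }
        if (depth > 0L) stop("unbalanced parentheses in modified sequence: ", s)
        tag <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
        name <- if (tolower(tag) %in% names(canon)) {
          canon[[tolower(tag)]]
        } else {
          ## verbose MaxQuant label: first word is the modification name
          sub("\\s*\\(.*$", "", tag)
        }
        res <- c(res, "[", name, "]")
        i <- j + 1L
      } else {
        res <- c(res, ch)
        i <- i + 1L
      }
    }
    paste(res, collapse = "")
  }
  needs <- grepl("(", out, fixed = TRUE)
  out[needs] <- vapply(out[needs], rewrite_one, character(1))
  out
}

#' Read a MaxQuant-evidence-style TSV into per-run observation tables
#'
#' Rows with missing, non-finite or non-positive CCS are dropped with a
#' message reporting the count. The \code{Type} column, when present, is
#' translated into \code{has_msms}/\code{has_ms1_feature} flags via
#' \code{type_map}; absent a \code{Type} column both flags default to TRUE.
#'
#' @param path path to a tab-separated evidence file.
#' @param column_map named character vector as from
#'   \code{\link{evidence_columns}}; the \code{type} entry is optional in the
#'   file, all others are mandatory.
#' @param type_map data.frame as from \code{\link{evidence_type_map}};
#'   types absent from the map fail both flags.
#' @param drop_prefix optional character vector; observations whose
#'   peptidoform starts with any of these prefixes (e.g. decoy or
#'   contaminant tags) are dropped before grouping.
#' @return named list of \code{data.table}s, one per distinct run id, each
#'   with columns \code{peptidoform}, \code{charge}, \code{run_id},
#'   \code{ccs}, \code{intensity}, \code{has_msms}, \code{has_ms1_feature}.
#' @export
read_evidence <- function(path, column_map = evidence_columns(),
                          type_map = evidence_type_map(),
                          drop_prefix = NULL) {
  if (!file.exists(path)) stop("evidence file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = column_map[["run_id"]]),
                          showProgress = FALSE)
  if (nrow(dt) == 0L) {
    warning("empty evidence file: ", path)
    return(structure(list(), names = character(0)))
  }
  mandatory <- c("peptidoform", "charge", "ccs", "intensity", "run_id")
  for (field in mandatory) {
    col <- column_map[[field]]
    if (!col %in% names(dt)) {
      stop("evidence format error: missing mandatory column '", col, "'")
    }
  }
  obs <- data.table::data.table(
    peptidoform = parse_modseq(as.character(dt[[column_map[["peptidoform"]]]])),
    charge      = as.integer(dt[[column_map[["charge"]]]]),
    run_id      = as.character(dt[[column_map[["run_id"]]]]),
    ccs         = as.numeric(dt[[column_map[["ccs"]]]]),
    intensity   = as.numeric(dt[[column_map[["intensity"]]]])
  )
  type_col <- column_map[["type"]]
  if (!is.na(type_col) && type_col %in% names(dt)) {
    idx <- match(as.character(dt[[type_col]]), type_map$type)
    obs[, has_msms := ifelse(is.na(idx), FALSE, type_map$has_msms[idx])]
    obs[, has_ms1_feature := ifelse(is.na(idx), FALSE,
                                    type_map$has_ms1_feature[idx])]
  } else {
    obs[, has_msms := TRUE]
    obs[, has_ms1_feature := TRUE]
  }
  if (!is.null(drop_prefix) && length(drop_prefix)) {
    pat <- paste0("^(", paste(gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1",
                                   drop_prefix), collapse = "|"), ")")
    obs <- obs[!grepl(pat, peptidoform)]
  }
  bad <- !is.finite(obs$ccs) | obs$ccs <= 0
  if (any(bad)) {
    message("read_evidence: dropped ", sum(bad),
            " row(s) with missing or non-positive CCS")
    obs <- obs[!bad]
  }
  if (any(obs$charge < 1L | obs$charge > 6L, na.rm = TRUE)) {
    n <- sum(obs$charge < 1L | obs$charge > 6L, na.rm = TRUE)
    message("read_evidence: dropped ", n, " row(s) with charge outside 1-6")
    obs <- obs[charge >= 1L & charge <= 6L]
  }
  split_runs(obs)
}

## Partition one observation table into a named list of per-run tables.
split_runs <- function(obs) {
  stopifnot(is.data.frame(obs))
  obs <- data.table::as.data.table(obs)
  runs <- split(obs, by = "run_id", sorted = TRUE)
  runs
}

#' Keep only observations identified by MS/MS with a distinct MS1 feature
#'
#' Applies the identification-quality criterion: an observation survives iff
#' \code{has_msms & has_ms1_feature}. Run tables left empty are removed.
#' Idempotent; never increases observation counts.
#'
#' @param runs named list of per-run observation tables
#'   (see \code{\link{read_evidence}}).
#' @return filtered named list of per-run tables.
#' @export
filter_identified <- function(runs) {
  stopifnot(is.list(runs))
  out <- lapply(runs, function(r) r[has_msms & has_ms1_feature])
  out[vapply(out, nrow, integer(1)) > 0L]
}

#' Write curated uni/multiconformer records to TSV
#'
#' Emits a wide table with columns \code{peptidoform}, \code{charge},
#' \code{n_conformers}, \code{ccs_1..ccs_k}, \code{support_1..support_k},
#' \code{label}, sorted by (peptidoform, charge). CCS lists are ascending
#' by construction. The format round-trips through
#' \code{\link{read_curated}} losslessly.
#'
#' @param records curated record table with list-columns \code{ccs_values}
#'   and \code{supports} (see \code{\link{curate}}).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_curated <- function(records, path) {
  stopifnot(is.data.frame(records))
  records <- data.table::as.data.table(records)
  kmax <- if (nrow(records)) max(vapply(records$ccs_values, length,
                                        integer(1))) else 1L
  wide <- data.table::data.table(
    peptidoform = records$peptidoform,
    charge = records$charge,
    n_conformers = vapply(records$ccs_values, length, integer(1))
  )
  for (k in seq_len(kmax)) {
    wide[[paste0("ccs_", k)]] <- vapply(records$ccs_values, function(v)
      if (length(v) >= k) v[k] else NA_real_, numeric(1))
    wide[[paste0("support_", k)]] <- vapply(records$supports, function(v)
      if (length(v) >= k) as.integer(v[k]) else NA_integer_, integer(1))
  }
  wide$label <- if (nrow(records)) records$label else character(0)
  data.table::setorder(wide, peptidoform, charge)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write curated file: ", path))
  close(con)
  data.table::fwrite(wide, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read a curated dataset written by \code{\link{write_curated}}
#'
#' @param path curated TSV path.
#' @return data.table with columns \code{peptidoform}, \code{charge},
#'   list-columns \code{ccs_values} and \code{supports}, and \code{label}.
#' @export
read_curated <- function(path) {
  if (!file.exists(path)) stop("curated file not found: ", path)
  wide <- data.table::fread(path, sep = "\t", header = TRUE,
                            showProgress = FALSE)
  ccs_cols <- grep("^ccs_[0-9]+$", names(wide), value = TRUE)
  sup_cols <- grep("^support_[0-9]+$", names(wide), value = TRUE)
  ccs_cols <- ccs_cols[order(as.integer(sub("ccs_", "", ccs_cols)))]
  sup_cols <- sup_cols[order(as.integer(sub("support_", "", sup_cols)))]
  if (nrow(wide) == 0L) {
    return(data.table::data.table(peptidoform = character(0),
                                  charge = integer(0),
                                  ccs_values = list(), supports = list(),
                                  label = character(0)))
  }
  cm <- as.matrix(wide[, ccs_cols, with = FALSE])
  sm <- as.matrix(wide[, sup_cols, with = FALSE])
  data.table::data.table(
    peptidoform = wide$peptidoform,
    charge = as.integer(wide$charge),
    ccs_values = lapply(seq_len(nrow(wide)), function(i)
      unname(cm[i, !is.na(cm[i, ]), drop = TRUE])),
    supports = lapply(seq_len(nrow(wide)), function(i)
      as.integer(sm[i, !is.na(sm[i, ]), drop = TRUE])),
    label = wide$label
  )
}
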