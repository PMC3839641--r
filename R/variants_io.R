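# Tab-delimited I/O for variant datasets, component-score tables, aligned
# FASTA, and prediction outputs. All tables are UTF-8 TSV with a header;
# positions are 1-based protein residue indices throughout.

default_col_map <- function() {
  c(protein_id = "protein_id", position = "position",
    wt = "wt", mut = "mut", label = "label")
}

#' Read a variant dataset
#'
#' Reads a TSV of single amino-acid substitutions (one row per variant:
#' protein accession, 1-based residue position, wild-type and mutant
#' residues, and an optional disease/polymorphism class label). Because
#' upstream exports differ in their column layout, the reader takes an
#' explicit column mapping rather than hard-coding one dialect.
#'
#' Rows violating the variant invariants (wild-type equal to mutant,
#' position < 1, residues outside the 20 standard amino acids, missing
#' fields) are rejected; the rejected rows and reasons are attached as the
#' `"rejected"` attribute and summarised in a warning. Duplicate variant
#' keys collapse to the first occurrence with a warning. Lowercase residue
#' codes are normalized to uppercase.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param col_map Named character vector mapping the canonical field names
#'   (`protein_id`, `position`, `wt`, `mut`, and optionally `label`) to the
#'   column names used in the file. Defaults to the identity mapping.
#' @param label_values Named character vector mapping the file's class
#'   annotations to the canonical labels; values are matched
#'   case-insensitively.
#' @return A tibble with columns `protein_id` (character), `position`
#'   (integer), `wt`, `mut` (uppercase single letters) and `label` (factor
#'   with levels disease, polymorphism; `NA` when unlabeled), carrying the
#'   per-row rejection report as attribute `"rejected"`.
#' @export
read_variants <- function(path, col_map = NULL,
                          label_values = c(Disease = "disease",
                                           Polymorphism = "polymorphism")) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path))
  }
  map <- default_col_map()
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- unname(map[c("protein_id", "position", "wt", "mut")])
  absent <- setdiff(needed, names(raw))
  if (length(absent) > 0) {
    rlang::abort(paste0("configured column(s) not in file: ",
                        paste(absent, collapse = ", ")))
  }
  has_label <- map[["label"]] %in% names(raw)
  tab <- tibble::tibble(
    protein_id = raw[[map[["protein_id"]]]],
    position_raw = raw[[map[["position"]]]],
    wt = toupper(trimws(raw[[map[["wt"]]]])),
    mut = toupper(trimws(raw[[map[["mut"]]]])),
    label_raw = if (has_label) raw[[map[["label"]]]] else NA_character_
  )
  suppressWarnings(pos <- as.integer(tab$position_raw))
  non_integer <- !is.na(tab$position_raw) &
    (is.na(pos) | as.character(pos) != trimws(tab$position_raw))
  reason <- rep(NA_character_, nrow(tab))
  reason[is.na(tab$protein_id) | tab$protein_id == ""] <- "missing protein_id"
  reason[non_integer | is.na(pos)] <- "non-integer position"
  reason[is.na(reason) & pos < 1] <- "position < 1"
  bad_aa <- !(tab$wt %in% AMINO_ACIDS) | !(tab$mut %in% AMINO_ACIDS)
  reason[is.na(reason) & bad_aa] <- "unknown amino-acid code"
  reason[is.na(reason) & tab$wt == tab$mut] <- "wild-type equals mutant"

  rejected <- tibble::tibble(row = which(!is.na(reason)),
                             reason = reason[!is.na(reason)])
  if (nrow(rejected) > 0) {
    rlang::warn(sprintf("rejected %d of %d row(s): %s", nrow(rejected),
                        nrow(tab),
                        paste(unique(rejected$reason), collapse = "; ")))
  }
  keep <- is.na(reason)
  label <- tolower(trimws(tab$label_raw))
  lv <- stats::setNames(unname(label_values), tolower(names(label_values)))
  label <- unname(lv[label])
  out <- tibble::tibble(
    protein_id = tab$protein_id[keep],
    position = pos[keep],
    wt = tab$wt[keep],
    mut = tab$mut[keep],
    label = factor(label[keep], levels = c("disease", "polymorphism"))
  )
  dup <- duplicated(out[, VARIANT_KEY])
  if (any(dup)) {
    rlang::warn(sprintf(
      "collapsed %d duplicate variant key(s) to first occurrence", sum(dup)))
    out <- out[!dup, ]
  }
  attr(out, "rejected") <- rejected
  out
}

#' Read a component-score table
#'
#' Reads per-variant raw scores from the four component predictors. Empty
#' cells mean "no prediction returned" and are kept as `NA` (flagged, not
#' filled — imputation is a separate, explicit step). Native scales are
#' preserved unchanged; any present score outside its method's documented
#' range (SIFT/PhD-SNP/PANTHER outside \[0, 1\], SNAP outside
#' \[-100, 100\]) is an error naming the row and method.
#'
#' @param path Path to a TSV whose header contains the variant key columns
#'   and the method columns `panther`, `phdsnp`, `sift`, `snap`.
#' @param registry Method registry used for range validation.
#' @return A tibble keyed by `protein_id`, `position`, `wt`, `mut` with one
#'   numeric column per method.
#' @export
read_scores <- function(path, registry = method_registry()) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  absent <- setdiff(registry$method, names(raw))
  if (length(absent) > 0) {
    rlang::abort(paste0("score table lacks method column(s): ",
                        paste(absent, collapse = ", ")))
  }
  out <- raw
  if ("position" %in% names(out)) out$position <- as.integer(out$position)
  for (m in registry$method) out[[m]] <- as.numeric(out[[m]])
  out <- tibble::as_tibble(out)
  validate_score_ranges(out, registry)
  out
}

#' Read an aligned FASTA file
#'
#' The first record is taken to be the query (ungapped coordinates of the
#' variant positions refer to it). Sequences must all have the same aligned
#' length.
#'
#' @param path Path to an aligned FASTA file.
#' @return A named character vector of aligned sequences (uppercase).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path))
  }
  seqs <- Biostrings::readBStringSet(path)
  aln <- toupper(as.character(seqs))
  if (length(unique(nchar(aln))) > 1) {
    rlang::abort("ragged alignment: sequences differ in aligned length")
  }
  aln
}

#' Write an aligned FASTA file
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  set <- Biostrings::BStringSet(alignment)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write meta-predictions to TSV
#'
#' Writes one row per variant with the disease probability, binary call,
#' reliability index and predictor-agreement subset tag. Probabilities and
#' reliability indices are written with six decimals and round-trip
#' losslessly at that precision via [read_predictions()].
#'
#' @param preds A data frame with the variant key plus `p_disease`, `call`,
#'   `ri` and optionally `subset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path) {
  preds <- tibble::as_tibble(preds)
  cols <- c(intersect(VARIANT_KEY, names(preds)),
            intersect(c("p_disease", "call", "ri", "subset"), names(preds)))
  out <- preds[, cols]
  for (nm in intersect(c("p_disease", "ri"), names(out))) {
    out[[nm]] <- sprintf("%.6f", out[[nm]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read meta-predictions written by [write_predictions()]
#'
#' @param path Path to the prediction TSV.
#' @return A tibble with numeric `p_disease` and `ri`, factor `call` and
#'   (if present) factor `subset`.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path))
  }
  out <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if ("position" %in% names(out)) out$position <- as.integer(out$position)
  for (nm in intersect(c("p_disease", "ri"), names(out))) {
    out[[nm]] <- as.numeric(out[[nm]])
  }
  if ("call" %in% names(out)) {
    out$call <- factor(out$call, levels = c("disease", "polymorphism"))
  }
  if ("subset" %in% names(out)) {
    out$subset <- factor(out$subset, levels = c("consensus", "majority", "tie"))
  }
  tibble::as_tibble(out)
}

#' Write a generic TSV table
#'
#' Thin wrapper used by the pipeline for variant tables, score tables and
#' feature tables so that all artifacts share one dialect (UTF-8,
#' tab-delimited, header row, `NA` as empty cell).
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, na = "", progress = FALSE)
  invisible(path)
}
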