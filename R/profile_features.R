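# Sequence-profile features at a mutated site: residue frequencies of the
# wild-type and mutant amino acids, alignment depth, and a conservation
# index, all computed from one column of a multiple sequence alignment (or
# supplied directly as a precomputed profile table).

GAP_CHARS <- c("-", ".")

#' Amino-acid profile of one alignment column
#'
#' Computes the relative frequencies of the 20 standard amino acids at one
#' (1-based) column of an alignment. Gaps are excluded from the frequency
#' denominator, and `n_aligned` counts the sequences contributing a
#' standard residue at the column. Non-standard residue codes (X, B, Z, ...)
#' are treated like gaps: absent from both numerator and denominator. No
#' pseudocounts or sequence weights are applied.
#'
#' @param alignment Character vector of equal-length aligned sequences.
#' @param column 1-based alignment column index.
#' @return A list with `frequencies` (named 20-vector summing to 1 when
#'   `n_aligned > 0`, all `NA` otherwise) and `n_aligned`.
#' @export
column_profile <- function(alignment, column) {
  widths <- unique(nchar(alignment))
  if (length(widths) != 1) {
    rlang::abort("ragged alignment: sequences differ in aligned length")
  }
  if (column < 1 || column > widths) {
    rlang::abort(sprintf("column %d out of range [1, %d]", column, widths))
  }
  res <- toupper(substr(alignment, column, column))
  res <- res[res %in% AMINO_ACIDS]
  n_aligned <- length(res)
  if (n_aligned == 0) {
    freqs <- stats::setNames(rep(NA_real_, length(AMINO_ACIDS)), AMINO_ACIDS)
  } else {
    counts <- table(factor(res, levels = AMINO_ACIDS))
    freqs <- stats::setNames(as.numeric(counts) / n_aligned, AMINO_ACIDS)
  }
  list(frequencies = freqs, n_aligned = n_aligned)
}

#' Conservation index of an alignment column
#'
#' One minus the normalized Shannon entropy of the 20-state amino-acid
#' frequency vector: `ci = 1 - H / ln(20)`. A fully conserved column scores
#' 1; a column uniform over all 20 residues scores 0. The index is
#' permutation-invariant over residue identities.
#'
#' @param profile Output of [column_profile()], or a bare numeric frequency
#'   vector summing to 1.
#' @return Conservation index in \[0, 1\].
#' @export
conservation_index <- function(profile) {
  freqs <- if (is.list(profile)) profile$frequencies else profile
  if (is.list(profile) && profile$n_aligned == 0) {
    rlang::abort("empty column: conservation index undefined at n_aligned = 0")
  }
  p <- freqs[!is.na(freqs) & freqs > 0]
  h <- -sum(p * log(p))
  1 - h / log(20)
}

#' Profile features at a mutated site
#'
#' Extracts the four profile features used by the meta-classifier at one
#' substitution site: `f_wt` and `f_mut` (relative frequencies of the
#' wild-type and mutant residues in the alignment column), `n_al` (number
#' of sequences with a residue at the column) and `ci` (conservation
#' index). The protein `position` is an ungapped residue index into the
#' first (query) sequence; it is mapped to the corresponding alignment
#' column by skipping query gaps. If the query residue at that position
#' differs from the declared wild type, a warning is emitted and the
#' features are still computed.
#'
#' @param alignment Character vector of equal-length aligned sequences;
#'   first sequence is the query.
#' @param position 1-based residue position in the ungapped query.
#' @param wt,mut Wild-type and mutant one-letter residue codes.
#' @return A one-row tibble with columns `f_wt`, `f_mut`, `n_al`, `ci`
#'   (features `NA` when the column holds no residues).
#' @export
site_features <- function(alignment, position, wt, mut) {
  query <- strsplit(toupper(alignment[[1]]), "")[[1]]
  residue_cols <- which(!(query %in% GAP_CHARS))
  if (position < 1 || position > length(residue_cols)) {
    rlang::abort(sprintf(
      "position %d beyond query length %d", position, length(residue_cols)))
  }
  column <- residue_cols[position]
  if (query[column] != toupper(wt)) {
    rlang::warn(sprintf(
      "query residue '%s' at position %d does not match declared wild type '%s'",
      query[column], position, toupper(wt)))
  }
  prof <- column_profile(alignment, column)
  if (prof$n_aligned == 0) {
    return(tibble::tibble(f_wt = NA_real_, f_mut = NA_real_,
                          n_al = 0L, ci = NA_real_))
  }
  tibble::tibble(
    f_wt = unname(prof$frequencies[toupper(wt)]),
    f_mut = unname(prof$frequencies[toupper(mut)]),
    n_al = as.integer(prof$n_aligned),
    ci = conservation_index(prof)
  )
}

#' Profile features for a variant table
#'
#' Computes [site_features()] for every variant, looking up each variant's
#' alignment by protein accession. Alternatively (alignment-free mode) a
#' precomputed profile table with columns `f_wt`, `f_mut`, `n_al`, `ci` can
#' be passed straight to [build_features()].
#'
#' @param variants Variant table (see [read_variants()]).
#' @param alignments Named list of alignments (character vectors), indexed
#'   by `protein_id`.
#' @return The variant key columns followed by `f_wt`, `f_mut`, `n_al`,
#'   `ci`.
#' @export
profile_features <- function(variants, alignments) {
  variants <- tibble::as_tibble(variants)
  absent <- setdiff(unique(variants$protein_id), names(alignments))
  if (length(absent) > 0) {
    rlang::abort(paste0("no alignment for protein(s): ",
                        paste(utils::head(absent, 5), collapse = ", ")))
  }
  feats <- purrr::pmap(
    variants[, VARIANT_KEY],
    function(protein_id, position, wt, mut) {
      site_features(alignments[[protein_id]], position, wt, mut)
    }
  )
  dplyr::bind_cols(variants[, VARIANT_KEY], dplyr::bind_rows(feats))
}
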