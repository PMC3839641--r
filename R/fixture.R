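# A 12-variant worked micro-dataset with hand-written scores and
# alignments: four consensus, four majority and four tie variants, one
# missing score per method, and one exactly-at-threshold score. Shipped
# both as code (this file) and as plain-text copies under
# inst/extdata/fixture/ for I/O round-trip tests.

#' Worked 12-variant micro-dataset
#'
#' A hand-constructed fixture covering every predictor-agreement stratum
#' (consensus-disease, consensus-polymorphism, majority, tie: four variants
#' each), one missing score per method, and one score exactly at its
#' method's threshold (SNAP = 0, which binarizes to neutral). Each variant
#' has its own 6-sequence alignment of aligned length 9 with the mutated
#' site at position 5; two alignments contain gaps at the site. Class
#' labels are balanced six/six.
#'
#' @return A list with `variants`, `scores`, `alignments` in the same
#'   shapes as [simulate_dataset()].
#' @export
worked_fixture <- function() {
  variants <- tibble::tibble(
    protein_id = sprintf("P%03d", 1:12),
    position = 5L,
    wt  = c("A", "R", "L", "K", "G", "C", "S", "F", "D", "E", "V", "T"),
    mut = c("V", "W", "I", "E", "D", "Y", "T", "L", "N", "Q", "M", "S"),
    label = factor(c("disease", "disease", "polymorphism", "polymorphism",
                     "disease", "disease", "polymorphism", "disease",
                     "disease", "polymorphism", "polymorphism",
                     "polymorphism"),
                   levels = c("disease", "polymorphism"))
  )
  scores <- dplyr::bind_cols(
    variants[, VARIANT_KEY],
    tibble::tibble(
      panther = c(0.9, 0.8, 0.1, 0.2, 0.9, 0.6, 0.1, NA, 0.9, 0.7, 0.8, 0.6),
      phdsnp  = c(0.9, 0.7, 0.2, 0.3, 0.8, 0.7, 0.3, 0.8, 0.7, 0.2, 0.3, NA),
      sift    = c(0.01, 0.02, 0.9, 0.5, 0.02, 0.01, 0.8, 0.03, 0.9, NA,
                  0.02, 0.04),
      snap    = c(50, 30, -40, -10, -20, 0, 60, 40, -50, 30, NA, -30)
    )
  )
  site_others <- list(
    c("A", "A", "A", "A", "A"),
    c("R", "R", "R", "R", "W"),
    c("I", "L", "I", "L", "I"),
    c("K", "E", "E", "G", "G"),
    c("G", "G", "G", "G", "-"),
    c("C", "C", "C", "-", "-"),
    c("T", "S", "T", "T", "S"),
    c("F", "F", "L", "F", "F"),
    c("D", "D", "D", "N", "N"),
    c("Q", "E", "Q", "Q", "E"),
    c("V", "V", "V", "V", "V"),
    c("S", "A", "T", "S", "A")
  )
  alignments <- purrr::pmap(
    list(variants$protein_id, variants$wt, site_others),
    function(protein, wt, others) {
      col <- c(wt, others)
      rows <- paste0("ACDE", col, "GHIK")
      names(rows) <- c(paste0(protein, "_query"),
                       paste0(protein, "_h", seq_along(others)))
      rows
    })
  names(alignments) <- variants$protein_id
  list(variants = variants, scores = scores, alignments = alignments)
}

#' Write the worked fixture to a directory as plain-text files
#'
#' Produces `variants.tsv`, `scores.tsv` and one aligned FASTA per protein,
#' in the dialects consumed by [read_variants()], [read_scores()] and
#' [read_alignment()].
#'
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dir) {
  fx <- worked_fixture()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(fx$variants, file.path(dir, "variants.tsv"))
  write_table(fx$scores, file.path(dir, "scores.tsv"))
  purrr::iwalk(fx$alignments, function(aln, protein) {
    write_alignment(aln, file.path(dir, paste0(protein, ".fasta")))
  })
  invisible(dir)
}
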