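#' Map a secondary structure onto alignment columns
#'
#' Structural base pairs are defined on the ungapped reference sequence; a
#' reference row of the alignment carries gaps, so each paired position is
#' pushed through the row's gap pattern to its alignment column.
#'
#' @param structure A `secondary_structure` whose length equals the
#'   ungapped length of the reference row.
#' @param reference_id Id of the alignment row the structure annotates.
#' @param aln A `multiple_alignment`.
#' @return Two-column integer matrix of 0-based paired alignment columns.
#' @export
map_structure <- function(structure, reference_id, aln) {
  stopifnot(inherits(structure, "secondary_structure"),
            inherits(aln, "multiple_alignment"))
  ids <- vapply(aln$records, function(r) r$id, character(1))
  row <- which(ids == reference_id)
  if (!length(row)) stop("reference '", reference_id, "' not in alignment")
  ref <- strsplit(aln$records[[row]]$residues, "", fixed = TRUE)[[1]]
  ungapped_cols <- which(ref != "-") - 1L      # 0-based alignment columns
  if (nchar(structure$dotbracket) != length(ungapped_cols))
    stop("structure length (", nchar(structure$dotbracket),
         ") does not match ungapped reference length (",
         length(ungapped_cols), ")")
  pairs <- structure$pairs
  cbind(i = ungapped_cols[pairs[, "i"] + 1L],
        j = ungapped_cols[pairs[, "j"] + 1L])
}

CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Classify structural base pairs between two sequences
#'
#' For each mapped pair, compares the two alignment rows and assigns one
#' of five mutually exclusive categories: `indel_overlap` (a gap occupies
#' either mapped column in either sequence), `disrupted` (either sequence
#' fails to form a canonical pair — Watson–Crick or G·U wobble, with T
#' read as U), `CBC` (both positions differ between the sequences and both
#' sequences still pair), `hemi_CBC` (exactly one position differs,
#' pairing retained), or `conserved_pair`.
#'
#' @param seq_a_id,seq_b_id Ids of two rows of `aln`.
#' @param aln A `multiple_alignment`.
#' @param pairs Mapped column pairs from [map_structure()].
#' @return Object of class `pair_classification`: `per_pair` `data.frame`
#'   (i, j, category) and `totals` (named integer vector over the five
#'   categories; sums to the number of structural pairs).
#' @export
classify_pairs <- function(seq_a_id, seq_b_id, aln, pairs) {
  stopifnot(inherits(aln, "multiple_alignment"))
  m <- aln_matrix(aln)
  for (id in c(seq_a_id, seq_b_id))
    if (!id %in% rownames(m)) stop("sequence '", id, "' not in alignment")
  a <- chartr("T", "U", m[seq_a_id, ])
  b <- chartr("T", "U", m[seq_b_id, ])
  cats <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ci <- pairs[k, 1] + 1L; cj <- pairs[k, 2] + 1L
    four <- c(a[ci], a[cj], b[ci], b[cj])
    if (any(four == "-")) { cats[k] <- "indel_overlap"; next }
    a_ok <- paste0(a[ci], a[cj]) %in% CANONICAL_PAIRS
    b_ok <- paste0(b[ci], b[cj]) %in% CANONICAL_PAIRS
    if (!a_ok || !b_ok) { cats[k] <- "disrupted"; next }
    ndiff <- (a[ci] != b[ci]) + (a[cj] != b[cj])
    cats[k] <- c("conserved_pair", "hemi_CBC", "CBC")[ndiff + 1L]
  }
  lev <- c("conserved_pair", "CBC", "hemi_CBC", "disrupted", "indel_overlap")
  totals <- table(factor(cats, levels = lev))
  structure(list(
    per_pair = data.frame(i = pairs[, 1], j = pairs[, 2], category = cats,
                          stringsAsFactors = FALSE),
    totals = stats::setNames(as.integer(totals), lev)
  ), class = "pair_classification")
}

#' @export
print.pair_classification <- function(x, ...) {
  cat("<pair_classification: ",
      paste(sprintf("%s=%d", names(x$totals), x$totals), collapse = ", "),
      ">\n", sep = "")
  invisible(x)
}

#' Screen two sequences for compensatory base changes
#'
#' Convenience wrapper: maps `structure` (folded on `template_id`) onto the
#' alignment and classifies every structural pair between the two named
#' sequences. The template must be named explicitly — the screen is only
#' meaningful relative to a declared common fold.
#'
#' @inheritParams classify_pairs
#' @param structure A `secondary_structure` for the template row.
#' @param template_id Alignment row the structure was folded on.
#' @return A `pair_classification`.
#' @export
cbc_screen <- function(aln, structure, template_id, seq_a_id, seq_b_id) {
  pairs <- map_structure(structure, template_id, aln)
  classify_pairs(seq_a_id, seq_b_id, aln, pairs)
}
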