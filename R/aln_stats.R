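#' Classify alignment columns as constant / parsimony-informative / variable
#'
#' Gaps (`-`) and missing data (`N`) are excluded from the state counts of
#' a column. A column is *constant* when at most one distinct state remains
#' (all-gap columns count as constant), *parsimony-informative* (PI) when
#' at least two states are each present in at least two sequences, and
#' otherwise *variable-uninformative* (VU). The three class counts always
#' sum to the alignment length.
#'
#' @param aln A `multiple_alignment` (>= 2 rows).
#' @return Object of class `column_classification`: counts `n_constant`,
#'   `n_parsimony_informative`, `n_variable_uninformative`; `n_gap_columns`
#'   (columns containing at least one gap or `N`, the headline
#'   "gaps or missing data" figure) plus `n_gap_cells` (individual gapped
#'   or missing cells); and `per_column` (factor of `constant`/`PI`/`VU`).
#' @export
classify_columns <- function(aln) {
  stopifnot(inherits(aln, "multiple_alignment"),
            length(aln$records) >= 2L)
  m <- aln_matrix(aln)
  per <- apply(m, 2, function(col) {
    states <- col[!col %in% c("-", "N")]
    tab <- table(states)
    if (length(tab) <= 1L) return("constant")
    if (sum(tab >= 2L) >= 2L) return("PI")
    "VU"
  })
  gapped <- m %in% c("-", "N")
  dim(gapped) <- dim(m)
  structure(list(
    n_constant = sum(per == "constant"),
    n_parsimony_informative = sum(per == "PI"),
    n_variable_uninformative = sum(per == "VU"),
    n_gap_columns = sum(apply(gapped, 2, any)),
    n_gap_cells = sum(gapped),
    per_column = factor(per, levels = c("constant", "PI", "VU"))
  ), class = "column_classification")
}

#' @export
print.column_classification <- function(x, ...) {
  total <- x$n_constant + x$n_parsimony_informative +
    x$n_variable_uninformative
  cat(sprintf(
    "<column_classification: %d columns — %d constant (%.0f%%), %d PI (%.0f%%), %d VU (%.0f%%); %d gap/missing columns>\n",
    total, x$n_constant, 100 * x$n_constant / total,
    x$n_parsimony_informative, 100 * x$n_parsimony_informative / total,
    x$n_variable_uninformative, 100 * x$n_variable_uninformative / total,
    x$n_gap_columns))
  invisible(x)
}

#' GC content per sequence and summary
#'
#' GC fraction over the ungapped, non-`N` residues of each record, plus the
#' unweighted mean, minimum and maximum across records.
#'
#' @param records List of `seq_record`s (alignments welcome; gaps ignored).
#' @return List: `per_sequence` (named numeric), `mean`, `min`, `max`.
#' @export
gc_content <- function(records) {
  if (inherits(records, "multiple_alignment")) records <- records$records
  if (inherits(records, "seq_record")) records <- list(records)
  per <- vapply(records, function(r) {
    ch <- strsplit(r$residues, "", fixed = TRUE)[[1]]
    ch <- ch[!ch %in% c("-", "N")]
    if (!length(ch))
      stop("sequence '", r$id, "' has no countable residues for GC content")
    mean(ch %in% c("G", "C"))
  }, numeric(1))
  names(per) <- vapply(records, function(r) r$id, character(1))
  list(per_sequence = per, mean = mean(per), min = min(per), max = max(per))
}

#' Collapse aligned sequences into haplotypes
#'
#' Two rows share a haplotype iff their aligned texts are identical
#' character-for-character — gaps and `N` are significant, so indel
#' variants remain distinct haplotypes. Haplotypes are ordered by first
#' appearance.
#'
#' @param aln A `multiple_alignment` (a single-row alignment is accepted
#'   via a list of records).
#' @return Object of class `haplotype_set`: `haplotypes` (list of
#'   `representative`, `members`), `n_haplotypes`.
#' @export
collapse_haplotypes <- function(aln) {
  records <- if (inherits(aln, "multiple_alignment")) aln$records else aln
  stopifnot(length(records) >= 1L)
  seqs <- residues_of(records)
  groups <- split(names(seqs), factor(seqs, levels = unique(seqs)))
  structure(list(
    haplotypes = lapply(seq_along(groups), function(k)
      list(representative = names(groups)[k], members = groups[[k]])),
    n_haplotypes = length(groups)
  ), class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set: %d haplotype(s) from %d sequence(s)>\n",
              x$n_haplotypes,
              sum(lengths(lapply(x$haplotypes, `[[`, "members")))))
  invisible(x)
}

# Invertebrate mitochondrial genetic code (NCBI translation table 5),
# the correct code for mosquito COI.
translate_codon_mito <- function(codon) {
  code <- Biostrings::getGeneticCode("5")
  if (grepl("[^ACGT]", codon)) return(NA_character_)
  unname(code[codon])
}

#' Group-diagnostic substitutions in a protein-coding alignment
#'
#' Scans for columns where one group is fixed for a state different from
#' the state fixed in all other groups (a fully diagnostic site), and
#' classifies each hit as synonymous or non-synonymous under the
#' invertebrate mitochondrial genetic code.
#'
#' @param aln A `multiple_alignment` of a protein-coding region.
#' @param labels Named character vector `sequence id -> group`.
#' @param frame_offset 0, 1 or 2: alignment column (0-based) where the
#'   first complete codon starts. Supplied, not inferred.
#' @return `data.frame` with one row per diagnostic site: `column`
#'   (1-based nucleotide position), `aa_index` (1-based codon number),
#'   `group`, `from_state`, `to_state` (other groups' state vs the focal
#'   group's state), `codon_position` (1-3), `syn` (logical; `NA` when a
#'   gap falls inside the implicated codon), `aa_from`, `aa_to`.
#' @export
diagnostic_substitutions <- function(aln, labels, frame_offset = 0L) {
  stopifnot(inherits(aln, "multiple_alignment"),
            frame_offset %in% 0:2)
  m <- aln_matrix(aln)
  ids <- rownames(m)
  if (!all(ids %in% names(labels)))
    stop("labels missing for: ",
         paste(setdiff(ids, names(labels)), collapse = ", "))
  grp <- labels[ids]
  groups <- unique(grp)
  hits <- list()
  for (col in seq_len(ncol(m))) {
    states <- m[, col]
    per_group <- tapply(states, grp, function(s) unique(s[!s %in% c("-", "N")]))
    if (any(lengths(per_group) != 1L)) next        # some group not fixed
    fixed <- vapply(per_group, identity, character(1))
    for (g in groups) {
      others <- fixed[names(fixed) != g]
      if (length(unique(others)) == 1L && others[1] != fixed[[g]]) {
        cp <- (col - 1L - frame_offset) %% 3L + 1L
        codon_start <- col - (cp - 1L)
        aa_index <- (codon_start - 1L - frame_offset) %/% 3L + 1L
        syn <- NA; aa_from <- NA_character_; aa_to <- NA_character_
        if (codon_start >= 1L && codon_start + 2L <= ncol(m)) {
          g_row <- which(grp == g)[1]
          o_row <- which(grp != g)[1]
          cod_o <- paste(m[o_row, codon_start:(codon_start + 2L)],
                         collapse = "")
          cod_g <- paste(m[g_row, codon_start:(codon_start + 2L)],
                         collapse = "")
          aa_from <- translate_codon_mito(cod_o)
          aa_to <- translate_codon_mito(cod_g)
          if (!is.na(aa_from) && !is.na(aa_to)) syn <- aa_from == aa_to
        }
        hits[[length(hits) + 1L]] <- data.frame(
          column = col, aa_index = aa_index, group = g,
          from_state = unname(others[1]), to_state = unname(fixed[[g]]),
          codon_position = cp, syn = syn,
          aa_from = aa_from, aa_to = aa_to, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(column = integer(), aa_index = integer(),
                      group = character(), from_state = character(),
                      to_state = character(), codon_position = integer(),
                      syn = logical(), aa_from = character(),
                      aa_to = character(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}
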