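#' Global pairwise alignment with affine gaps
#'
#' End-to-end (Needleman–Wunsch) alignment under affine gap scoring, used to
#' describe how one intragenomic spacer copy variant differs from another.
#' A gap of length `L` costs `gap_open + L * gap_extend`. The backing
#' engine is `Biostrings::pairwiseAlignment()`; the difference list is
#' derived column-by-column from the aligned strings.
#'
#' @param a,b `seq_record`s (or bare strings); must be ungapped.
#' @param scoring Numeric vector `c(match, mismatch, gap_open, gap_extend)`
#'   with `match > 0` and the rest `<= 0`.
#' @return Object of class `pairwise_alignment` with `aligned_a`,
#'   `aligned_b`, `score`, and `events`: a `data.frame` of
#'   (kind, position, length, detail) where `kind` is `substitution`,
#'   `insertion` (present in `b`, absent in `a`) or `deletion`, and
#'   `position` is the 0-based alignment column where the event starts.
#' @export
align_pair <- function(a, b, scoring = c(1, -1, -4, -1)) {
  sa <- if (inherits(a, "seq_record")) a$residues else canonicalize_residues(a)
  sb <- if (inherits(b, "seq_record")) b$residues else canonicalize_residues(b)
  if (grepl("-", sa, fixed = TRUE) || grepl("-", sb, fixed = TRUE))
    stop("align_pair expects ungapped input sequences")
  stopifnot(length(scoring) == 4, scoring[1] > 0, all(scoring[2:4] <= 0))
  key <- paste(sa, sb, paste(scoring, collapse = ","), sep = "\r")
  hit <- .align_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (sa == sb) {                          # common fast path
    out <- structure(list(aligned_a = sa, aligned_b = sb,
                          score = scoring[1] * nchar(sa),
                          events = alignment_events(sa, sb)),
                     class = "pairwise_alignment")
    .align_cache[[key]] <- out
    return(out)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring[1], mismatch = scoring[2], baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = sa, subject = sb, type = "global",
    substitutionMatrix = mat,
    gapOpening = abs(scoring[3]), gapExtension = abs(scoring[4]))
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  out <- structure(list(aligned_a = ga, aligned_b = gb,
                        score = Biostrings::score(pa),
                        events = alignment_events(ga, gb)),
                   class = "pairwise_alignment")
  .align_cache[[key]] <- out
  out
}

# Session-scope memo for align_pair: the pipeline re-aligns the same class
# representatives for every individual of a species.
.align_cache <- new.env(parent = emptyenv())

# Column scan of two equal-length gapped strings -> event table.
# Runs of gap columns coalesce into single insertion/deletion events.
alignment_events <- function(ga, gb) {
  ca <- strsplit(ga, "", fixed = TRUE)[[1]]
  cb <- strsplit(gb, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  kind <- ifelse(ca == "-", "insertion",
                 ifelse(cb == "-", "deletion",
                        ifelse(ca != cb, "substitution", "match")))
  ev <- list()
  i <- 1L
  while (i <= length(kind)) {
    k <- kind[i]
    if (k %in% c("insertion", "deletion")) {
      j <- i
      while (j < length(kind) && kind[j + 1L] == k) j <- j + 1L
      seg <- if (k == "insertion") substr(gb, i, j) else substr(ga, i, j)
      ev[[length(ev) + 1L]] <- data.frame(
        kind = k, position = i - 1L, length = j - i + 1L,
        detail = seg, stringsAsFactors = FALSE)
      i <- j + 1L
    } else {
      if (k == "substitution")
        ev[[length(ev) + 1L]] <- data.frame(
          kind = k, position = i - 1L, length = 1L,
          detail = paste0(ca[i], ">", cb[i]), stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  if (!length(ev))
    return(data.frame(kind = character(), position = integer(),
                      length = integer(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, ev)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment score=%g, %d event(s)>\n",
              x$score, nrow(x$events)))
  invisible(x)
}

# Substitution count and total indel bp summarised from an event table.
event_summary <- function(events) {
  list(mismatches = sum(events$kind == "substitution"),
       indel_bp = sum(events$length[events$kind %in%
                                      c("insertion", "deletion")]))
}

#' Call intragenomic copy-variant classes from cloned sequences
#'
#' Clones from one individual are grouped by exact sequence identity into
#' variant classes. Class 1 is the majority class (ties broken by the
#' lexicographically smallest representative); every other class is
#' described by its alignment differences against class 1.
#'
#' An optional error-correction pass (off by default) merges singleton
#' classes into a larger class when they differ by at most one substitution
#' and no indel — a guard against polymerase error in cloned PCR products.
#'
#' @param clones List of `seq_record`s (>= 2) from a single individual.
#' @param scoring Passed to [align_pair()].
#' @param correct_errors Merge 1-substitution singletons into larger classes.
#' @return Object of class `variant_set`: `individual`, `classes` (list of
#'   `representative`, `clone_count`, `members`, `diff_events`).
#' @export
call_variants <- function(clones, scoring = c(1, -1, -4, -1),
                          correct_errors = FALSE) {
  if (length(clones) < 2L) stop("variant calling needs >=2 clones")
  seqs <- residues_of(clones)
  indiv <- unique(vapply(clones, function(r) r$individual, character(1)))
  indiv <- indiv[nzchar(indiv)]
  if (length(indiv) > 1L)
    stop("clones from more than one individual: ",
         paste(indiv, collapse = ", "))
  groups <- split(names(seqs), factor(seqs, levels = unique(seqs)))
  reps <- names(groups)            # representative sequence text
  counts <- lengths(groups)

  if (correct_errors && length(reps) > 1L) {
    keep <- rep(TRUE, length(reps))
    ord_big <- order(-counts)
    for (i in seq_along(reps)) {
      if (counts[i] != 1L) next
      for (j in ord_big) {
        if (j == i || counts[j] <= 1L) next
        sm <- event_summary(align_pair(reps[i], reps[j], scoring)$events)
        if (sm$mismatches <= 1L && sm$indel_bp == 0L) {
          groups[[j]] <- c(groups[[j]], groups[[i]])
          counts[j] <- counts[j] + 1L
          keep[i] <- FALSE
          break
        }
      }
    }
    groups <- groups[keep]; reps <- reps[keep]; counts <- counts[keep]
  }

  ord <- order(-counts, reps)      # majority first, then lexicographic
  reps <- reps[ord]; groups <- groups[ord]; counts <- counts[ord]
  classes <- lapply(seq_along(reps), function(k) {
    ev <- if (k == 1L) {
      alignment_events(reps[1], reps[1])
    } else {
      align_pair(reps[1], reps[k], scoring)$events
    }
    list(representative = reps[k], clone_count = as.integer(counts[k]),
         members = groups[[k]], diff_events = ev)
  })
  structure(list(individual = if (length(indiv)) indiv else "",
                 classes = classes),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set %s: %d class(es), clone counts %s>\n",
              x$individual, length(x$classes),
              paste(vapply(x$classes, function(cl) cl$clone_count,
                           integer(1)), collapse = "/")))
  invisible(x)
}

#' Predict the heteroduplex gel signature of a variant set
#'
#' Reannealed PCR products from an individual with `k` intragenomic variant
#' classes form `k` homoduplexes and `k(k-1)/2` heteroduplexes. Each
#' heteroduplex is classified by the differences between the two class
#' representatives: `snp_het` when only substitutions mispair, `indel_het`
#' when an unpaired loop (indel) retards migration. Clone counts are
#' ignored: gels score band presence, not intensity.
#'
#' @param vs A `variant_set`.
#' @param scoring Passed to [align_pair()].
#' @return Object of class `heteroduplex_signature`: a `data.frame` of
#'   duplex classes (kind, mismatches, indel_bp), ordered homoduplex <
#'   snp_het < indel_het and by increasing distortion within kind.
#' @export
duplex_signature <- function(vs, scoring = c(1, -1, -4, -1)) {
  stopifnot(inherits(vs, "variant_set"))
  k <- length(vs$classes)
  rows <- list()
  for (i in seq_len(k))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "homoduplex", mismatches = 0L, indel_bp = 0L,
      stringsAsFactors = FALSE)
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      sm <- event_summary(
        align_pair(vs$classes[[i]]$representative,
                   vs$classes[[j]]$representative, scoring)$events)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = if (sm$indel_bp > 0L) "indel_het" else "snp_het",
        mismatches = as.integer(sm$mismatches),
        indel_bp = as.integer(sm$indel_bp), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  kind_rank <- match(df$kind, c("homoduplex", "snp_het", "indel_het"))
  df <- df[order(kind_rank, df$mismatches, df$indel_bp), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("heteroduplex_signature", "data.frame"))
}

#' Render a signature as a compact string (for reports)
#' @param sig A `heteroduplex_signature`.
#' @export
signature_string <- function(sig) {
  paste(sprintf("%s(m%d,i%d)", sig$kind, sig$mismatches, sig$indel_bp),
        collapse = "+")
}

#' Test equality of two heteroduplex signatures
#'
#' Signatures are compared as multisets of (kind, mismatches, indel_bp).
#' @param a,b `heteroduplex_signature`s.
#' @export
signatures_equal <- function(a, b) {
  identical(signature_string(a), signature_string(b))
}

#' Fixation test for copy variants across conspecific individuals
#'
#' Concerted evolution predicts that the copy-variant complement of the
#' rDNA array is fixed within an interbreeding population: every individual
#' of a genotype should show the same heteroduplex signature. This test
#' checks that prediction.
#'
#' @param group List of `variant_set`s sharing a genotype label (>= 2).
#' @param scoring Passed to [duplex_signature()].
#' @return List with `fixed` (logical) and `witness` (character vector of
#'   the first unequal pair of individuals in input order, or empty).
#' @export
fixation_test <- function(group, scoring = c(1, -1, -4, -1)) {
  if (length(group) < 2L) stop("fixation test needs >=2 individuals")
  sigs <- lapply(group, duplex_signature, scoring = scoring)
  ids <- vapply(group, function(vs) vs$individual, character(1))
  for (j in 2:length(sigs)) {
    if (!signatures_equal(sigs[[1]], sigs[[j]]))
      return(list(fixed = FALSE, witness = c(ids[1], ids[j])))
  }
  list(fixed = TRUE, witness = character(0))
}
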