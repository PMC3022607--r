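#' Restriction enzyme definition
#'
#' @param name Display name.
#' @param motif Recognition motif over `A,C,G,T`.
#' @param cut_offset Cut position within the motif: a site starting at
#'   0-based position `s` cuts between residues `s + cut_offset - 1` and
#'   `s + cut_offset`.
#' @return Object of class `enzyme`.
#' @examples
#' msp_i()  # CCGG, cutting C^CGG
#' @export
enzyme <- function(name, motif, cut_offset) {
  motif <- toupper(motif)
  if (!nzchar(motif) || grepl("[^ACGT]", motif))
    stop("enzyme motif must be non-empty over A,C,G,T")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(motif))
    stop("cut_offset must lie within the motif")
  structure(list(name = name, motif = motif, cut_offset = cut_offset),
            class = "enzyme")
}

#' Msp I (C^CGG), the enzyme used for ITS2 genotyping
#' @export
msp_i <- function() enzyme("MspI", "CCGG", 1L)

#' Gel visibility model
#'
#' Emulates band scoring on a 3% agarose gel: fragments below
#' `min_detectable` run off or are too faint, and fragments whose lengths
#' differ by at most `comigration_tolerance` of the larger co-migrate as a
#' single band.
#'
#' @param min_detectable Smallest visible fragment (bp, default 50).
#' @param comigration_tolerance Relative length difference below which two
#'   fragments merge (default 0.05).
#' @export
gel_model <- function(min_detectable = 50L, comigration_tolerance = 0.05) {
  min_detectable <- as.integer(min_detectable)
  stopifnot(min_detectable >= 1L,
            comigration_tolerance >= 0, comigration_tolerance < 0.5)
  structure(list(min_detectable = min_detectable,
                 comigration_tolerance = comigration_tolerance),
            class = "gel_model")
}

#' Locate restriction cut positions in a sequence
#'
#' Returns 0-based between-residue cut indices: position `p` means a cut
#' between residues `p-1` and `p`. Matches can overlap; `N` never matches a
#' motif character (conservative site calling). For palindromic motifs a
#' single-strand scan is complete.
#'
#' @param seq A `seq_record` (or bare residue string); must be ungapped.
#' @param enz An `enzyme`.
#' @return Strictly increasing integer vector of cut positions.
#' @examples
#' find_cut_sites("ACCGGTCCGGA", msp_i())  # 2, 7
#' @export
find_cut_sites <- function(seq, enz = msp_i()) {
  s <- if (inherits(seq, "seq_record")) seq$residues else
    canonicalize_residues(seq)
  if (grepl("-", s, fixed = TRUE))
    stop("find_cut_sites expects an ungapped sequence")
  hits <- Biostrings::matchPattern(enz$motif, Biostrings::DNAString(s),
                                   fixed = TRUE)
  starts0 <- Biostrings::start(hits) - 1L    # 0-based motif starts
  sort(unique(starts0 + enz$cut_offset))
}

#' Digest an amplicon in silico
#'
#' Complete digestion of a linear amplicon: `k` cuts give `k + 1` fragments
#' whose lengths sum to the amplicon length.
#'
#' @inheritParams find_cut_sites
#' @param gel A `gel_model` used to derive the visible band pattern.
#' @return Object of class `digest_profile` with `seq_id`,
#'   `fragment_lengths` (descending) and `visible_bands`.
#' @export
digest <- function(seq, enz = msp_i(), gel = gel_model()) {
  id <- if (inherits(seq, "seq_record")) seq$id else "seq"
  s <- if (inherits(seq, "seq_record")) seq$residues else
    canonicalize_residues(seq)
  cuts <- find_cut_sites(seq, enz)
  bounds <- c(0L, cuts, nchar(s))
  frags <- sort(diff(bounds), decreasing = TRUE)
  frags <- frags[frags > 0L]
  if (!length(frags)) frags <- nchar(s)  # degenerate: cut at 0 or L only
  prof <- structure(list(seq_id = id,
                         fragment_lengths = as.integer(frags),
                         visible_bands = integer(0)),
                    class = "digest_profile")
  prof$visible_bands <- gel_bands(prof, gel)
  prof
}

#' @export
print.digest_profile <- function(x, ...) {
  cat(sprintf("<digest %s: fragments {%s}; bands {%s}>\n", x$seq_id,
              paste(x$fragment_lengths, collapse = ","),
              paste(x$visible_bands, collapse = ",")))
  invisible(x)
}

#' Apply the gel visibility model to a digest
#'
#' Fragments shorter than `min_detectable` are dropped; fragments whose
#' lengths differ by at most `comigration_tolerance` of the larger are
#' merged into a single band at their rounded mean (single-linkage on the
#' sorted lengths, so a ladder of mutually close fragments forms one band).
#'
#' @param profile A `digest_profile` (or bare integer vector of lengths).
#' @param gel A `gel_model`.
#' @return Integer vector of visible band sizes, descending.
#' @export
gel_bands <- function(profile, gel = gel_model()) {
  frags <- if (inherits(profile, "digest_profile"))
    profile$fragment_lengths else as.integer(profile)
  frags <- sort(frags[frags >= gel$min_detectable], decreasing = TRUE)
  if (!length(frags)) return(integer(0))
  cluster <- cumsum(c(1L, diff(frags) < -gel$comigration_tolerance *
                        frags[-length(frags)]))
  as.integer(round(tapply(frags, cluster, mean)))
}

#' Match two band patterns under comigration tolerance
#'
#' Patterns match iff they have the same number of bands and a one-to-one
#' pairing (greedy, both sorted descending) puts every pair within
#' tolerance. This mirrors eye-matching of gel lanes against a ladder.
#'
#' @param a,b Integer vectors of band sizes.
#' @param gel A `gel_model`.
#' @return Logical scalar.
#' @export
bands_match <- function(a, b, gel = gel_model()) {
  if (length(a) != length(b)) return(FALSE)
  if (!length(a)) return(TRUE)
  a <- sort(a, decreasing = TRUE); b <- sort(b, decreasing = TRUE)
  all(abs(a - b) <= gel$comigration_tolerance * pmax(a, b))
}

#' Cluster band patterns into RFLP genotype classes
#'
#' Each pattern joins the first existing class whose representative pattern
#' it matches under [bands_match()]; otherwise it founds a new class.
#' Classes are labelled `A`, `B`, `C`, ... in order of first appearance, so
#' the assignment is deterministic given input order and the partition is
#' stable (up to relabelling) under reordering of well-separated patterns.
#'
#' @param patterns Named list: `seq_id -> integer vector of visible bands`.
#' @param gel A `gel_model`.
#' @return Named character vector `seq_id -> class label`.
#' @export
cluster_profiles <- function(patterns, gel = gel_model()) {
  stopifnot(is.list(patterns), length(patterns) >= 1L,
            !is.null(names(patterns)))
  reps <- list()           # class label -> representative band pattern
  assign <- character(length(patterns))
  names(assign) <- names(patterns)
  for (i in seq_along(patterns)) {
    hit <- NA_character_
    for (lab in names(reps)) {
      if (bands_match(patterns[[i]], reps[[lab]], gel)) { hit <- lab; break }
    }
    if (is.na(hit)) {
      hit <- class_label(length(reps) + 1L)
      reps[[hit]] <- patterns[[i]]
    }
    assign[i] <- hit
  }
  assign
}

# 1 -> "A", 26 -> "Z", 27 -> "AA", ...
class_label <- function(i) {
  out <- ""
  while (i > 0L) {
    out <- paste0(LETTERS[(i - 1L) %% 26L + 1L], out)
    i <- (i - 1L) %/% 26L
  }
  out
}
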