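#' Construct a sequence record
#'
#' The basic unit carried through the pipeline: one DNA sequence with its
#' marker and (optional) individual / collection-site / genotype annotations.
#' Residues are canonicalized to uppercase `A,C,G,T,N,-`; `U` becomes `T`
#' and any other character becomes `N` with a warning.
#'
#' @param id Unique sequence label.
#' @param residues DNA string (gaps allowed for aligned sequences).
#' @param marker One of `"ITS2"`, `"COI"`, `"other"`.
#' @param individual,site,genotype Optional annotations (`""` when unknown).
#' @return An object of class `seq_record`.
#' @examples
#' seq_record("s1", "acgu")  # canonicalized to ACGT
#' @export
seq_record <- function(id, residues, marker = "other",
                       individual = "", site = "", genotype = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  marker <- match.arg(marker, c("ITS2", "COI", "other"))
  residues <- canonicalize_residues(residues, id = id)
  structure(
    list(id = id, residues = residues, marker = marker,
         individual = individual, site = site, genotype = genotype),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s [%s] %d nt%s>\n", x$id, x$marker,
              nchar(x$residues),
              if (nzchar(x$genotype)) paste0(" genotype=", x$genotype) else ""))
  invisible(x)
}

# Uppercase, U->T, anything outside {A,C,G,T,N,-} -> N (warned once per call).
canonicalize_residues <- function(residues, id = "?") {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (!nzchar(residues)) stop("sequence '", id, "' has empty residues")
  r <- chartr("u", "T", toupper(residues))
  r <- chartr("U", "T", r)
  bad <- gsub("[ACGTN-]", "", r)
  if (nzchar(bad)) {
    warning("sequence '", id, "': ", nchar(bad),
            " non-DNA character(s) replaced by N", call. = FALSE)
    r <- gsub("[^ACGTN-]", "N", r)
  }
  r
}

#' Residues of one or many records as a character vector
#' @param records A `seq_record` or list of them.
#' @return Named character vector of residue strings.
#' @export
residues_of <- function(records) {
  if (inherits(records, "seq_record")) records <- list(records)
  stats::setNames(vapply(records, function(r) r$residues, character(1)),
                  vapply(records, function(r) r$id, character(1)))
}

#' Bundle aligned records into a multiple alignment
#'
#' @param records List of `seq_record`s with equal residue lengths (>= 2).
#' @return An object of class `multiple_alignment` with elements `records`
#'   and `length` (number of columns). Column indices are 0-based half-open
#'   at all API boundaries.
#' @export
multiple_alignment <- function(records) {
  stopifnot(is.list(records), length(records) >= 2L)
  lens <- vapply(records, function(r) nchar(r$residues), integer(1))
  if (length(unique(lens)) != 1L)
    stop("alignment rows have unequal lengths: ",
         paste(unique(lens), collapse = ", "))
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate ids in alignment: ",
                               ids[duplicated(ids)][1])
  structure(list(records = records, length = lens[[1]]),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment: %d sequences x %d columns>\n",
              length(x$records), x$length))
  invisible(x)
}

# Character matrix view (rows = sequences), used by the column-wise analyses.
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(residues_of(aln$records), "", fixed = TRUE))
  rownames(m) <- vapply(aln$records, function(r) r$id, character(1))
  m
}

#' Read sequences from FASTA or relaxed sequential Phylip
#'
#' FASTA ids may embed annotations as `id|individual|site|genotype`; these
#' are split into the corresponding `seq_record` fields. The Phylip dialect
#' is "relaxed sequential": a header line `<n> <length>` followed by one
#' `name sequence` line per record, names delimited by whitespace (no 10
#' character truncation, no interleaving).
#'
#' @param path Input file.
#' @param format `"fasta"` or `"phylip_relaxed"`.
#' @param marker Marker tag applied to all records.
#' @return List of `seq_record`s in file order.
#' @export
read_sequences <- function(path, format = c("fasta", "phylip_relaxed"),
                           marker = "other") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         fasta = read_fasta_records(path, marker),
         phylip_relaxed = read_phylip_records(path, marker))
}

read_fasta_records <- function(path, marker) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    parts <- strsplit(header, "|", fixed = TRUE)[[1]]
    seq_record(id = parts[1],
               residues = as.character(set[[i]]),
               marker = marker,
               individual = if (length(parts) >= 2) parts[2] else "",
               site = if (length(parts) >= 3) parts[3] else "",
               genotype = if (length(parts) >= 4) parts[4] else "")
  })
}

read_phylip_records <- function(path, marker) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty Phylip file: ", path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
    stop("malformed Phylip header at line 1: '", lines[1], "'")
  n <- as.integer(hdr[1]); len <- as.integer(hdr[2])
  if (length(lines) - 1L < n)
    stop("Phylip file declares ", n, " sequences but has ",
         length(lines) - 1L, " data lines")
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    ln <- trimws(lines[i + 1L])
    m <- regmatches(ln, regexec("^(\\S+)\\s+(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("malformed Phylip record at line ", i + 1L, ": '", ln, "'")
    seqtxt <- gsub("\\s+", "", m[3])
    if (nchar(seqtxt) != len)
      stop("Phylip length mismatch at line ", i + 1L, ": got ",
           nchar(seqtxt), " residues, header says ", len)
    recs[[i]] <- seq_record(m[2], seqtxt, marker = marker)
  }
  ids <- vapply(recs, function(r) r$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sequence id in Phylip file: ", ids[duplicated(ids)][1])
  recs
}

#' Write sequences to FASTA or relaxed sequential Phylip
#'
#' Writers emit files their readers accept bit-exactly (round-trip identity
#' on canonical records). FASTA headers re-embed non-empty annotations as
#' `id|individual|site|genotype`.
#'
#' @inheritParams read_sequences
#' @param records List of `seq_record`s.
#' @export
write_sequences <- function(records, path,
                            format = c("fasta", "phylip_relaxed")) {
  format <- match.arg(format)
  if (inherits(records, "seq_record")) records <- list(records)
  if (format == "fasta") {
    headers <- vapply(records, function(r) {
      ann <- c(r$individual, r$site, r$genotype)
      if (any(nzchar(ann))) paste(c(r$id, ann), collapse = "|") else r$id
    }, character(1))
    writeLines(paste0(">", headers, "\n",
                      vapply(records, function(r) r$residues, character(1)),
                      collapse = "\n"), path)
  } else {
    lens <- vapply(records, function(r) nchar(r$residues), integer(1))
    if (length(unique(lens)) != 1L)
      stop("Phylip output needs equal-length sequences")
    writeLines(c(paste(length(records), lens[[1]]),
                 vapply(records, function(r)
                   paste(r$id, r$residues), character(1))), path)
  }
  invisible(path)
}

#' Read a site/metadata table
#'
#' Tab-separated with header columns `site_id`, `latitude`, `longitude`,
#' `individual`, `genotype` (extra columns are ignored with a warning).
#'
#' @param path TSV file.
#' @return `data.frame` of class `site_table` with typed columns.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("site_id", "latitude", "longitude", "individual", "genotype")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("site table missing required column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra))
    warning("ignoring extra site-table column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  df <- df[required]
  site_table(df$site_id, as.numeric(df$latitude), as.numeric(df$longitude),
             df$individual, df$genotype)
}

#' Construct a site table in code
#' @param site_id,individual,genotype Character vectors.
#' @param latitude,longitude Decimal degrees.
#' @return `data.frame` of class `site_table`.
#' @export
site_table <- function(site_id = character(), latitude = numeric(),
                       longitude = numeric(), individual = character(),
                       genotype = character()) {
  df <- data.frame(site_id = as.character(site_id),
                   latitude = as.numeric(latitude),
                   longitude = as.numeric(longitude),
                   individual = as.character(individual),
                   genotype = as.character(genotype),
                   stringsAsFactors = FALSE)
  bad_lat <- which(!is.na(df$latitude) & abs(df$latitude) > 90)
  if (length(bad_lat))
    stop("latitude out of [-90,90] at row ", bad_lat[1], ": ",
         df$latitude[bad_lat[1]])
  bad_lon <- which(!is.na(df$longitude) & abs(df$longitude) > 180)
  if (length(bad_lon))
    stop("longitude out of [-180,180] at row ", bad_lon[1], ": ",
         df$longitude[bad_lon[1]])
  key <- paste(df$site_id, df$individual, sep = "\r")
  if (nrow(df) && anyDuplicated(key))
    stop("duplicate (site_id, individual) pair: ",
         gsub("\r", "/", key[duplicated(key)][1]))
  class(df) <- c("site_table", "data.frame")
  df
}

#' Read a dot-bracket secondary structure
#'
#' Two-line record: sequence id, then a dot-bracket string over `.()`.
#' Brackets must balance and nest (pseudoknot-free).
#'
#' @param path Structure file.
#' @return Object of class `secondary_structure` with `seq_id`, `dotbracket`
#'   and `pairs` (two-column matrix of 0-based paired positions).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("structure file needs id line + dot-bracket line")
  secondary_structure(trimws(lines[1]), trimws(lines[2]))
}

#' Construct a secondary structure from a dot-bracket string
#' @param seq_id Id of the (ungapped) sequence the structure annotates.
#' @param dotbracket String over `.`, `(`, `)`.
#' @export
secondary_structure <- function(seq_id, dotbracket) {
  chars <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  if (any(!chars %in% c(".", "(", ")")))
    stop("dot-bracket string contains characters outside '.()'")
  structure(list(seq_id = seq_id, dotbracket = dotbracket,
                 pairs = dotbracket_pairs(chars)),
            class = "secondary_structure")
}

# Stack parse of a nested dot-bracket string; errors name the first
# offending 0-based index.
dotbracket_pairs <- function(chars) {
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k - 1L)
    } else if (chars[k] == ")") {
      if (!length(stack))
        stop("unbalanced ')' at index ", k - 1L)
      pairs <- rbind(pairs, c(stack[length(stack)], k - 1L))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    stop("unbalanced '(' at index ", stack[length(stack)],
         " (unclosed at end of string)")
  pairs[order(pairs[, 1]), , drop = FALSE]
}

#' Write a dot-bracket secondary structure file
#' @param structure A `secondary_structure`.
#' @param path Output file.
#' @export
write_structure <- function(structure, path) {
  writeLines(c(structure$seq_id, structure$dotbracket), path)
  invisible(path)
}
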