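# Bundled tables from a published field survey of the Anopheles
# longirostris morphospecies complex in Papua New Guinea: 302 specimens
# from 76 collection sites, genotyped at the ITS2 by Msp I PCR-RFLP and
# heteroduplex analysis into nine genotypes (A, B, C1, C2, D, E, F, G, H).
# They give the worked examples real numbers without any download.

survey_file <- function(name) {
  path <- system.file("extdata", "survey", name, package = "ribosplit")
  if (!nzchar(path)) stop("bundled survey file not found: ", name)
  path
}

#' Bundled survey: collection sites
#'
#' Collection sites of the Papua New Guinea *Anopheles longirostris*
#' survey: map site number, field site code, coordinates, and specimen
#' counts (`n_paren` are additional specimens not genotyped by RFLP).
#' @return `data.frame`.
#' @export
survey_sites <- function() {
  utils::read.delim(survey_file("collection_sites.tsv"),
                    stringsAsFactors = FALSE)
}

#' Bundled survey: ITS2 genotype abundance and distribution
#'
#' Specimen counts, relative frequencies and map sites of the nine ITS2
#' genotypes (the 302-specimen survey summary).
#' @return `data.frame`.
#' @export
survey_abundance <- function() {
  utils::read.delim(survey_file("genotype_abundance.tsv"),
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "integer", "numeric",
                                   "character"))
}

#' Bundled survey: sympatric genotype records
#'
#' Sites at which two or more ITS2 genotypes were collected together, as
#' published (unsubscripted `C` entries left verbatim; see
#' [survey_sympatry_site_table()] for the interpretation applied before
#' analysis).
#' @return `data.frame` with `site` and comma-separated `genotypes`.
#' @export
survey_sympatry <- function() {
  utils::read.delim(survey_file("sympatric_genotypes.tsv"),
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character"))
}

#' Bundled survey: RFLP band sizes per genotype
#'
#' Msp I band patterns of the nine ITS2 genotypes on a 3% agarose gel.
#' Bands printed only as "below 100 bp" are encoded `lt100`;
#' [survey_rflp_patterns()] returns the numeric patterns with such bands
#' dropped (they cannot anchor exact matching).
#' @return `data.frame` with `genotype` and comma-separated `bands`.
#' @export
survey_rflp_bands <- function() {
  utils::read.delim(survey_file("rflp_bands.tsv"),
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character"))
}

#' Numeric RFLP band patterns from the bundled survey
#' @return Named list `genotype -> integer vector of band sizes`
#'   (sub-100 bp bands of unstated size omitted).
#' @export
survey_rflp_patterns <- function() {
  tab <- survey_rflp_bands()
  out <- lapply(strsplit(tab$bands, ",", fixed = TRUE), function(b)
    sort(as.integer(b[b != "lt100"]), decreasing = TRUE))
  stats::setNames(out, tab$genotype)
}

#' Bundled survey: clones sequenced per genotype
#'
#' Total cloned ITS2 sequences per genotype (the H row was published
#' without counts and is `NA`).
#' @return `data.frame`.
#' @export
survey_clone_counts <- function() {
  utils::read.delim(survey_file("clone_counts.tsv"),
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "integer"))
}

#' Survey sympatry records as a site table
#'
#' Expands the sympatric-genotype records into a [site_table()] (one
#' synthetic individual per genotype-site pair, coordinates joined from
#' the collection-site table) ready for [cooccurrence()]. Unsubscripted
#' `C` entries are interpreted as `C2`, the widespread C subtype; pass
#' `c_as = "C1"` to override. Genotypes absent from the records (here F
#' and H, never collected in sympatry) are appended at their first
#' published map site so the co-occurrence report covers all nine
#' genotypes.
#'
#' @param c_as Genotype to substitute for unsubscripted `C` entries.
#' @return A `site_table`.
#' @export
survey_sympatry_site_table <- function(c_as = "C2") {
  sym <- survey_sympatry()
  sites <- survey_sites()
  abund <- survey_abundance()
  rows <- do.call(rbind, lapply(seq_len(nrow(sym)), function(i) {
    g <- strsplit(sym$genotypes[i], ",", fixed = TRUE)[[1]]
    g <- ifelse(g == "C", c_as, g)
    data.frame(site = sym$site[i], genotype = unique(g),
               stringsAsFactors = FALSE)
  }))
  missing <- setdiff(abund$genotype, rows$genotype)
  if (length(missing)) {
    first_site <- vapply(missing, function(g)
      strsplit(abund$map_sites[abund$genotype == g], ",")[[1]][1],
      character(1))
    rows <- rbind(rows, data.frame(site = first_site, genotype = missing,
                                   stringsAsFactors = FALSE))
  }
  coord <- sites[match(as.integer(rows$site), sites$map_site), ]
  site_table(site_id = rows$site,
             latitude = coord$latitude,
             longitude = coord$longitude,
             individual = paste0("rep_", rows$site, "_", rows$genotype),
             genotype = rows$genotype)
}
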