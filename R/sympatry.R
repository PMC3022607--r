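#' Genotype co-occurrence across collection sites
#'
#' Builds the presence side of a sympatry report: which genotypes occur at
#' each site, which genotypes share at least one site with another
#' genotype (sympatric), and with whom.
#'
#' @param st A `site_table`; every row must carry a genotype.
#' @return Object of class `sympatry_report`: `site_genotypes` (named list
#'   `site -> genotype set`), `genotypes`, `sympatric` (named logical),
#'   `partners` (named list).
#' @export
cooccurrence <- function(st) {
  stopifnot(inherits(st, "site_table"))
  if (any(!nzchar(st$genotype)))
    stop("every site-table row must carry a genotype")
  site_genotypes <- lapply(split(st$genotype, st$site_id),
                           function(g) sort(unique(g)))
  genotypes <- sort(unique(st$genotype))
  partners <- stats::setNames(vector("list", length(genotypes)), genotypes)
  for (g in genotypes) partners[[g]] <- character(0)
  for (gs in site_genotypes) {
    if (length(gs) < 2L) next
    for (g in gs) partners[[g]] <- sort(union(partners[[g]], setdiff(gs, g)))
  }
  structure(list(site_genotypes = site_genotypes,
                 genotypes = genotypes,
                 sympatric = vapply(partners, function(p) length(p) > 0L,
                                    logical(1)),
                 partners = partners,
                 isolation_evidence = NULL, reasons = NULL),
            class = "sympatry_report")
}

#' @export
print.sympatry_report <- function(x, ...) {
  cat(sprintf("<sympatry_report: %d genotypes, %d sympatric (%s)>\n",
              length(x$genotypes), sum(x$sympatric),
              paste(names(x$sympatric)[x$sympatric], collapse = ", ")))
  if (!is.null(x$isolation_evidence))
    cat(sprintf("  isolation evidence: %s\n",
                paste(names(x$isolation_evidence)[x$isolation_evidence],
                      collapse = ", ")))
  invisible(x)
}

#' Score per-genotype evidence of reproductive isolation
#'
#' A genotype shows evidence of reproductive isolation at the rDNA locus
#' when (i) it is sympatric with at least one other genotype, (ii) it
#' shares no ITS2 sequence class with any sympatric partner (no ancestral
#' polymorphism or ongoing gene flow at the array), and (iii) no
#' individual of the genotype carries a hybrid RFLP profile — a band
#' pattern equal, within comigration tolerance, to the union of two
#' genotypes' patterns, which is what an F1 between them would show.
#'
#' @param report A `sympatry_report` from [cooccurrence()].
#' @param st The `site_table` behind the report (maps individuals to
#'   genotypes).
#' @param its2_classes Named list `individual -> character vector of ITS2
#'   sequence classes` (e.g. distinct clone sequences); classes are shared
#'   iff the same class string occurs in two genotypes.
#' @param rflp_profiles Named list `individual -> integer vector of
#'   visible bands`.
#' @param genotype_profiles Named list `genotype -> representative band
#'   pattern`; defaults to the first individual's profile per genotype.
#' @param gel A `gel_model` for band comparison.
#' @return The report with `isolation_evidence` (named logical) and
#'   `reasons` (named character) filled in.
#' @export
isolation_evidence <- function(report, st, its2_classes, rflp_profiles,
                               genotype_profiles = NULL, gel = gel_model()) {
  stopifnot(inherits(report, "sympatry_report"), inherits(st, "site_table"))
  indiv_geno <- stats::setNames(st$genotype, st$individual)
  missing_cls <- setdiff(names(indiv_geno), names(its2_classes))
  if (length(missing_cls))
    stop("missing ITS2 class for individual(s): ",
         paste(missing_cls, collapse = ", "))
  if (is.null(genotype_profiles)) {
    genotype_profiles <- lapply(
      split(names(indiv_geno), indiv_geno),
      function(ids) {
        ids <- intersect(ids, names(rflp_profiles))
        if (length(ids)) rflp_profiles[[ids[1]]] else integer(0)
      })
  }
  geno_classes <- lapply(split(names(indiv_geno), indiv_geno), function(ids)
    unique(unlist(its2_classes[ids], use.names = FALSE)))

  evidence <- stats::setNames(logical(length(report$genotypes)),
                              report$genotypes)
  reasons <- stats::setNames(character(length(report$genotypes)),
                             report$genotypes)
  hybrid_flagged <- character(0)
  # hybrid scan: an individual of genotype g whose bands equal the
  # gel-merged union of g's profile with another genotype's (what an F1
  # between the two would show); third-party coincidences do not count
  geno_names <- names(genotype_profiles)
  for (ind in names(rflp_profiles)) {
    g_ind <- indiv_geno[[ind]]
    if (is.null(g_ind) || !g_ind %in% geno_names) next
    for (other in setdiff(geno_names, g_ind)) {
      un <- gel_bands(c(genotype_profiles[[g_ind]],
                        genotype_profiles[[other]]), gel)
      if (length(un) > max(length(genotype_profiles[[g_ind]]),
                           length(genotype_profiles[[other]])) &&
          bands_match(rflp_profiles[[ind]], un, gel)) {
        hybrid_flagged <- union(hybrid_flagged, c(g_ind, other))
      }
    }
  }
  for (g in report$genotypes) {
    if (!report$sympatric[g]) {
      evidence[g] <- FALSE; reasons[g] <- "never sympatric"
      next
    }
    shared <- unlist(lapply(report$partners[[g]], function(p)
      intersect(geno_classes[[g]], geno_classes[[p]])), use.names = FALSE)
    if (length(shared)) {
      evidence[g] <- FALSE
      reasons[g] <- "shares ITS2 sequence class with a sympatric partner"
    } else if (g %in% hybrid_flagged) {
      evidence[g] <- FALSE
      reasons[g] <- "hybrid RFLP profile observed"
    } else {
      evidence[g] <- TRUE
      reasons[g] <- "sympatric; no shared ITS2 class; no hybrid profile"
    }
  }
  report$isolation_evidence <- evidence
  report$reasons <- reasons
  report
}
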