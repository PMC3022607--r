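# End-to-end orchestration: simulate (or load) -> RFLP digest/cluster ->
# heteroduplex signatures/fixation -> alignment statistics -> distances,
# tree, monophyly -> sympatry/isolation -> consolidated report.

majority_sequence <- function(seqs) {
  tab <- table(seqs)
  names(tab)[order(-as.integer(tab), names(tab))][1]
}

#' Assign ITS2 genotypes by RFLP class refined by heteroduplex signature
#'
#' Individuals are first clustered by the Msp I band pattern of their
#' majority ITS2 amplicon ([cluster_profiles()]); within each RFLP class,
#' individuals are then split by heteroduplex signature, mirroring how
#' copy-variant profiling resolves genotypes a restriction digest cannot
#' (one RFLP class harbouring two signature classes becomes e.g. `C1`,
#' `C2`). The signature partition therefore always refines the RFLP
#' partition, never coarsens it.
#'
#' @param clones List of ITS2 `seq_record`s whose `individual` field
#'   groups them.
#' @param enz,gel Digest model.
#' @param scoring Alignment scoring for variant calling.
#' @return List: `rflp_class`, `genotype` (named by individual),
#'   `profiles` (bands per individual), `variant_sets`, `signatures`.
#' @export
assign_genotypes <- function(clones, enz = msp_i(), gel = gel_model(),
                             scoring = c(1, -1, -4, -1)) {
  indivs <- vapply(clones, function(r) r$individual, character(1))
  if (any(!nzchar(indivs)))
    stop("every clone must carry an individual annotation")
  by_ind <- split(clones, indivs)

  profiles <- lapply(by_ind, function(cl) {
    amp <- majority_sequence(residues_of(cl))
    digest(seq_record(cl[[1]]$individual, amp), enz, gel)$visible_bands
  })
  rflp <- cluster_profiles(profiles, gel)

  variant_sets <- lapply(by_ind, call_variants, scoring = scoring)
  signatures <- lapply(variant_sets, duplex_signature, scoring = scoring)

  genotype <- rflp
  for (cls in unique(rflp)) {
    members <- names(rflp)[rflp == cls]
    sig_keys <- vapply(signatures[members], signature_string, character(1))
    distinct <- unique(sig_keys)
    if (length(distinct) > 1L)
      genotype[members] <- paste0(cls, match(sig_keys, distinct))
  }
  list(rflp_class = rflp, genotype = genotype, profiles = profiles,
       variant_sets = variant_sets, signatures = signatures)
}

#' Run the whole delimitation pipeline
#'
#' Executes every stage in dependency order on either a simulated dataset
#' (pass a [sim_config()] or a `sim_dataset`) or loaded data (pass a list
#' with `clones`, `coi`, `sites` as produced by the readers). Stages that
#' lack their inputs (e.g. sympatry with an empty site table, ITS2 column
#' statistics when clone amplicons differ in length and no alignment is
#' supplied) are skipped with a notice rather than aborting the run.
#'
#' @param x A `sim_config`, `sim_dataset`, or list with elements `clones`
#'   (list of ITS2 `seq_record`s), `coi` (list of equal-length COI
#'   `seq_record`s) and optionally `sites` (a `site_table`).
#' @param enz,gel Digest model.
#' @param scoring Alignment scoring.
#' @param n_boot Bootstrap replicates for the COI tree.
#' @param boot_seed Seed for bootstrap resampling.
#' @param outdir Optional directory; when given, intermediate artifacts
#'   (FASTA, TSV, Newick, JSON report) are written there.
#' @return Object of class `pipeline_report`.
#' @export
run_pipeline <- function(x, enz = msp_i(), gel = gel_model(),
                         scoring = c(1, -1, -4, -1),
                         n_boot = 100L, boot_seed = 1L, outdir = NULL) {
  seed_used <- NA_integer_
  if (inherits(x, "sim_config")) {
    seed_used <- x$seed
    x <- simulate_dataset(x)
  }
  clones <- x$clones; coi <- x$coi
  sites <- if (!is.null(x$sites)) x$sites else NULL
  notices <- character(0)

  # -- RFLP + signatures -----------------------------------------------------
  gt <- assign_genotypes(clones, enz, gel, scoring)
  n_rflp <- length(unique(gt$rflp_class))
  n_geno <- length(unique(gt$genotype))

  # -- fixation within each genotype -----------------------------------------
  fixation <- lapply(split(names(gt$genotype), gt$genotype), function(ids) {
    if (length(ids) < 2L)
      return(list(fixed = NA, witness = character(0)))
    fixation_test(gt$variant_sets[ids], scoring)
  })

  # -- alignment statistics --------------------------------------------------
  coi_aln <- multiple_alignment(coi)
  coi_stats <- classify_columns(coi_aln)
  coi_haplo <- collapse_haplotypes(coi_aln)
  its2_stats <- NULL
  clone_lens <- nchar(residues_of(clones))
  if (length(unique(clone_lens)) == 1L) {
    its2_stats <- classify_columns(multiple_alignment(clones))
  } else {
    notices <- c(notices,
                 "ITS2 clone amplicons differ in length; column statistics skipped (supply an alignment)")
  }
  its2_gc <- gc_content(clones)

  # -- distances, tree, monophyly --------------------------------------------
  ind_of_coi <- vapply(coi, function(r) r$individual, character(1))
  coi_labels <- stats::setNames(gt$genotype[ind_of_coi],
                                vapply(coi, function(r) r$id, character(1)))
  dm <- pairwise_steps(coi_aln)
  divergence <- divergence_summary(dm, coi_labels)
  tree <- bootstrap_support(coi_aln, n_reps = n_boot, seed = boot_seed)
  mono <- monophyly(tree, coi_labels)

  # -- sympatry / isolation --------------------------------------------------
  sympatry <- NULL
  if (!is.null(sites) && nrow(sites) > 0L) {
    st <- sites
    st$genotype <- unname(gt$genotype[st$individual])  # pipeline-assigned
    st <- site_table(st$site_id, st$latitude, st$longitude,
                     st$individual, st$genotype)
    its2_classes <- lapply(split(clones,
                                 vapply(clones, function(r) r$individual,
                                        character(1))),
                           function(cl) unique(unname(residues_of(cl))))
    sympatry <- isolation_evidence(cooccurrence(st), st, its2_classes,
                                   gt$profiles, gel = gel)
  } else {
    notices <- c(notices, "empty site table; sympatry stage skipped")
  }

  report <- structure(list(
    n_rflp_classes = n_rflp,
    n_signature_classes = n_geno,
    genotype = gt$genotype,
    rflp_class = gt$rflp_class,
    profiles = gt$profiles,
    signatures = gt$signatures,
    variant_sets = gt$variant_sets,
    fixation = fixation,
    its2_stats = its2_stats,
    its2_gc = its2_gc,
    coi_stats = coi_stats,
    coi_haplotypes = coi_haplo,
    distance_matrix = dm,
    divergence = divergence,
    tree = tree,
    monophyly = mono,
    sympatry = sympatry,
    notices = notices,
    provenance = list(seed = seed_used, n_boot = n_boot,
                      boot_seed = boot_seed,
                      version = as.character(utils::packageVersion("ribosplit")))
  ), class = "pipeline_report")
  if (!is.null(outdir)) write_report(report, x, outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== ribosplit pipeline report ==\n")
  cat(sprintf("RFLP classes: %d; genotypes after signature refinement: %d\n",
              x$n_rflp_classes, x$n_signature_classes))
  fx <- vapply(x$fixation, function(f) f$fixed, logical(1))
  cat(sprintf("Copy variants fixed within genotype: %d/%d (%s)\n",
              sum(fx, na.rm = TRUE), sum(!is.na(fx)),
              paste(names(fx)[which(!is.na(fx) & fx)], collapse = ", ")))
  print(x$coi_stats)
  cat(sprintf("COI haplotypes: %d\n", x$coi_haplotypes$n_haplotypes))
  cat(sprintf("Monophyletic genotypes on the COI tree: %d/%d\n",
              sum(x$monophyly$monophyletic), nrow(x$monophyly)))
  print(x$divergence)
  if (!is.null(x$sympatry)) print(x$sympatry)
  for (n in x$notices) cat("note: ", n, "\n", sep = "")
  invisible(x)
}

#' Serialize a pipeline report (plus artifacts) to a directory
#' @param report A `pipeline_report`.
#' @param dataset The dataset the report was computed from.
#' @param outdir Output directory (created if needed).
#' @export
write_report <- function(report, dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(dataset$clones))
    write_sequences(dataset$clones, file.path(outdir, "clones.fasta"))
  if (!is.null(dataset$coi))
    write_sequences(dataset$coi, file.path(outdir, "coi.fasta"))
  ape::write.tree(report$tree, file.path(outdir, "coi_nj.nwk"))
  fx <- vapply(report$fixation, function(f) f$fixed, logical(1))
  summary <- list(
    n_rflp_classes = report$n_rflp_classes,
    n_signature_classes = report$n_signature_classes,
    genotypes = as.list(report$genotype),
    fixation = as.list(fx),
    coi = list(n_haplotypes = report$coi_haplotypes$n_haplotypes,
               n_constant = report$coi_stats$n_constant,
               n_pi = report$coi_stats$n_parsimony_informative,
               n_vu = report$coi_stats$n_variable_uninformative),
    monophyletic = stats::setNames(as.list(report$monophyly$monophyletic),
                                   report$monophyly$group),
    barcode_gap = as.list(report$divergence$barcode_gap),
    isolation_evidence = if (!is.null(report$sympatry))
      as.list(report$sympatry$isolation_evidence) else NULL,
    provenance = report$provenance)
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
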