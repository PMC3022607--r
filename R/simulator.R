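# Seedable simulator of rDNA spacer arrays evolving under incomplete
# concerted evolution, plus a faster single-copy mitochondrial locus on the
# same species tree. Every emitted dataset carries a truth table so each
# pipeline stage can be checked against known answers.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulator configuration
#'
#' Parameterizes the concerted-evolution simulator. Time is measured in
#' units of the species-tree depth (trees are rescaled so the root-to-tip
#' distance is 1), so a rate of `r` per site means an expected `r`
#' substitutions per site from root to tip on a single un-homogenized copy.
#'
#' @param n_species Number of species (>= 2).
#' @param tree Optional Newick string; when `NULL` a Yule tree is drawn.
#' @param birth_rate Yule birth rate used when `tree` is `NULL`.
#' @param spacer_length Spacer length in bp of the ancestral array copy.
#' @param gc_target Ancestral GC fraction of the spacer.
#' @param array_copies Number of spacer copies per rDNA array.
#' @param sub_rate_rdna Per-site, per-copy substitution rate of the spacer.
#' @param conversion_rate Gene-conversion events per array per unit time
#'   (intrachromosomal: a random donor copy overwrites a random recipient).
#' @param conversion_tract `"whole_spacer"` or `"geometric"` (tract length
#'   geometric with mean `conversion_tract_mean`).
#' @param conversion_tract_mean Mean tract length (bp) for geometric tracts.
#' @param ancestral_cut_sites Number of `CCGG` motifs written into the
#'   ancestral spacer at evenly spread positions, so amplicons start from a
#'   multi-band restriction pattern whose turnover then differentiates
#'   species (chance occurrences add to these).
#' @param indel_rate Tandem indel events per copy per unit time
#'   (duplication or deletion of an adjacent motif).
#' @param indel_size_range Inclusive bp range of indel sizes.
#' @param sub_rate_coi Per-site substitution rate of the single-copy
#'   mitochondrial locus (defaults to 5x the spacer rate).
#' @param kappa Transition/transversion ratio of the K2P substitution model.
#' @param coi_length Length of the mitochondrial locus (bp).
#' @param individuals_per_species,clones_per_individual Sampling design.
#' @param within_species_noise Per-site substitution probability applied to
#'   each individual's array copy (0 keeps arrays species-fixed).
#' @param pcr_error Per-site error probability applied independently per
#'   clone (polymerase artifact).
#' @param coi_individual_depth Extra terminal branch (time units) evolved
#'   privately per individual at the mitochondrial locus, giving realistic
#'   within-species haplotype diversity.
#' @param n_sites Number of collection sites.
#' @param sympatry_overlap Expected fraction of sites housing >= 2 species.
#' @param primer_pad Conserved flank (bp) added to each side of the spacer
#'   so amplicons resemble a real PCR product (620 + 2x30 = 680 bp).
#' @param codon_aware Reject mitochondrial substitutions creating in-frame
#'   stop codons (invertebrate mitochondrial code).
#' @param seed Integer master seed; identical configs give byte-identical
#'   datasets.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_species = 5L, tree = NULL, birth_rate = 1,
                       spacer_length = 620L, gc_target = 0.62,
                       array_copies = 20L,
                       sub_rate_rdna = 0.03, conversion_rate = 9000,
                       conversion_tract = c("whole_spacer", "geometric"),
                       conversion_tract_mean = 100,
                       ancestral_cut_sites = 4L,
                       indel_rate = 2, indel_size_range = c(1L, 10L),
                       sub_rate_coi = 5 * sub_rate_rdna, kappa = 2,
                       coi_length = 524L,
                       individuals_per_species = 3L,
                       clones_per_individual = 5L,
                       within_species_noise = 0, pcr_error = 0,
                       coi_individual_depth = 0.05,
                       n_sites = 10L, sympatry_overlap = 0.5,
                       primer_pad = 30L, codon_aware = FALSE, seed = 1L) {
  conversion_tract <- match.arg(conversion_tract)
  cfg <- list(n_species = as.integer(n_species), tree = tree,
              birth_rate = birth_rate,
              spacer_length = as.integer(spacer_length),
              gc_target = gc_target, array_copies = as.integer(array_copies),
              sub_rate_rdna = sub_rate_rdna,
              conversion_rate = conversion_rate,
              conversion_tract = conversion_tract,
              conversion_tract_mean = conversion_tract_mean,
              ancestral_cut_sites = as.integer(ancestral_cut_sites),
              indel_rate = indel_rate,
              indel_size_range = as.integer(indel_size_range),
              sub_rate_coi = sub_rate_coi, kappa = kappa,
              coi_length = as.integer(coi_length),
              individuals_per_species = as.integer(individuals_per_species),
              clones_per_individual = as.integer(clones_per_individual),
              within_species_noise = within_species_noise,
              pcr_error = pcr_error,
              coi_individual_depth = coi_individual_depth,
              n_sites = as.integer(n_sites),
              sympatry_overlap = sympatry_overlap,
              primer_pad = as.integer(primer_pad),
              codon_aware = isTRUE(codon_aware),
              seed = as.integer(seed))
  stopifnot(cfg$n_species >= 2L, cfg$array_copies >= 2L,
            cfg$sub_rate_rdna >= 0, cfg$conversion_rate >= 0,
            cfg$indel_rate >= 0, cfg$sub_rate_coi >= 0,
            cfg$gc_target >= 0, cfg$gc_target <= 1,
            cfg$within_species_noise >= 0, cfg$within_species_noise <= 1,
              cfg$pcr_error >= 0, cfg$pcr_error <= 1,
            cfg$sympatry_overlap >= 0, cfg$sympatry_overlap <= 1,
            length(cfg$indel_size_range) == 2L,
            cfg$indel_size_range[1] >= 1L,
            cfg$indel_size_range[2] >= cfg$indel_size_range[1])
  structure(cfg, class = "sim_config")
}

#' Simulate (or validate) the species tree
#'
#' Draws an ultrametric Yule (pure-birth) tree with `n_species` leaves
#' labelled `sp1..spN`, rescaled to unit depth; or parses and echoes a
#' supplied Newick tree after validation.
#'
#' @param config A `sim_config`.
#' @return An `ape` `phylo` tree.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$tree)) {
    tr <- tryCatch(ape::read.tree(text = config$tree),
                   error = function(e) NULL)
    if (is.null(tr) || is.null(tr$edge.length))
      stop("malformed supplied tree: ", config$tree)
    return(tr)
  }
  tr <- with_seed(config$seed, {
    t0 <- ape::rphylo(config$n_species, birth = config$birth_rate,
                      death = 0)
    t0
  })
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- paste0("sp", seq_len(config$n_species))
  tr
}

# -- sequence helpers --------------------------------------------------------

# Exact-composition draw: the realized GC fraction equals the target up to
# rounding, so base composition is a controlled property of the dataset.
random_dna <- function(n, gc) {
  n_g <- round(n * gc / 2); n_c <- round(n * gc) - n_g
  n_a <- (n - n_g - n_c) %/% 2; n_t <- n - n_g - n_c - n_a
  paste(sample(rep(c("G", "C", "A", "T"), c(n_g, n_c, n_a, n_t))),
        collapse = "")
}

# K2P mutant of a single base: transition with prob kappa/(kappa+2).
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
k2p_mutate_base <- function(base, kappa) {
  if (stats::runif(1) < kappa / (kappa + 2)) return(TRANSITION[[base]])
  tv <- setdiff(c("A", "C", "G", "T"), c(base, TRANSITION[[base]]))
  tv[sample.int(2L, 1L)]
}

substitute_at <- function(s, pos, kappa) {
  base <- substr(s, pos, pos)
  paste0(substr(s, 1L, pos - 1L), k2p_mutate_base(base, kappa),
         substr(s, pos + 1L, nchar(s)))
}

# Tandem indel: duplication inserts a copy of an adjacent motif, deletion
# removes one. Copies are kept at >= 2x the maximum indel size.
tandem_indel <- function(s, size_range) {
  L <- nchar(s)
  size <- sample(seq.int(size_range[1], size_range[2]), 1L)
  if (stats::runif(1) < 0.5 && L > 2L * size_range[2]) {   # deletion
    pos <- sample.int(L - size + 1L, 1L)
    paste0(substr(s, 1L, pos - 1L), substr(s, pos + size, L))
  } else {                                                  # duplication
    pos <- sample.int(L - size + 1L, 1L)
    motif <- substr(s, pos, pos + size - 1L)
    paste0(substr(s, 1L, pos + size - 1L), motif, substr(s, pos + size, L))
  }
}

# Tract gene conversion: a geometric tract of the donor overwrites the
# recipient at shared coordinates (up to the shorter copy's length).
convert_copy_tract <- function(copies, pick, config) {
  donor <- copies[pick[1]]; recip <- copies[pick[2]]
  L <- min(nchar(donor), nchar(recip))
  tract <- max(1L, stats::rgeom(1L, 1 / config$conversion_tract_mean) + 1L)
  start <- sample.int(L, 1L)
  end <- min(L, start + tract - 1L)
  copies[pick[2]] <- paste0(substr(recip, 1L, start - 1L),
                            substr(donor, start, end),
                            substr(recip, end + 1L, nchar(recip)))
  copies
}

# Stochastic walk of one array along one branch: per-copy substitutions,
# array-level gene conversions, per-copy tandem indels. Event counts are
# drawn from the jump chain with rates frozen at branch entry (indels move
# total array length by well under 1%, so the frozen-rate approximation to
# exact waiting times is second-order), then applied in random order.
evolve_array_branch <- function(copies, t, config) {
  if (t <= 0) return(copies)
  if (config$sub_rate_rdna * t > 0.5)
    warning("branch of length ", signif(t, 3),
            " expects > 0.5 substitutions/site (saturation)", call. = FALSE)
  n <- length(copies)
  lens <- nchar(copies)
  n_sub <- stats::rpois(1L, config$sub_rate_rdna * sum(lens) * t)
  n_conv <- stats::rpois(1L, config$conversion_rate * t)
  n_ind <- stats::rpois(1L, config$indel_rate * n * t)
  n_ev <- n_sub + n_conv + n_ind
  if (n_ev == 0L) return(copies)
  kind <- sample(rep.int(c(1L, 2L, 3L), c(n_sub, n_conv, n_ind)))
  whole <- config$conversion_tract == "whole_spacer"
  for (e in kind) {
    if (e == 2L) {                      # gene conversion (the common event)
      pick <- sample.int(n, 2L)
      if (whole) {
        copies[pick[2]] <- copies[pick[1]]
        lens[pick[2]] <- lens[pick[1]]
      } else {
        copies <- convert_copy_tract(copies, pick, config)
        lens[pick[2]] <- nchar(copies[pick[2]])
      }
    } else if (e == 1L) {               # substitution
      k <- sample.int(n, 1L, prob = lens)
      pos <- sample.int(lens[k], 1L)
      copies[k] <- substitute_at(copies[k], pos, config$kappa)
    } else {                            # tandem indel
      k <- sample.int(n, 1L)
      copies[k] <- tandem_indel(copies[k], config$indel_size_range)
      lens[k] <- nchar(copies[k])
    }
  }
  copies
}

# Poisson substitutions on a single-copy locus along one branch.
evolve_seq_branch <- function(s, t, rate, config) {
  if (t <= 0 || rate <= 0) return(s)
  n_sub <- stats::rpois(1L, rate * nchar(s) * t)
  for (i in seq_len(n_sub)) {
    repeat {
      pos <- sample.int(nchar(s), 1L)
      cand <- substitute_at(s, pos, config$kappa)
      if (!config$codon_aware || !has_inframe_stop(cand)) break
    }
    s <- cand
  }
  s
}

has_inframe_stop <- function(s) {
  L <- nchar(s) - nchar(s) %% 3L
  if (L < 3L) return(FALSE)
  codons <- substring(s, seq(1L, L, 3L), seq(3L, L, 3L))
  any(codons %in% c("TAA", "TAG"))   # stops of the invertebrate mito code
}

# Group identical copies into variant classes (majority first, ties by
# lexicographically smallest representative).
array_classes <- function(copies) {
  tab <- table(copies)
  ord <- order(-as.integer(tab), names(tab))
  list(representatives = names(tab)[ord],
       counts = as.integer(tab)[ord])
}

#' Evolve rDNA arrays along the species tree
#'
#' The ancestral array is `array_copies` identical spacers drawn at the
#' target GC content. Along each branch the array accumulates per-copy
#' substitutions (K2P), intrachromosomal gene conversions (a random donor
#' copy overwrites a random recipient — the homogenizing force) and tandem
#' indels, via an exact Gillespie scheme. Each leaf yields the species
#' array together with its copy-variant classes relative to the majority
#' copy.
#'
#' @param tree `phylo` from [simulate_tree()].
#' @param config A `sim_config`.
#' @return Object of class `sim_arrays`: `arrays` (named list
#'   `species -> character vector of copies`), `classes` (per species:
#'   representatives, counts, diff events vs majority), `ancestor`,
#'   `pads` (5' and 3' conserved flanks), `tree`.
#' @export
evolve_arrays <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    ancestor <- random_dna(config$spacer_length, config$gc_target)
    if (config$ancestral_cut_sites > 0L) {
      k <- config$ancestral_cut_sites
      at <- round(config$spacer_length * seq_len(k) / (k + 1)) +
        sample(-15:15, k, replace = TRUE)
      for (p in at)
        ancestor <- paste0(substr(ancestor, 1L, p - 1L), "CCGG",
                           substr(ancestor, p + 4L, nchar(ancestor)))
    }
    pads <- c(p5 = random_dna(config$primer_pad, 0.5),
              p3 = random_dna(config$primer_pad, 0.5))
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    states <- vector("list", n_tip + tree$Nnode)
    states[[root]] <- rep(ancestor, config$array_copies)
    # preorder edge walk
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    edge_len <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1]; child <- edges[e, 2]
      states[[child]] <- evolve_array_branch(states[[parent]],
                                             edge_len[e], config)
    }
    arrays <- stats::setNames(states[seq_len(n_tip)], tree$tip.label)
    classes <- lapply(arrays, function(copies) {
      cl <- array_classes(copies)
      cl$diff_events <- lapply(seq_along(cl$representatives), function(k) {
        if (k == 1L) alignment_events(cl$representatives[1],
                                      cl$representatives[1])
        else align_pair(cl$representatives[1],
                        cl$representatives[k])$events
      })
      cl
    })
    structure(list(arrays = arrays, classes = classes,
                   ancestor = ancestor, pads = pads, tree = tree),
              class = "sim_arrays")
  })
}

#' Plant known-answer features into simulated arrays
#'
#' Requests (applied in order):
#' \describe{
#'   \item{`add_cut_site(species, position)`}{write a `CCGG` motif at the
#'     0-based spacer position in every copy of the species.}
#'   \item{`add_cbc(species_a, species_b, i, j)`}{set positions `i < j`
#'     (0-based, spacer coordinates) to `G`/`C` in species A and `A`/`T`
#'     in species B in all copies — a compensatory double substitution
#'     that keeps canonical pairing on a structure pairing (i, j).}
#'   \item{`add_fixed_variant(species, position, size)`}{append to the
#'     species array a copy carrying a tandem duplication of `size` bp at
#'     `position`, fixed in the species (the heteroduplex-refinement
#'     phenomenon).}
#'   \item{`add_private_variant(individual)`}{mark one individual (e.g.
#'     `"sp1_i2"`) so that, at emission, one of its array copies gains a
#'     private 2 bp deletion — breaking fixation for that species.}
#'   \item{`clone_array(from_species, to_species)`}{overwrite one species'
#'     array with another's, so the two share a digest pattern.}
#' }
#'
#' @param sim A `sim_arrays`.
#' @param requests List of lists, each with an `op` field naming the
#'   request and its arguments (see above).
#' @return The modified `sim_arrays`, with `engineered` describing every
#'   applied feature (the truth record for acceptance checks).
#' @export
engineer_features <- function(sim, requests) {
  stopifnot(inherits(sim, "sim_arrays"))
  engineered <- list()
  for (rq in requests) {
    op <- rq$op
    if (op == "add_cut_site") {
      sp <- rq$species; pos <- rq$position
      if (pos < 0L || pos + 4L > min(nchar(sim$arrays[[sp]])))
        stop("add_cut_site position out of range for ", sp)
      sim$arrays[[sp]] <- vapply(sim$arrays[[sp]], function(s)
        paste0(substr(s, 1L, pos), "CCGG", substr(s, pos + 5L, nchar(s))),
        character(1), USE.NAMES = FALSE)
    } else if (op == "add_cbc") {
      i <- rq$i; j <- rq$j
      stopifnot(i < j)
      put <- function(s, pos, ch)
        paste0(substr(s, 1L, pos), ch, substr(s, pos + 2L, nchar(s)))
      sim$arrays[[rq$species_a]] <- vapply(sim$arrays[[rq$species_a]],
        function(s) put(put(s, i, "G"), j, "C"), character(1),
        USE.NAMES = FALSE)
      sim$arrays[[rq$species_b]] <- vapply(sim$arrays[[rq$species_b]],
        function(s) put(put(s, i, "A"), j, "T"), character(1),
        USE.NAMES = FALSE)
    } else if (op == "add_fixed_variant") {
      sp <- rq$species; pos <- rq$position; size <- rq$size
      base <- sim$arrays[[sp]][1]
      motif <- substr(base, pos + 1L, pos + size)
      variant <- paste0(substr(base, 1L, pos + size), motif,
                        substr(base, pos + size + 1L, nchar(base)))
      n_var <- max(2L, ceiling(length(sim$arrays[[sp]]) / 4))
      sim$arrays[[sp]][seq_len(n_var)] <- variant
    } else if (op == "add_private_variant") {
      # applied at emission; just recorded here
    } else if (op == "clone_array") {
      sim$arrays[[rq$to_species]] <- sim$arrays[[rq$from_species]]
    } else {
      stop("unknown engineering request: ", op)
    }
    engineered[[length(engineered) + 1L]] <- rq
  }
  # refresh variant classes for touched species
  sim$classes <- lapply(sim$arrays, function(copies) {
    cl <- array_classes(copies)
    cl$diff_events <- lapply(seq_along(cl$representatives), function(k) {
      if (k == 1L) alignment_events(cl$representatives[1],
                                    cl$representatives[1])
      else align_pair(cl$representatives[1],
                      cl$representatives[k])$events
    })
    cl
  })
  sim$engineered <- c(sim$engineered, engineered)
  sim
}

apply_noise <- function(s, per_site, kappa) {
  n <- stats::rbinom(1L, nchar(s), per_site)
  for (i in seq_len(n))
    s <- substitute_at(s, sample.int(nchar(s), 1L), kappa)
  s
}

#' Emit a full synthetic dataset
#'
#' Samples individuals and clones from the species arrays, evolves the
#' mitochondrial locus on the same tree, assigns individuals to collection
#' sites with the requested sympatric overlap, and returns everything with
#' a truth table.
#'
#' Clone FASTA ids follow the `id|individual|site|genotype` convention with
#' the true species as genotype, so the pipeline can be scored against
#' truth.
#'
#' @param sim A `sim_arrays` (possibly after [engineer_features()]).
#' @param config The same `sim_config`.
#' @return Object of class `sim_dataset`: `clones` (list of `seq_record`,
#'   ITS2 amplicons), `coi` (list of `seq_record`), `sites`
#'   (`site_table`), `truth` (`data.frame`), `tree`, `classes`,
#'   `engineered`.
#' @export
emit_dataset <- function(sim, config) {
  stopifnot(inherits(sim, "sim_arrays"), inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    species <- names(sim$arrays)
    n_sp <- length(species)
    private_ind <- vapply(Filter(function(r) r$op == "add_private_variant",
                                 sim$engineered %||% list()),
                          function(r) r$individual, character(1))

    # -- collection sites ----------------------------------------------------
    primary <- species[(seq_len(config$n_sites) - 1L) %% n_sp + 1L]
    secondary <- rep(NA_character_, config$n_sites)
    multi <- stats::runif(config$n_sites) < config$sympatry_overlap
    for (k in which(multi))
      secondary[k] <- sample(setdiff(species, primary[k]), 1L)
    site_ids <- sprintf("site%02d", seq_len(config$n_sites))
    site_lat <- stats::runif(config$n_sites, -10, -2)
    site_lon <- stats::runif(config$n_sites, 141, 150)
    sites_of <- lapply(stats::setNames(species, species), function(sp)
      site_ids[primary == sp | (!is.na(secondary) & secondary == sp)])

    # -- mitochondrial locus -------------------------------------------------
    coi_anc <- random_dna(config$coi_length, 0.35)
    n_tip <- length(sim$tree$tip.label)
    states <- vector("list", n_tip + sim$tree$Nnode)
    states[[n_tip + 1L]] <- coi_anc
    tr <- ape::reorder.phylo(sim$tree, "cladewise")
    for (e in seq_len(nrow(tr$edge)))
      states[[tr$edge[e, 2]]] <- evolve_seq_branch(
        states[[tr$edge[e, 1]]], tr$edge.length[e],
        config$sub_rate_coi, config)
    coi_species <- stats::setNames(states[seq_len(n_tip)],
                                   sim$tree$tip.label)

    clones <- list(); coi <- list(); truth <- list()
    st_site <- character(0); st_ind <- character(0); st_geno <- character(0)
    for (sp in species) {
      cl_reps <- array_classes(sim$arrays[[sp]])$representatives
      for (ii in seq_len(config$individuals_per_species)) {
        ind <- sprintf("%s_i%d", sp, ii)
        ind_sites <- sites_of[[sp]]
        site <- ind_sites[(ii - 1L) %% length(ind_sites) + 1L]
        st_site <- c(st_site, site); st_ind <- c(st_ind, ind)
        st_geno <- c(st_geno, sp)
        array <- sim$arrays[[sp]]
        if (config$within_species_noise > 0)
          array <- vapply(array, apply_noise,
                          per_site = config$within_species_noise,
                          kappa = config$kappa, character(1),
                          USE.NAMES = FALSE)
        if (ind %in% private_ind) {
          k <- 1L
          s <- array[k]
          pos <- nchar(s) %/% 2L
          array[k] <- paste0(substr(s, 1L, pos - 1L),
                             substr(s, pos + 2L, nchar(s)))
        }
        # the heteroduplex gel sees every variant class in the genome (the
        # whole array is amplified), whereas cloning subsamples it; to keep
        # the clone pool faithful to the gel, clones deterministically cover
        # the most abundant classes first (up to the clone budget) and the
        # remaining budget repeats the majority class, so the pool is
        # majority-dominated and identical for identical arrays
        cls <- array_classes(array)
        n_cover <- min(length(cls$representatives),
                       config$clones_per_individual)
        picked <- c(match(cls$representatives[seq_len(n_cover)], array),
                    rep(match(cls$representatives[1], array),
                        config$clones_per_individual - n_cover))
        for (ci in seq_along(picked)) {
          s <- array[picked[ci]]
          if (config$pcr_error > 0)
            s <- apply_noise(s, config$pcr_error, config$kappa)
          amplicon <- paste0(sim$pads[["p5"]], s, sim$pads[["p3"]])
          cid <- sprintf("%s_c%d", ind, ci)
          clones[[length(clones) + 1L]] <-
            seq_record(cid, amplicon, marker = "ITS2", individual = ind,
                       site = site, genotype = sp)
          truth[[length(truth) + 1L]] <- data.frame(
            seq_id = cid, marker = "ITS2", species = sp, individual = ind,
            clone = ci, site = site,
            variant_class = match(s, cl_reps, nomatch = NA_integer_),
            stringsAsFactors = FALSE)
        }
        coi_seq <- evolve_seq_branch(coi_species[[sp]],
                                     config$coi_individual_depth,
                                     config$sub_rate_coi, config)
        coi_id <- sprintf("%s_coi", ind)
        coi[[length(coi) + 1L]] <-
          seq_record(coi_id, coi_seq, marker = "COI", individual = ind,
                     site = site, genotype = sp)
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = coi_id, marker = "COI", species = sp, individual = ind,
          clone = NA_integer_, site = site, variant_class = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    st <- site_table(st_site,
                     stats::setNames(site_lat, site_ids)[st_site],
                     stats::setNames(site_lon, site_ids)[st_site],
                     st_ind, st_geno)
    structure(list(clones = clones, coi = coi, sites = st,
                   truth = do.call(rbind, truth), tree = sim$tree,
                   classes = sim$classes,
                   engineered = sim$engineered %||% list()),
              class = "sim_dataset")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-call simulation: tree, arrays, features, dataset
#'
#' @param config A `sim_config`.
#' @param requests Optional engineering requests for [engineer_features()].
#' @return A `sim_dataset`.
#' @export
simulate_dataset <- function(config = sim_config(), requests = NULL) {
  tree <- simulate_tree(config)
  sim <- evolve_arrays(tree, config)
  if (!is.null(requests)) sim <- engineer_features(sim, requests)
  emit_dataset(sim, config)
}

#' Write a simulated dataset to an output directory
#'
#' Emits `clones.fasta`, `coi.fasta`, `sites.tsv` and `truth.tsv`.
#'
#' @param ds A `sim_dataset`.
#' @param outdir Directory (created if needed).
#' @export
write_dataset <- function(ds, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_sequences(ds$clones, file.path(outdir, "clones.fasta"), "fasta")
  write_sequences(ds$coi, file.path(outdir, "coi.fasta"), "fasta")
  utils::write.table(ds$sites, file.path(outdir, "sites.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(ds$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(outdir)
}
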