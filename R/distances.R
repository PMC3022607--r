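#' Pairwise mutational-step distances
#'
#' `steps[i,j]` counts alignment columns where both rows carry a non-gap,
#' non-`N` state and the states differ ("mutational steps");
#' `compared_sites[i,j]` counts the columns where both are comparable.
#' `p_dist` divides steps by the full alignment length — the convention
#' under which printed step counts and printed percentages agree for this
#' kind of barcode data — while `p_dist_compared` divides by the per-pair
#' comparable sites.
#'
#' @param aln A `multiple_alignment` (>= 2 rows).
#' @param allow_zero_compared Permit pairs with no comparable sites
#'   (their `p_dist_compared` is `NA`); default errors on such pairs.
#' @return Object of class `distance_matrix` with `labels`, `steps`,
#'   `compared_sites`, `p_dist`, `p_dist_compared`.
#' @export
pairwise_steps <- function(aln, allow_zero_compared = FALSE) {
  stopifnot(inherits(aln, "multiple_alignment"),
            length(aln$records) >= 2L)
  m <- aln_matrix(aln)
  n <- nrow(m)
  ok <- !(m == "-" | m == "N")
  steps <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  comp <- matrix(0L, n, n, dimnames = dimnames(steps))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- ok[i, ] & ok[j, ]
    s <- sum(m[i, both] != m[j, both])
    steps[i, j] <- steps[j, i] <- s
    comp[i, j] <- comp[j, i] <- sum(both)
  }
  diag(comp) <- ncol(m)
  if (!allow_zero_compared) {
    zero <- which(comp == 0L & row(comp) != col(comp), arr.ind = TRUE)
    if (nrow(zero))
      stop("no comparable sites between '", rownames(m)[zero[1, 1]],
           "' and '", rownames(m)[zero[1, 2]], "'")
  }
  pdc <- ifelse(comp > 0L, steps / comp, NA_real_)
  structure(list(labels = rownames(m), steps = steps,
                 compared_sites = comp,
                 p_dist = steps / ncol(m),
                 p_dist_compared = pdc),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix: %d labels, max %d steps>\n",
              length(x$labels), max(x$steps)))
  invisible(x)
}

#' Intra/inter-group divergence summary with barcode-gap assessment
#'
#' For each group, the maximum intra-group step count (0 for singletons)
#' and, for each group pair, the minimum inter-group step count. A group
#' `g` sits in a "barcode gap" when its smallest divergence from any other
#' group exceeds the largest intra-group diversity among all groups it is
#' compared against (including its own) — when it does not, threshold-based
#' assignment would confound it with its neighbour, and the offending
#' configuration is recorded as a witness.
#'
#' @param dm A `distance_matrix`.
#' @param labels Named character vector `id -> group`.
#' @return Object of class `divergence_summary`: `max_intra` (named),
#'   `min_inter` (matrix), `barcode_gap` (named logical),
#'   `overlap_witnesses` (`data.frame` of group pair, min_inter and the
#'   offending max_intra).
#' @export
divergence_summary <- function(dm, labels) {
  stopifnot(inherits(dm, "distance_matrix"))
  if (!all(dm$labels %in% names(labels)))
    stop("labels missing for: ",
         paste(setdiff(dm$labels, names(labels)), collapse = ", "))
  grp <- labels[dm$labels]
  groups <- sort(unique(grp))
  max_intra <- vapply(groups, function(g) {
    idx <- which(grp == g)
    if (length(idx) < 2L) return(0L)
    as.integer(max(dm$steps[idx, idx]))
  }, integer(1))
  min_inter <- matrix(NA_integer_, length(groups), length(groups),
                      dimnames = list(groups, groups))
  for (a in seq_along(groups)) for (b in seq_along(groups)) {
    if (a == b) next
    min_inter[a, b] <- as.integer(
      min(dm$steps[grp == groups[a], grp == groups[b], drop = FALSE]))
  }
  gap <- logical(length(groups)); names(gap) <- groups
  wit <- list()
  for (g in groups) {
    others <- setdiff(groups, g)
    nearest <- min(min_inter[g, others])
    neighbours <- others[min_inter[g, others] == nearest]
    intra_ceiling <- max(max_intra[c(g, others)])
    gap[g] <- nearest > intra_ceiling
    if (!gap[g]) {
      worst <- names(which.max(max_intra[c(g, others)]))
      wit[[length(wit) + 1L]] <- data.frame(
        group = g, neighbour = neighbours[1], min_inter = nearest,
        offending_group = worst,
        offending_max_intra = unname(max_intra[worst]),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(max_intra = max_intra, min_inter = min_inter,
                 barcode_gap = gap,
                 overlap_witnesses = if (length(wit)) do.call(rbind, wit)
                 else data.frame()),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat("<divergence_summary>\n")
  for (g in names(x$max_intra))
    cat(sprintf("  %s: max intra %d steps, nearest neighbour %d steps, barcode gap %s\n",
                g, x$max_intra[g],
                suppressWarnings(min(x$min_inter[g, ], na.rm = TRUE)),
                if (x$barcode_gap[g]) "yes" else "NO"))
  invisible(x)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour-joining agglomeration on the `p_dist` matrix (via
#' `ape::nj()`); negative branch-length estimates are clamped to zero with
#' a message. The result is an unrooted `ape::phylo` tree.
#'
#' @param dm A `distance_matrix`, or a plain symmetric numeric matrix.
#' @param quiet Suppress the clamping note (used for bootstrap replicates).
#' @return An `ape` `phylo` object.
#' @export
nj_tree <- function(dm, quiet = FALSE) {
  d <- if (inherits(dm, "distance_matrix")) dm$p_dist else as.matrix(dm)
  if (!isSymmetric(unname(d), tol = 1e-9))
    stop("distance matrix must be symmetric")
  if (nrow(d) < 3L) stop("neighbour joining needs >= 3 labels")
  tr <- ape::nj(d)
  if (any(tr$edge.length < 0)) {
    if (!quiet)
      message("clamping ", sum(tr$edge.length < 0),
              " negative NJ branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

# Distance + NJ pipeline used for bootstrap replicates; resampled columns
# may leave pairs with no comparable sites, so those are tolerated.
nj_from_char_matrix <- function(m, quiet = TRUE) {
  recs <- lapply(rownames(m), function(id)
    seq_record(id, paste(m[id, ], collapse = "")))
  dm <- pairwise_steps(multiple_alignment(recs), allow_zero_compared = TRUE)
  nj_tree(dm, quiet = quiet)
}

#' Bootstrap support for the neighbour-joining tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree per replicate, and scores each internal edge of the
#' full-data tree by the percentage of replicate trees containing the same
#' leaf bipartition (branch lengths ignored). Reproducible given `seed`;
#' the caller's RNG state is left untouched.
#'
#' @param aln A `multiple_alignment`.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed.
#' @return The full-data NJ tree (`phylo`) with `node.label` set to
#'   integer support percentages (root label empty).
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L) {
  stopifnot(inherits(aln, "multiple_alignment"), n_reps >= 1L)
  m <- aln_matrix(aln)
  full <- nj_from_char_matrix(m)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    reps[[r]] <- nj_from_char_matrix(m[, cols, drop = FALSE])
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_reps)
  full$node.label <- as.character(support)
  full$node.label[1] <- ""   # root of the unrooted representation
  full
}

# Tip-label sets on each side of every internal edge of an unrooted tree.
tree_bipartitions <- function(tree) {
  parts <- ape::prop.part(tree)
  tips <- attr(parts, "labels")
  lapply(parts, function(p) tips[p])
}

#' Per-group monophyly on an unrooted tree
#'
#' A group is monophyletic iff some edge bipartition separates exactly its
#' leaves from the rest (single-member groups and the full leaf set are
#' trivially monophyletic). Also reports the size of the smallest clade
#' (either side of any bipartition) covering all the group's leaves.
#'
#' @param tree A `phylo` tree.
#' @param labels Named character vector `leaf -> group`, covering all leaves.
#' @return `data.frame`: group, n_leaves, monophyletic, covering_clade_size.
#' @export
monophyly <- function(tree, labels) {
  tips <- tree$tip.label
  if (!all(tips %in% names(labels)))
    stop("unlabeled leaf: ", setdiff(tips, names(labels))[1])
  grp <- labels[tips]
  sides <- tree_bipartitions(tree)
  sides <- c(sides, lapply(sides, function(s) setdiff(tips, s)),
             list(tips))
  out <- lapply(sort(unique(grp)), function(g) {
    leaves <- tips[grp == g]
    mono <- length(leaves) <= 1L || length(leaves) == length(tips) ||
      any(vapply(sides, function(s) setequal(s, leaves), logical(1)))
    covering <- vapply(sides, function(s)
      if (all(leaves %in% s)) length(s) else NA_integer_, numeric(1))
    data.frame(group = g, n_leaves = length(leaves), monophyletic = mono,
               covering_clade_size = as.integer(min(covering, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
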