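test_that("mutational steps skip gaps and missing data", {
  dm <- pairwise_steps(make_aln(c("ACGT", "ACGA")))
  expect_identical(dm$steps[1, 2], 1L)
  dm2 <- pairwise_steps(make_aln(c("AC-T", "ACGT")))
  expect_identical(dm2$steps[1, 2], 0L)
  expect_identical(dm2$compared_sites[1, 2], 3L)
  expect_error(pairwise_steps(make_aln(c("AC--", "--GT"))), "no comparable")
})

test_that("the step matrix equals a double-loop oracle on random 50-mers", {
  set.seed(41)
  seqs <- replicate(5, random_seq(50, c("A", "C", "G", "T", "-", "N")))
  dm <- pairwise_steps(make_aln(seqs), allow_zero_compared = TRUE)
  for (i in 1:4) for (j in (i + 1):5) {
    o <- naive_steps(seqs[i], seqs[j])
    expect_identical(dm$steps[i, j], unname(o["steps"]))
    expect_identical(dm$compared_sites[i, j], unname(o["compared"]))
  }
  expect_true(isSymmetric(dm$steps))
  expect_true(all(diag(dm$steps) == 0L))
  expect_true(all(dm$p_dist >= 0 & dm$p_dist <= 1))
})

fake_dm <- function(labels, steps) {
  n <- length(labels)
  dimnames(steps) <- list(labels, labels)
  structure(list(labels = labels, steps = steps,
                 compared_sites = matrix(100L, n, n),
                 p_dist = steps / 100,
                 p_dist_compared = steps / 100),
            class = "distance_matrix")
}

test_that("well-separated groups sit in a barcode gap", {
  steps <- rbind(c(0L, 0L, 5L, 5L),
                 c(0L, 0L, 5L, 5L),
                 c(5L, 5L, 0L, 0L),
                 c(5L, 5L, 0L, 0L))
  dm <- fake_dm(c("x1", "x2", "y1", "y2"), steps)
  ds <- divergence_summary(dm, c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y"))
  expect_true(all(ds$barcode_gap))
  expect_identical(nrow(ds$overlap_witnesses), 0L)
})

test_that("a shallow split under deep intra-group diversity fails the gap", {
  # one diverse group (17 steps max inside) and a neighbour only 9 away:
  # the neighbour hides inside the other group's intraspecific variation
  steps <- rbind(c(0L, 17L, 9L),
                 c(17L, 0L, 12L),
                 c(9L, 12L, 0L))
  dm <- fake_dm(c("g1", "g2", "e1"), steps)
  ds <- divergence_summary(dm, c(g1 = "G", g2 = "G", e1 = "E"))
  expect_identical(unname(ds$max_intra["G"]), 17L)
  expect_identical(unname(ds$max_intra["E"]), 0L)    # singleton
  expect_identical(unname(ds$min_inter["E", "G"]), 9L)
  expect_false(ds$barcode_gap[["E"]])
  expect_false(ds$barcode_gap[["G"]])
  w <- ds$overlap_witnesses
  expect_true("E" %in% w$group)
  expect_identical(w$min_inter[w$group == "E"], 9L)
  expect_identical(w$offending_max_intra[w$group == "E"], 17L)
})

test_that("NJ reconstructs additive matrices exactly", {
  # 4-taxon additive matrix built from a known tree
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:1):2);")
  d <- ape::cophenetic.phylo(tr)
  got <- nj_tree(d[order(rownames(d)), order(colnames(d))], quiet = TRUE)
  expect_equal(phangorn::RF.dist(ape::unroot(tr), got), 0)

  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    rtr <- ape::rtree(n)
    rtr$edge.length <- rtr$edge.length + 0.05
    d <- ape::cophenetic.phylo(rtr)
    got <- nj_tree(d, quiet = TRUE)
    expect_equal(phangorn::RF.dist(ape::unroot(rtr), got), 0,
                     info = paste("leaves:", n))
  }
})

test_that("3-taxon NJ gives the analytic star branch lengths", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.4,
                0.5, 0.4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["a"]), (0.3 + 0.5 - 0.4) / 2)
  expect_equal(unname(bl["b"]), (0.3 + 0.4 - 0.5) / 2)
  expect_equal(unname(bl["c"]), (0.5 + 0.4 - 0.3) / 2)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("two-cluster ultrametric matrices produce the cluster bipartition", {
  labs <- c(paste0("a", 1:4), paste0("b", 1:4))
  d <- matrix(1, 8, 8, dimnames = list(labs, labs))
  d[1:4, 1:4] <- 0.1; d[5:8, 5:8] <- 0.1; diag(d) <- 0
  tr <- nj_tree(d, quiet = TRUE)
  parts <- lapply(ape::prop.part(tr), function(p)
    sort(attr(ape::prop.part(tr), "labels")[p]))
  has_split <- any(vapply(parts, function(p)
    identical(p, sort(paste0("a", 1:4))) ||
      identical(p, sort(paste0("b", 1:4))), logical(1)))
  expect_true(has_split)
})

make_two_clade_aln <- function(n_per = 2, L = 200, n_diag = 30, seed = 5) {
  set.seed(seed)
  anc <- random_seq(L)
  flip <- function(s, pos) {
    ch <- substr(s, pos, pos)
    sub <- setdiff(c("A", "C", "G", "T"), ch)[1]
    paste0(substr(s, 1, pos - 1), sub, substr(s, pos + 1, nchar(s)))
  }
  other <- anc
  for (p in sample(L, n_diag)) other <- flip(other, p)
  jitter <- function(s) flip(s, sample(nchar(s), 1))
  seqs <- c(vapply(1:n_per, function(i) jitter(anc), character(1)),
            vapply(1:n_per, function(i) jitter(other), character(1)))
  make_aln(seqs, c(paste0("a", 1:n_per), paste0("b", 1:n_per)))
}

test_that("bootstrap support is seeded, reproducible, and finds real clades", {
  aln <- make_two_clade_aln()
  t1 <- bootstrap_support(aln, n_reps = 100, seed = 7)
  t2 <- bootstrap_support(aln, n_reps = 100, seed = 7)
  expect_identical(t1$node.label, t2$node.label)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 95))   # both clades overwhelmingly supported

  one <- bootstrap_support(aln, n_reps = 1, seed = 3)
  s1 <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
})

test_that("monophyly is an edge-bipartition test on the unrooted tree", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1,(c1:1,(c2:1,b3:1):1):1);")
  labels <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", b3 = "B",
              c1 = "C", c2 = "C")
  mo <- monophyly(tr, labels)
  expect_true(mo$monophyletic[mo$group == "A"])
  expect_false(mo$monophyletic[mo$group == "B"])   # b3 sits with the c's
  expect_false(mo$monophyletic[mo$group == "C"])
  expect_gt(mo$covering_clade_size[mo$group == "B"], 3L)

  single <- c(labels[-(1:2)], a1 = "A1", a2 = "A2")
  mo2 <- monophyly(tr, single)
  expect_true(all(mo2$monophyletic[mo2$group %in% c("A1", "A2")]))
  expect_error(monophyly(tr, labels[-1]), "unlabeled")
})
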