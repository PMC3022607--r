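test_that("column classes on the 4x6 toy match exhaustive classification", {
  aln <- make_aln(c("AATTCG", "AATACG", "TATTCG", "TAT-CG"))
  cc <- classify_columns(aln)
  m <- do.call(rbind, strsplit(c("AATTCG", "AATACG", "TATTCG", "TAT-CG"), ""))
  expected <- apply(m, 2, naive_classify_column)
  expect_identical(as.character(cc$per_column), expected)
  expect_identical(cc$n_constant, sum(expected == "constant"))
  expect_identical(cc$n_parsimony_informative, sum(expected == "PI"))
  expect_identical(cc$n_gap_columns, 1L)
})

test_that("column classes agree with the oracle on random alignments", {
  set.seed(31)
  for (i in 1:500) {
    nrow_ <- sample(2:6, 1); ncol_ <- sample(3:9, 1)
    seqs <- replicate(nrow_, random_seq(ncol_, c("A", "C", "G", "T", "-", "N")))
    # classify_columns requires seq_record-compatible rows
    aln <- make_aln(seqs)
    cc <- classify_columns(aln)
    m <- do.call(rbind, strsplit(seqs, ""))
    expected <- apply(m, 2, naive_classify_column)
    expect_identical(as.character(cc$per_column), expected)
    expect_identical(cc$n_constant + cc$n_parsimony_informative +
                       cc$n_variable_uninformative, ncol_)
  }
})

test_that("GC content counts only real residues", {
  expect_equal(gc_content(list(seq_record("x", "GGCC")))$per_sequence[["x"]], 1)
  expect_equal(gc_content(list(seq_record("x", "ATGC-N")))$per_sequence[["x"]],
               0.5)
  g <- gc_content(list(seq_record("a", "GGGG"), seq_record("b", "ATAT")))
  expect_equal(g$mean, 0.5)
  expect_equal(g$min, 0)
  expect_equal(g$max, 1)
  expect_error(gc_content(list(seq_record("bad", "--NN"))), "bad")
})

test_that("haplotype collapse uses exact aligned identity, gaps significant", {
  aln <- make_aln(c("ACGT", "ACGT", "ACGT"))
  expect_identical(collapse_haplotypes(aln)$n_haplotypes, 1L)
  expect_identical(collapse_haplotypes(make_aln(c("ACGT", "ACGA")))$n_haplotypes,
                   2L)
  expect_identical(collapse_haplotypes(make_aln(c("AC-T", "ACGT")))$n_haplotypes,
                   2L)

  set.seed(32)
  seqs <- replicate(8, random_seq(12, c("A", "C")))
  base <- collapse_haplotypes(make_aln(seqs))$n_haplotypes
  for (i in 1:5) {
    ord <- sample(seq_along(seqs))
    expect_identical(collapse_haplotypes(make_aln(seqs[ord]))$n_haplotypes,
                     base)
  }
})

test_that("diagnostic substitutions classify Ser->Ala as nonsynonymous", {
  # two groups, codon 2 engineered TCT (Ser) -> GCT (Ala) in group B
  gA <- c("ATGTCTAAA", "ATGTCTAAA")
  gB <- c("ATGGCTAAA", "ATGGCTAAA")
  aln <- make_aln(c(gA, gB), c("a1", "a2", "b1", "b2"))
  labels <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  hits <- diagnostic_substitutions(aln, labels, frame_offset = 0L)
  hit <- hits[hits$group == "B", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$column, 4L)
  expect_identical(hit$aa_index, 2L)
  expect_identical(hit$codon_position, 1L)
  expect_false(hit$syn)
  expect_identical(hit$aa_from, "S")
  expect_identical(hit$aa_to, "A")
})

test_that("third-position CTT->CTC is reported as synonymous Leu->Leu", {
  aln <- make_aln(c("ATGCTTAAA", "ATGCTTAAA", "ATGCTCAAA", "ATGCTCAAA"),
                  c("a1", "a2", "b1", "b2"))
  labels <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  hits <- diagnostic_substitutions(aln, labels, frame_offset = 0L)
  hit <- hits[hits$group == "B", ]
  expect_identical(hit$codon_position, 3L)
  expect_true(hit$syn)
  expect_identical(hit$aa_from, "L")
  expect_identical(hit$aa_to, "L")
})

test_that("identical groups yield no diagnostic sites; gaps mark syn as NA", {
  aln <- make_aln(c("ATGTCT", "ATGTCT", "ATGTCT", "ATGTCT"),
                  c("a1", "a2", "b1", "b2"))
  labels <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  expect_identical(nrow(diagnostic_substitutions(aln, labels)), 0L)

  gap <- make_aln(c("ATG-CTAAA", "ATG-CTAAA", "ATG-GTAAA", "ATG-GTAAA"),
                  c("a1", "a2", "b1", "b2"))
  hits <- diagnostic_substitutions(gap, labels, frame_offset = 0L)
  expect_true(nrow(hits) >= 1L)
  expect_true(all(is.na(hits$syn)))
})
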