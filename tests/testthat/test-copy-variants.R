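test_that("identical sequences align with zero events and full match score", {
  pa <- align_pair("ACGTACGT", "ACGTACGT", c(1, -1, -4, -1))
  expect_identical(nrow(pa$events), 0L)
  expect_equal(pa$score, 8)
})

test_that("a single deletion is recovered from the classic toy", {
  pa <- align_pair("ACGT", "ACT", c(1, -1, -2, -1))
  expect_identical(pa$events$kind, "deletion")
  expect_identical(pa$events$length, 1L)
  expect_equal(pa$score, 0)   # 3 matches - (open 2 + 1 extension)
})

test_that("alignment scores match a Gotoh dynamic-programming oracle", {
  set.seed(21)
  schemes <- list(c(1, -1, -2, -1), c(2, -3, -5, -2), c(1, -2, -1, -1))
  for (i in 1:120) {
    a <- random_seq(sample(1:12, 1))
    b <- random_seq(sample(1:12, 1))
    sc <- schemes[[(i %% 3) + 1]]
    expect_equal(align_pair(a, b, sc)$score,
                 gotoh_score(a, b, sc[1], sc[2], -sc[3], -sc[4]),
                 info = paste(a, b, paste(sc, collapse = "/")))
  }
})

test_that("swapping the inputs mirrors the event kinds", {
  set.seed(22)
  for (i in 1:40) {
    a <- random_seq(sample(5:30, 1))
    b <- random_seq(sample(5:30, 1))
    ev_ab <- align_pair(a, b)$events
    ev_ba <- align_pair(b, a)$events
    expect_identical(sum(ev_ab$kind == "substitution"),
                     sum(ev_ba$kind == "substitution"))
    expect_identical(sum(ev_ab$length[ev_ab$kind == "insertion"]),
                     sum(ev_ba$length[ev_ba$kind == "deletion"]))
    expect_identical(sum(ev_ab$length[ev_ab$kind == "deletion"]),
                     sum(ev_ba$length[ev_ba$kind == "insertion"]))
  }
})

test_that("variant calling groups clones by identity, majority first", {
  x <- random_seq(80)
  expect_error(call_variants(make_clones(x)), ">=2 clones")

  vs <- call_variants(make_clones(rep(x, 5)))
  expect_length(vs$classes, 1L)
  expect_identical(vs$classes[[1]]$clone_count, 5L)
  expect_identical(nrow(vs$classes[[1]]$diff_events), 0L)

  del2 <- paste0(substr(x, 1, 39), substr(x, 42, 80))
  vs2 <- call_variants(make_clones(c(rep(x, 4), del2)))
  expect_length(vs2$classes, 2L)
  expect_identical(vs2$classes[[1]]$representative, x)
  ev <- vs2$classes[[2]]$diff_events
  expect_identical(ev$kind, "deletion")
  expect_identical(ev$length, 2L)
})

test_that("the optional error-correction pass absorbs 1-SNP singletons", {
  x <- random_seq(60)
  y <- substitute_one <- paste0("T", substr(x, 2, 60))
  if (substr(x, 1, 1) == "T") y <- paste0("A", substr(x, 2, 60))
  raw <- call_variants(make_clones(c(rep(x, 4), y)))
  expect_length(raw$classes, 2L)
  fixed <- call_variants(make_clones(c(rep(x, 4), y)), correct_errors = TRUE)
  expect_length(fixed$classes, 1L)
  expect_identical(fixed$classes[[1]]$clone_count, 5L)
})

test_that("duplex signatures have k homoduplexes and C(k,2) heteroduplexes", {
  x <- random_seq(100)
  one <- duplex_signature(call_variants(make_clones(rep(x, 4))))
  expect_identical(one$kind, "homoduplex")

  snp <- paste0(substr(x, 1, 49),
                setdiff(c("A", "C"), substr(x, 50, 50))[1],
                substr(x, 51, 100))
  two <- duplex_signature(call_variants(make_clones(c(x, x, x, snp))))
  expect_identical(table(two$kind)[["homoduplex"]], 2L)
  expect_identical(two$mismatches[two$kind == "snp_het"], 1L)

  del <- paste0(substr(x, 1, 70), substr(x, 74, 100))
  three <- duplex_signature(call_variants(make_clones(c(x, x, snp, del, del))))
  expect_equal(nrow(three), 3 + choose(3, 2))
  expect_true("indel_het" %in% three$kind)
  for (k in 1:3) {
    # deletions of distinct lengths at well-separated positions: k distinct
    # variant classes by construction
    seqs <- c(rep(x, 4), vapply(seq_len(k - 1), function(j)
      paste0(substr(x, 1, 10 * j), substr(x, 10 * j + 1 + j, 100)),
      character(1)))
    sig <- duplex_signature(call_variants(make_clones(seqs)))
    expect_equal(nrow(sig), k + choose(k, 2))
  }
})

test_that("signature equality ignores clone counts and clone order", {
  x <- random_seq(90)
  snp <- paste0("G", substr(x, 2, 90))
  if (substr(x, 1, 1) == "G") snp <- paste0("C", substr(x, 2, 90))
  a <- duplex_signature(call_variants(make_clones(c(x, x, x, x, snp))))
  b <- duplex_signature(call_variants(make_clones(c(snp, x, x, x))))
  expect_true(signatures_equal(a, b))
})

test_that("the fixation test flags the first individual with a private variant", {
  x <- random_seq(100)
  snp <- paste0(substr(x, 1, 59), "A", substr(x, 61, 100))
  if (substr(x, 60, 60) == "A")
    snp <- paste0(substr(x, 1, 59), "C", substr(x, 61, 100))
  mk <- function(ind, seqs) {
    vsrec <- lapply(seq_along(seqs), function(i)
      seq_record(paste0(ind, "_c", i), seqs[i], individual = ind))
    call_variants(vsrec)
  }
  same <- list(mk("i1", c(x, x, snp, x)), mk("i2", c(x, snp, x, x, x)))
  expect_true(fixation_test(same)$fixed)

  del <- paste0(substr(x, 1, 20), substr(x, 24, 100))
  odd <- list(mk("i1", c(x, x, snp, x)), mk("i2", c(x, snp, x, del)))
  res <- fixation_test(odd)
  expect_false(res$fixed)
  expect_identical(res$witness, c("i1", "i2"))
  expect_error(fixation_test(odd[1]), ">=2")
})
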