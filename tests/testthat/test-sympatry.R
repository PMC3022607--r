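test_that("the published sympatry records give seven of nine sympatric genotypes", {
  st <- survey_sympatry_site_table()
  rep <- cooccurrence(st)
  expect_length(rep$genotypes, 9L)
  expect_identical(sum(rep$sympatric), 7L)
  expect_setequal(names(rep$sympatric)[!rep$sympatric], c("F", "H"))
  expect_setequal(rep$site_genotypes[["7"]], c("B", "C1", "C2", "D", "E", "G"))
})

test_that("partnership is symmetric and single-genotype sites add nothing", {
  st <- site_table(c("s1", "s1", "s2", "s3"), c(-3, -3, -4, -5),
                   c(141, 141, 142, 143),
                   c("i1", "i2", "i3", "i4"), c("X", "Y", "X", "Z"))
  rep <- cooccurrence(st)
  expect_true("Y" %in% rep$partners[["X"]])
  expect_true("X" %in% rep$partners[["Y"]])
  expect_false(rep$sympatric[["Z"]])
  expect_length(rep$partners[["Z"]], 0L)
})

test_that("adding an allopatric site never changes existing partnerships", {
  st <- site_table(c("s1", "s1"), c(-3, -3), c(141, 141),
                   c("i1", "i2"), c("X", "Y"))
  base <- cooccurrence(st)$partners
  st2 <- site_table(c("s1", "s1", "s9"), c(-3, -3, -8), c(141, 141, 148),
                    c("i1", "i2", "i9"), c("X", "Y", "W"))
  grown <- cooccurrence(st2)$partners
  expect_identical(grown[["X"]], base[["X"]])
  expect_identical(grown[["Y"]], base[["Y"]])
})

three_species_setup <- function() {
  st <- site_table(rep("s1", 6), rep(-3, 6), rep(141, 6),
                   paste0("i", 1:6), rep(c("X", "Y", "Z"), each = 2))
  classes <- list(i1 = "xx", i2 = "xx", i3 = "yy", i4 = "yy",
                  i5 = "zz", i6 = "zz")
  profiles <- list(i1 = c(300L, 100L), i2 = c(300L, 100L),
                   i3 = c(250L, 150L), i4 = c(250L, 150L),
                   i5 = c(400L), i6 = c(400L))
  list(st = st, classes = classes, profiles = profiles)
}

test_that("sympatric species with disjoint classes all show isolation evidence", {
  s <- three_species_setup()
  rep <- isolation_evidence(cooccurrence(s$st), s$st, s$classes, s$profiles)
  expect_true(all(rep$isolation_evidence))
})

test_that("a hybrid band pattern withdraws evidence from both parents", {
  s <- three_species_setup()
  # i2 (an X individual) carries the superposition of the X and Y patterns
  s$profiles$i2 <- c(300L, 250L, 150L, 100L)
  rep <- isolation_evidence(cooccurrence(s$st), s$st, s$classes, s$profiles)
  expect_false(rep$isolation_evidence[["X"]])
  expect_false(rep$isolation_evidence[["Y"]])
  expect_true(rep$isolation_evidence[["Z"]])
  expect_match(rep$reasons[["X"]], "hybrid")
})

test_that("shared sequence classes and allopatry each block the evidence", {
  s <- three_species_setup()
  s$classes$i3 <- c("yy", "xx")    # Y shares a class with X
  rep <- isolation_evidence(cooccurrence(s$st), s$st, s$classes, s$profiles)
  expect_false(rep$isolation_evidence[["X"]])
  expect_false(rep$isolation_evidence[["Y"]])
  expect_match(rep$reasons[["X"]], "share")

  st <- site_table(c("s1", "s1", "s2"), c(-3, -3, -4), c(141, 141, 142),
                   c("i1", "i2", "i3"), c("X", "Y", "W"))
  classes <- list(i1 = "xx", i2 = "yy", i3 = "ww")
  profiles <- list(i1 = c(300L), i2 = c(250L), i3 = c(200L))
  rep2 <- isolation_evidence(cooccurrence(st), st, classes, profiles)
  expect_false(rep2$isolation_evidence[["W"]])
  expect_match(rep2$reasons[["W"]], "never sympatric")
  expect_error(isolation_evidence(cooccurrence(st), st, classes[-1], profiles),
               "missing ITS2 class")
})
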