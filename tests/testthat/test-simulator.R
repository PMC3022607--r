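small_cfg <- function(...) {
  sim_config(n_species = 3, individuals_per_species = 2,
             clones_per_individual = 5, n_sites = 4, ...)
}

test_that("identical configurations give byte-identical datasets", {
  a <- simulate_dataset(small_cfg(seed = 5))
  b <- simulate_dataset(small_cfg(seed = 5))
  expect_identical(residues_of(a$clones), residues_of(b$clones))
  expect_identical(residues_of(a$coi), residues_of(b$coi))
  expect_identical(a$truth, b$truth)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))

  c2 <- simulate_dataset(small_cfg(seed = 6))
  expect_false(identical(residues_of(a$clones), residues_of(c2$clones)))
})

test_that("the no-mutation limit leaves every copy identical to the ancestor", {
  cfg <- small_cfg(sub_rate_rdna = 0, indel_rate = 0, seed = 3)
  tr <- simulate_tree(cfg)
  sim <- evolve_arrays(tr, cfg)
  for (sp in names(sim$arrays))
    expect_true(all(sim$arrays[[sp]] == sim$ancestor))
  ds <- emit_dataset(sim, cfg)
  expect_identical(length(unique(unname(residues_of(ds$clones)))), 1L)
  expect_identical(nchar(ds$clones[[1]]$residues),
                   cfg$spacer_length + 2L * cfg$primer_pad)   # ~680 bp amplicon
})

test_that("overwhelming gene conversion homogenizes the arrays", {
  # conversion 100x the total per-array substitution rate
  sub <- 0.01
  cfg <- small_cfg(sub_rate_rdna = sub, indel_rate = 0,
                   conversion_rate = 100 * sub * 620 * 20, seed = 4)
  sim <- evolve_arrays(simulate_tree(cfg), cfg)
  n_classes <- vapply(sim$classes, function(cl)
    length(cl$representatives), integer(1))
  expect_lte(mean(n_classes), 2)
  expect_gte(mean(n_classes), 1)
})

test_that("with no within-species noise, variant sets are fixed in every species", {
  ds <- cached_sim("default3", small_cfg(seed = 8))
  by_ind <- split(ds$clones, vapply(ds$clones, `[[`, "", "individual"))
  vs <- lapply(by_ind, call_variants)
  species <- vapply(ds$clones, `[[`, "", "genotype")
  ind_sp <- tapply(species, vapply(ds$clones, `[[`, "", "individual"),
                   unique)
  for (sp in unique(ind_sp)) {
    group <- vs[names(ind_sp)[ind_sp == sp]]
    expect_true(fixation_test(group)$fixed, info = sp)
  }
})

test_that("an engineered private variant breaks fixation for its species only", {
  cfg <- small_cfg(seed = 8)
  ds <- simulate_dataset(cfg, requests = list(
    list(op = "add_private_variant", individual = "sp2_i2")))
  by_ind <- split(ds$clones, vapply(ds$clones, `[[`, "", "individual"))
  vs <- lapply(by_ind, call_variants)
  expect_false(fixation_test(vs[c("sp2_i1", "sp2_i2")])$fixed)
  expect_true(fixation_test(vs[c("sp1_i1", "sp1_i2")])$fixed)
  expect_true(fixation_test(vs[c("sp3_i1", "sp3_i2")])$fixed)
})

test_that("an engineered cut site adds exactly one cut at the requested spot", {
  cfg <- small_cfg(seed = 12)
  tr <- simulate_tree(cfg)
  sim <- evolve_arrays(tr, cfg)
  before <- find_cut_sites(sim$arrays$sp1[1])
  pos <- 333L
  sim2 <- engineer_features(sim, list(
    list(op = "add_cut_site", species = "sp1", position = pos)))
  after <- find_cut_sites(sim2$arrays$sp1[1])
  expect_true((pos + msp_i()$cut_offset) %in% after)
  expect_true(all(setdiff(after, before) >= pos - 3))
})

test_that("the mitochondrial locus outpaces the spacer consensus", {
  ds <- cached_sim("default3", small_cfg(seed = 8))
  reps <- vapply(ds$classes, function(cl) cl$representatives[1], character(1))
  coi_by_sp <- split(vapply(ds$coi, `[[`, "", "residues"),
                     vapply(ds$coi, `[[`, "", "genotype"))
  sp <- names(reps)
  its2_p <- coi_p <- c()
  for (i in 1:(length(sp) - 1)) for (j in (i + 1):length(sp)) {
    ev <- align_pair(reps[sp[i]], reps[sp[j]])$events
    its2_p <- c(its2_p, sum(ev$kind == "substitution") / nchar(reps[sp[i]]))
    coi_p <- c(coi_p,
               naive_steps(coi_by_sp[[sp[i]]][1],
                           coi_by_sp[[sp[j]]][1])["steps"] / 524)
  }
  expect_gt(mean(coi_p), mean(its2_p))
})

test_that("emitted spacer GC tracks the configured target", {
  cfg <- small_cfg(seed = 8, primer_pad = 0L)
  ds <- simulate_dataset(cfg)
  gc <- gc_content(ds$clones)
  expect_lt(abs(gc$mean - cfg$gc_target), 0.02)
})

test_that("dataset dimensions follow the sampling design", {
  ds <- cached_sim("default5", sim_config(n_species = 5, seed = 42))
  expect_length(ds$clones, 5 * 3 * 5)
  expect_length(ds$coi, 15L)
  expect_identical(nrow(ds$truth), 90L)
  expect_identical(anyDuplicated(ds$truth$seq_id), 0L)
})

test_that("zero sympatric overlap gives single-species sites", {
  cfg <- small_cfg(sympatry_overlap = 0, seed = 31)
  ds <- simulate_dataset(cfg)
  per_site <- tapply(ds$sites$genotype, ds$sites$site_id,
                     function(g) length(unique(g)))
  expect_true(all(per_site == 1L))
})

test_that("dataset files round-trip through the writers and readers", {
  ds <- cached_sim("default3", small_cfg(seed = 8))
  out <- withr::local_tempdir()
  write_dataset(ds, out)
  back <- read_sequences(file.path(out, "clones.fasta"), "fasta", "ITS2")
  expect_identical(residues_of(back), residues_of(ds$clones))
  expect_identical(back[[1]]$individual, ds$clones[[1]]$individual)
  st <- read_site_table(file.path(out, "sites.tsv"))
  expect_identical(nrow(st), nrow(ds$sites))
})
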