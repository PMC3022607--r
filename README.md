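# ribosplit

Cryptic species delimitation from rDNA ITS2 copy variants and
mitochondrial DNA barcodes.

## The problem

Mosquito morphospecies (and many other insects) frequently hide complexes
of reproductively isolated cryptic species. The mitochondrial COI barcode
reveals divergent lineages but cannot demonstrate reproductive isolation,
and fails when a young species' interspecific divergence has not yet
escaped its neighbour's intraspecific variation — the missing *barcode
gap*. The nuclear ribosomal DNA second internal transcribed spacer (ITS2)
offers a complementary signal: the spacer sits in a tandem array of
hundreds of near-identical repeats evolving by concerted evolution.
Where recombination is restricted, homogenization of the array is
incomplete and each genome stably carries a few **copy variants** (SNP or
indel repeats). If the array moves through an interbreeding population as
a single evolutionary unit, every conspecific individual shows the same
variant complement — so genotype-specific, *fixed* copy-variant profiles
among sympatric populations are evidence of reproductive isolation at the
rDNA locus.

`ribosplit` implements that analysis chain for field surveys, and a
simulator of rDNA arrays under incomplete concerted evolution so every
stage can be exercised against known truth:

| stage | functions |
| --- | --- |
| in-silico PCR-RFLP (Msp I `C^CGG`), gel model, genotype clustering | `digest`, `gel_bands`, `cluster_profiles` |
| copy-variant calling, heteroduplex signatures, fixation test | `call_variants`, `duplex_signature`, `fixation_test` |
| alignment statistics, haplotypes, diagnostic codon changes | `classify_columns`, `gc_content`, `collapse_haplotypes`, `diagnostic_substitutions` |
| mutational-step distances, barcode-gap assessment, NJ + bootstrap, monophyly | `pairwise_steps`, `divergence_summary`, `nj_tree`, `bootstrap_support`, `monophyly` |
| sympatry and reproductive-isolation scoring | `cooccurrence`, `isolation_evidence` |
| compensatory base change (CBC) screening on supplied structures | `map_structure`, `classify_pairs`, `cbc_screen` |
| concerted-evolution simulator + truth tables | `sim_config`, `simulate_dataset`, `engineer_features` |
| whole pipeline | `run_pipeline` |

The package also bundles the tabulated results of a published survey of
the *Anopheles longirostris* morphospecies complex in Papua New Guinea
(302 specimens, 76 sites, nine ITS2 genotypes) as plain-text tables
(`survey_abundance()`, `survey_sympatry()`, `survey_rflp_patterns()`,
...) so the worked examples run on real numbers.

## Worked example

Simulate five cryptic species under incomplete concerted evolution and
run the full pipeline:

```r
library(ribosplit)
cfg <- sim_config(n_species = 5, seed = 42)
report <- run_pipeline(cfg, n_boot = 100, boot_seed = 1)
print(report)
```

```
== ribosplit pipeline report ==
RFLP classes: 4; genotypes after signature refinement: 5
Copy variants fixed within genotype: 5/5 (A, B1, B2, C, D)
<column_classification: 524 columns — 289 constant (55%), 207 PI (40%), 28 VU (5%); 0 gap/missing columns>
COI haplotypes: 15
Monophyletic genotypes on the COI tree: 5/5
<divergence_summary>
  A: max intra 6 steps, nearest neighbour 31 steps, barcode gap yes
  B1: max intra 7 steps, nearest neighbour 30 steps, barcode gap yes
  B2: max intra 9 steps, nearest neighbour 30 steps, barcode gap yes
  C: max intra 9 steps, nearest neighbour 138 steps, barcode gap yes
  D: max intra 9 steps, nearest neighbour 96 steps, barcode gap yes
<sympatry_report: 5 genotypes, 5 sympatric (A, B1, B2, C, D)>
  isolation evidence: A, B1, B2, C, D
note: ITS2 clone amplicons differ in length; column statistics skipped (supply an alignment)
```

Reading the report: restriction digestion alone resolves only four band
classes — two species share a digest pattern — but their heteroduplex
signatures differ, so the class splits into genotypes `B1` and `B2`
(exactly how copy-variant profiling resolves species a restriction digest
cannot). Every genotype's variant complement is fixed across its
individuals; all five genotypes are monophyletic on the COI
neighbour-joining tree; each genotype's nearest-neighbour divergence
(e.g. 31 mutational steps for `A`) exceeds the largest intra-genotype
diversity (9 steps), so every genotype sits in a barcode gap; and all
five are sympatric with others while sharing no ITS2 sequence classes and
showing no hybrid band patterns — the signature of reproductive isolation
at the rDNA locus.

Real data go through the same entry points: `read_sequences()` (FASTA or
relaxed sequential Phylip), `read_site_table()`, `read_structure()`, then
the stage functions or `run_pipeline()`. A thin command-line front end
lives at `inst/cli/ribosplit.R` (`simulate`, `digest`, `pipeline`
subcommands).

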