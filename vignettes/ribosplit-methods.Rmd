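---
title: "Delimiting cryptic species from rDNA copy variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting cryptic species from rDNA copy variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribosplit)
```

## The scientific problem

Many insect morphospecies — mosquito vectors prominently among them — are
complexes of reproductively isolated cryptic species that no morphological
key can separate. Two molecular markers with very different evolutionary
dynamics are the workhorses for resolving them:

* the **mitochondrial COI barcode**, a fast-evolving, maternally inherited
  single-copy locus that reveals divergent lineages but cannot by itself
  demonstrate reproductive isolation, and can fail for recently separated
  species whose interspecific divergence has not yet escaped the range of
  intraspecific variation (the *barcode gap* problem);
* the **nuclear ribosomal DNA second internal transcribed spacer (ITS2)**,
  one spacer in a tandem array of hundreds of near-identical rDNA repeats.
  The array evolves by *concerted evolution*: turnover machinery (chiefly
  gene conversion, and unequal crossover where recombination permits)
  spreads or removes sequence variants within a genome (*homogenization*)
  and, through interbreeding, within a population (*fixation*).

The key empirical signature this package is built around: when an rDNA
array sits in a region of restricted recombination (e.g. near a
centromere), homogenization is incomplete and a genome can stably carry a
small set of **copy variants** — repeats differing from the majority class
by a SNP or a short indel. If the array moves through an interbreeding
population as a single evolutionary unit, *every individual of that
population shows the same copy-variant complement*, while reproductively
isolated populations accumulate different complements. Copy-variant
profiles then become a species-diagnostic character, and their fixity in
sympatry is itself evidence of reproductive isolation at the rDNA locus.

`ribosplit` implements the full analysis chain used in such studies:

1. **In-silico PCR-RFLP** (`digest()`, `gel_bands()`,
   `cluster_profiles()`): Msp I (`C^CGG`) digestion of the ITS2 amplicon,
   a gel-visibility model, and band-pattern clustering into genotypes.
2. **Copy-variant profiling** (`call_variants()`, `duplex_signature()`,
   `fixation_test()`): variant classes from cloned amplicons, the
   heteroduplex banding signature they imply on a native acrylamide gel,
   and a test that the signature is fixed across conspecific individuals.
3. **Sequence statistics** (`classify_columns()`, `gc_content()`,
   `collapse_haplotypes()`, `diagnostic_substitutions()`).
4. **Divergence and trees** (`pairwise_steps()`, `divergence_summary()`,
   `nj_tree()`, `bootstrap_support()`, `monophyly()`).
5. **Sympatry and isolation** (`cooccurrence()`, `isolation_evidence()`).
6. **Compensatory base change (CBC) screening** (`map_structure()`,
   `classify_pairs()`, `cbc_screen()`).
7. A **simulator** of rDNA arrays under incomplete concerted evolution
   (`sim_config()`, `simulate_dataset()`), so the whole pipeline is
   testable against known truth.

## Conventions and numerical choices

* Residues are canonicalized to uppercase `A,C,G,T,N,-`; `U` becomes `T`;
  anything else becomes `N` with a warning. `N` never matches a
  restriction motif (conservative site calling) and is excluded, with
  gaps, from column state counts and step distances.
* All column and position indices at API boundaries are 0-based half-open;
  reports that mirror tabular output (diagnostic substitutions) use
  1-based positions and say so.
* The gel model drops fragments below `min_detectable` (default 50 bp,
  the smallest band scorable on a 3% agarose gel) and merges fragments
  within `comigration_tolerance` (default 5%, a typical 3% agarose
  resolution) by single linkage on sorted lengths, at the rounded mean.
  Band-pattern matching is a greedy size-ordered one-to-one pairing under
  the same tolerance — the computational analogue of matching lanes by
  eye against a ladder.
* Pairwise alignment (`align_pair()`) is global with affine gaps (a gap
  of length *L* costs `gap_open + L * gap_extend`; defaults 1/-1/-4/-1),
  backed by `Biostrings::pairwiseAlignment()` and memoised. Ties between
  co-optimal alignments follow the library's canonical traceback; event
  *positions* of co-optimal alignments may therefore differ between a
  pair and its swap, while event counts are symmetric.
* Variant classes are exact-identity groups of clones. An optional
  error-correction pass (`correct_errors = TRUE`) merges singleton
  classes differing from a larger class by one substitution and no indel
  — a guard against polymerase error; it is off by default because clean
  simulated clones need no correction.
* Heteroduplex signatures compare duplex classes as multisets of
  (kind, mismatch count, indel bp); clone counts are ignored because gels
  score band presence, not intensity. Electrophoretic mobility itself is
  not modelled; classes are ordered homoduplex < SNP heteroduplex <
  indel heteroduplex for display only.
* Percentage divergence divides step counts by the alignment length, the
  convention under which printed step counts and printed percentages
  agree for COI barcode data; per-pair comparable-site denominators are
  also reported (`p_dist_compared`).
* Neighbour joining (via `ape::nj`) clamps negative branch estimates to
  zero with a note. Bootstrap support resamples columns with
  replacement, rebuilds the NJ tree per replicate, and scores each
  internal edge of the full-data tree by the percentage of replicates
  containing the same leaf bipartition (branch lengths ignored); the
  caller's RNG state is saved and restored around the seeded resampling.
* The invertebrate mitochondrial genetic code (translation table 5) is
  used for COI codon classification. The reading frame is supplied, not
  inferred: amplicon frames depend on primer placement, so
  `diagnostic_substitutions()` takes `frame_offset` explicitly and
  reports both nucleotide and amino-acid indexing for every hit.
* CBC screening treats structures as *inputs* (dot-bracket, nested,
  pseudoknot-free). RNA folding is deliberately out of scope: fold
  engines are version-sensitive and the inferential step in a CBC screen
  is the comparison, not the fold. The template sequence whose fold is
  used must be named explicitly. Canonical pairs are Watson–Crick plus
  the G·U wobble; both-position changes that retain canonical pairing are
  CBCs, single-position changes are hemi-CBCs, anything else is
  disrupted, and pairs touching a gap are reported as indel overlap.

## The simulator: what it emulates, and what it does not

The generator evolves, on a shared Yule species tree rescaled to unit
depth, (i) a per-species rDNA array of `array_copies` spacer copies and
(ii) a single-copy mitochondrial locus. Array events are per-copy K2P
substitutions, *intrachromosomal* gene conversions (a random donor copy
overwrites a random recipient — the homogenizing force; interchromosomal
exchange is deliberately absent, matching the reduced-recombination
setting that produces stable copy variants), and tandem
duplications/deletions of 1–10 bp. Event counts per branch are drawn from
the jump chain with rates frozen at branch entry and applied in random
order; since indels move the total array length by well under 1%, this is
a second-order approximation to exact waiting times at a fraction of the
cost.

Arrays are tracked at species level with optional individual-level noise
because the observable of interest is the species-fixed variant
complement; the default `within_species_noise = 0` realizes the fixation
hypothesis exactly, and tests break it with engineered private variants
rather than with population genetics.

Default rates were chosen once to land in the qualitative regime the
biology dictates, using Moran-model expectations: with per-copy
substitution events at array rate $M$ and conversions at rate $C$, the
standing number of variant classes behaves like an Ewens sample with
$\theta \approx n_\text{copies} M / C$, while the species consensus
diverges at rate $M / n_\text{copies}$. The defaults
(`sub_rate_rdna = 0.03`, `conversion_rate = 9000`, `indel_rate = 2`,
20 copies of a 620 bp spacer) give $\theta \approx 0.9$ — arrays with a
dominant majority class plus 0–4 fixed variants, occasionally including
an indel variant — and inter-species spacer divergence of roughly 1–8%,
with amplicons of about 680 bp (620 + 2 × 30 bp conserved primer
flanks) at 62% GC, drawn with exact base composition so GC is a
controlled property. Four `CCGG` motifs are written into the ancestral
spacer at spread positions so digestion starts from a multi-band pattern
whose turnover differentiates species. The mitochondrial locus evolves
five times faster per site, plus a short private terminal branch per
individual (`coi_individual_depth = 0.05`) for realistic within-species
haplotype diversity.

Clone pools are composed deterministically from the array: the most
abundant classes first, up to the clone budget, with the remaining
budget repeating the majority class. The heteroduplex gel sees every
variant class in the genome because the whole array is amplified;
random subsampling of 4–5 clones would mis-state that observable and
make the fixation test depend on sampling luck rather than on the
biology being modelled. PCR error (`pcr_error`) and within-species noise
re-introduce stochastic clone variation when a test wants it.

What the simulator does **not** emulate — so what passing tests do *not*
show about real data: unequal crossover and copy-number change;
selection and rDNA pseudogenes; population-level coalescent structure
within species; chimeric clones and alignment error; partial digestion
and gel-mobility artifacts; and real ITS2 secondary structure (planted
CBC coordinates stand in for folded helices). Conclusions about real
datasets must rest on the deposited-data checks, not on simulation.

## Genotype assignment and the refinement invariant

`assign_genotypes()` reproduces the two-tier genotyping logic: RFLP
classes from the majority-amplicon digest, then a split of each RFLP
class by heteroduplex signature. The signature partition can only refine
the RFLP partition, never coarsen it — two individuals with different
digests never share a genotype, while one RFLP class can harbour two
signature classes (the phenomenon that splits one restriction genotype
into two cryptic species). Two species can remain merged if they share
both the digest pattern *and* the abstract signature; that is a faithful
limitation of the assay, not of the implementation, and the sequence-level
stages (haplotypes, trees, distances) are where such pairs separate.

The reproductive-isolation score for genotype *g* requires: *g* sympatric
with another genotype; no ITS2 sequence class shared between *g* and any
sympatric partner; and no individual *of g* whose band pattern equals the
gel-merged union of *g*'s and another genotype's patterns (what an F1
would show). The hybrid scan is restricted to individuals of the two
genotypes involved: with few-band patterns, a third genotype's pattern
can coincidentally equal a union, and such a coincidence says nothing
about gene flow between the pair.

## Study-scale problem sizes

The bundled survey tables carry the real study's tabulated results (302
specimens, 76 sites, 9 genotypes) and are analysed exactly. Simulated
checks run at the study's sampling design — 9 species × 3 individuals ×
5 clones, 13 sites — with 100 bootstrap replicates for the COI tree;
module tests use 2–5 species. These sizes keep every property sharp (the
partition identities and oracle equivalences are exact at any size)
while the whole suite completes in well under a minute.

## Known limitations

* Interleaved Phylip and GenBank flat files are not parsed; alignments
  are accepted as given (only pairwise alignment is computed in-package).
* Multi-enzyme double digests and partial digestion are not modelled.
* The NJ + bootstrap tree is a deliberate stand-in for likelihood and
  Bayesian inference; topology-level conclusions (monophyly, clade
  support) are its intended use, branch lengths are not.
* Band patterns printed only as "below 100 bp" cannot anchor exact
  matching and are treated as unsized.
* Pseudoknotted structures are rejected by the dot-bracket parser;
  CBC screening covers nested structures only.
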