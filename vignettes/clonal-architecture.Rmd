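---
title: "Clonal architecture and the apparent mutation burden of tumours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal architecture and the apparent mutation burden of tumours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonarch)
```

## The problem

Bulk whole-genome sequencing of a tumour detects a mutation only when a
substantial proportion of the sequenced cells carry it. In a tumour that
grew through successive clonal sweeps, most of the per-cell mutation burden
is truncal and therefore bulk-visible. But some tumours — notably kidney
tumours of very young children — evolve like a normal tissue: a very short
trunk (single-digit to low-double-digit shared mutations) followed by many
near-independent lineages, each carrying tens to hundreds of private
mutations. Bulk sequencing of such a "comb-like" tumour sees little more
than the trunk, and the tumour appears hypomutated even though each of its
cells carries a burden comparable to, or higher than, normal cells of the
same age. Single-molecule duplex sequencing, which calls mutations present
on one original DNA duplex (hence in one cell), measures the per-cell
burden directly and exposes the discrepancy.

`clonarch` implements the full inference machinery needed to reproduce and
quantify this effect on synthetic data: a clonal-architecture simulator, a
duplex consensus caller and burden estimator, the bulk substitution filter
stack with depth downsampling, the phylogeny-construction pipeline
(germline, strand-imbalance, confidence, and copy-number filters; maximum
parsimony; maximum-likelihood mutation assignment; branch scaling),
architecture statistics, and a rule-based driver annotator.

## The simulator

### Phylogenies

`simulate_phylogeny()` draws a rooted mutation-bearing tree in one of two
modes:

* **comb** — root, one trunk branch, then `n_clones` terminal lineages
  with private branches. Trunk length is uniform on `trunk_range`
  (default 9–26); private branch lengths are negative-binomial with mean
  `private_mean` (default 300) and dispersion `private_disp` (default 10).
  The negative binomial was chosen because lineage-level mutation counts
  are overdispersed relative to Poisson in real tissues; the dispersion
  default keeps the coefficient of variation near 35% at the default mean.
* **sweep** — a long trunk followed by a chain of nested subclones with
  configurable cell fractions (default 0.5/0.3/0.2) and internal branch
  lengths, then short private branches.

Clone cell fractions in comb mode, when not given, are a symmetric
Dirichlet draw with concentration 10. The concentration matters: comb-mode
lineages must be *near-independent*, with no clone large enough to act as
a detectable subclone — a 20-clone tumour containing a 25%-fraction clone
is partly sweep-like, which is exactly the architecture comb mode is
defined against. Concentration 10 keeps the largest of 20 clones near
0.1 while still varying clone sizes realistically. The fractions are
exposed as configuration for anyone wanting a different regime.

Mutations are placed uniformly over a 22-autosome genome model under an
infinite-sites assumption (no recurrence; duplicate positions redrawn),
with burden reported per diploid genome of 6.2 Gb. At the burdens studied
(tens to hundreds of mutations) recurrence is astronomically unlikely, so
infinite sites is innocuous.

### Presets

`preset_library()` fixes the study conditions. Per-cell burden targets are
met by solving `trunk midpoint + mean branch path below the trunk =
target midpoint`:

| preset | mode | trunk | per-cell target |
|---|---|---|---|
| `neonatal_comb` | comb | 9–26 | 65–92 |
| `schoolage_sweep` | sweep | 150–200 | 221–248 |
| `colorectal_sweep` | sweep | 450–550 | (adult-cancer regime) |
| `neonatal_normal_kidney` | comb | 0–5 | 65–92 |
| `schoolage_normal_kidney` | comb | 0–5 | 221–248 |

The school-age sweep preset accounts for the expected internal-branch
contribution (fraction-weighted chain depth) in its calibration.

### Observations

Three observation layers share one generating tree:

* **Microbiopsies** (`sample_biopsies()`): each ~100-cell biopsy draws its
  cells from one locally dominant clone (the clonal-unit assumption used
  for tree building) with 5% admixture from one random sibling clone by
  default, so the clonal-unit approximation is testable rather than
  hard-coded.
* **Bulk pieces** (`bulk_piece_genotypes()`): the chunk bulk WGS sequences
  is a polyclonal mixture, so each mutation's cell fraction is its
  tumour-wide carrier fraction, with mild local clone enrichment
  (Dirichlet concentration 100 around the global fractions). This
  distinction between a bulk piece and a microbiopsy is essential: a
  microbiopsy is nearly clonal and would reveal private mutations at
  VAF ~0.5, which is not what bulk sequencing of a tumour piece sees.
* **Duplex bundles** (`simulate_duplex_bundles()`): each interrogated
  bundle-base originates from one cell drawn by clone fraction; a bundle
  over a mutated site carries the variant on both strands; per-read errors
  are independent. Bundle metadata (reads per strand, consensus qualities,
  read-end offsets, per-read mismatch counts, alignment-score margins)
  follow configurable clean/noisy mixtures so every consensus filter has
  something to reject. Mutation-bearing (and double-strand-error) bundles
  are materialised read by read; the overwhelmingly more numerous clean
  reference bundle-bases are accounted in aggregate with exact binomial
  draws of how many pass the interrogation filters — distributionally
  identical to materialising them, and testable against the explicit
  read-level mode (`explicit_background = TRUE`).

Read counts are binomial: depth Poisson around the target (default 30X),
mutant reads `Binomial(depth, purity x cell fraction x 0.5)` under the
heterozygous-diploid model, strand split symmetric. Matched normals carry
zero somatic tumour mutations except configurable embryonic mosaic
variants (low cell fraction in the normal, truncal in the tumour) and
shared germline heterozygous sites. Mis-mapping artefacts are injected in
three flavours (low alignment score, heavy clipping, strand-imbalanced) so
each bulk filter's removal behaviour is exercised.

## Duplex consensus calling and burden

A variant is called from a read bundle iff: at least two reads per strand;
every read's alignment-score margin exceeds 50; at most two mismatches per
read; the call at least 8 bp from the nearer read end; both strand
consensuses (unanimous within strand) agree on the same non-reference
base; and the consensus base quality is at least 6. Where the aggregation
of per-read qualities was open, the minimum over supporting reads was
chosen as the conservative option. Rejection reasons are reported in a
fixed canonical order; re-ordering the rules can change the recorded
reason but never the outcome.

A bundle-base is *interrogated* iff it passes every
non-variant-dependent rule (completeness, margin, mismatches, read-end
trim). The burden estimate is

```
burden = calls / interrogated bundle-bases x diploid genome size,
```

with an exact Poisson (Garwood) 95% interval on the call count. Counting
the denominator this way keeps it consistent with the numerator — a base
that could never have yielded a call must not dilute the rate. Counts here
are small (tens), which is why the exact interval is used rather than a
normal approximation. `contamination_adjusted_burden()` inverts the
dilution by non-tumour cells: `(observed - f x non-tumour burden)/(1 - f)`.

## Bulk filtering and burden

`qc_filter()` removes records whose supporting reads have median alignment
score < 140 or clipped fraction >= 0.5; `organoid_vaf_filter()` removes
records at VAF <= 0.3 in organoid samples (in-vitro mutations);
`downsample_to_depth()` subsamples reads without replacement
(hypergeometric — reads are a finite pool, and drawing mutant totals then
forward-strand parts keeps strand counts consistent) to a reference
coverage, 30X by default. The bulk burden of a sample is the number of
passing records called in it. Since the published probabilistic caller is
not re-run here, a transparent stand-in detection rule is used: at least 4
mutant reads with both strands represented — the same confidence criteria
the phylogeny module uses. The rule is configurable; its exact form shifts
the bulk count by a handful of noise calls but not the architecture-driven
discrepancy.

Panel-of-normals SNP masking and the cruciform-DNA artefact filter for
low-input libraries are represented as optional site-exclusion inputs
rather than re-derived; the simulator does not generate population SNPs.

## Phylogeny construction

The filter stack, applied per record:

* **Germline**: removed iff the matched normal is consistent with clonal
  heterozygosity (two-sided exact binomial against 0.5, not rejected at
  `alpha_clonal` = 0.01) *and* the tumour is not enriched over the normal.
  Enrichment is a one-sided exact two-proportion (Fisher) test of pooled
  tumour counts against the normal's counts at `alpha_enrich` = 0.001. A
  two-sample test is deliberate: testing tumour reads against the
  normal-VAF *point estimate* mis-labels half of genuine germline variants
  as "enriched" at 30X, because the point estimate is noisy. Embryonic
  mosaic variants (low normal VAF, clonal in tumour) fail the clonality
  test and survive, by design.
* **Strand imbalance**: two-sided exact binomial on the pooled
  forward/reverse mutant split against 0.5, removal at `alpha` = 0.001.
  Untestably small counts (one mutant read, p = 1) are retained.
* **Confidence**: a record must be called in at least one sample with
  >= 4 mutant reads, VAF >= 0.3, and both strands represented.
* **Copy number**: variants in segments whose total copy number differs
  across samples are excluded (`standard` mode), or only deleted regions
  in heavily rearranged genomes (`deletion_only`); the excluded genome
  fraction feeds branch scaling.

The significance defaults are conservative at 30X and are configuration,
not constants.

Trees are built over clonal units by maximum parsimony on binary presence
characters, rooted by a zero-mutation outgroup representing the matched
normal. Identical columns are collapsed into weighted characters. Up to 8
units the search is exhaustive over all rooted topologies (10,395 at 7
units) scored by a two-state dynamic program, so the result is exact;
beyond that, a greedy perfect-phylogeny construction (clades accepted in
decreasing weight if laminar with those already accepted) is refined by
leaf-regraft hill climbing. Regrafting single units was preferred to
nearest-neighbour interchange because the trees here are strongly
multifurcating (a comb is one big polytomy), where NNI is undefined on
most edges; leaf regrafts explore a superset of the useful moves at these
sizes (20–30 units). Ties are broken deterministically by enumeration
order, so identical inputs give identical trees.

Mutations are then assigned to branches by maximum likelihood: for each
branch, a product over samples of binomial likelihoods with expected VAF
`0.5 x purity` below the branch and `epsilon` elsewhere (default 1e-4,
clamped to >= 1e-12 so the log-likelihoods stay finite as `epsilon -> 0`).
Variants in concordant non-diploid regions can override the 0.5 factor
with mutant-copies/total-copies (one mutant copy assumed). Ties prefer the
larger clade, then the lower node id. Mutations with zero mutant reads
everywhere are flagged unassignable and excluded from branch lengths.
Branch lengths are scaled as `raw/(1 - excluded fraction)`, which
preserves all branch-length ratios.

The trunk is defined as the branch path from the root to the first node
with at least two tumour descendants.

## Architecture statistics

`architecture_report()` collects trunk length, mean per-cell burden (mean
root-to-leaf path), bulk and duplex burdens, their fold change and
absolute difference, and the *detected fraction* (bulk / per-cell). The
classifier calls comb below 0.5, sweep above 0.8, intermediate between;
these cutoffs are an operationalisation of a distinction the source
material draws qualitatively, are invariant to uniform burden rescaling,
and are configurable. `total_distinct_mutations()` extrapolates the
tumour-wide distinct mutation count by summing private loads per clonal
lineage (not per cell, to avoid double-counting within clones) on top of
the trunk.

## Driver annotation

Rules, each yielding a call citing exactly one rule: hotspot missense or
in-frame events in oncogenes; truncating events in recessive-gene
footprints; focal (< 1 Mb) homozygous deletions of recessive genes;
oncogene amplifications above copy number 4 (diploid) or 8 (tetraploid);
sub-threshold oncogene amplifications and regulatory-domain
rearrangements only when RNA expression is elevated (z-score >= 2 — the
threshold is not fixed by any source and is configurable); whitelisted
fusions; breakpoints through recessive footprints; and rescue of
recurrently filtered promoter sites. A call is clonal if its mutation
assigns to the trunk. Gene models ship as an editable TSV; the bundled
list is a small synthetic fixture (real symbols, synthetic coordinates),
not a licensed census.

## What the simulations do and do not show

The generator reproduces the statistical structure the analysis relies
on: carrier-fraction-driven detectability in bulk data, single-molecule
resolution in duplex data, clonal-unit genotypes with admixture, germline
and mosaic contamination of matched normals, and filterable artefact
classes. It does not model mutational signatures or trinucleotide
context, read-level sequences (no FASTQ), indels or structural variants
as burden classes, population SNPs, or regional mutation-rate variation.
Passing tests therefore demonstrate correctness of the inference
machinery under the stated observation model, not robustness to every
artefact class in real sequencing data.

Problem sizes used by the test suite were chosen to exercise the methods
at the study's natural scales: trees of 20–50 clones; 25 biopsies of 100
cells; bulk pieces at 30X (60X for downsampling checks); duplex depths of
1e6–2e9 interrogated bundle-bases; parsimony oracle comparisons at up to
7 units against exhaustive enumeration (an independent implementation,
`phangorn`, serves as the oracle); exact-test p-values verified against
brute-force enumeration at depths up to 40.

## Known limitations

* The bulk "caller" is a transparent threshold rule, not a re-derivation
  of a probabilistic caller; absolute bulk counts on real data would
  differ, though the architecture-driven discrepancy would not.
* Duplex burden estimation at very shallow duplex depth is
  Poisson-limited: at ~1e8 interrogated bundle-bases and a burden of
  ~78/6.2e9, each simulated sample yields on the order of one call, so
  averages over tens of replicates still carry >10% sampling error. This
  is a property of the counting statistics, not of the estimator, which
  is unbiased.
* The greedy-plus-regraft search beyond 8 units is a heuristic; for the
  star-like and nested matrices this domain produces it recovers the
  optimum in practice (verified against the exhaustive oracle at small
  sizes), but adversarial homoplasy at large unit counts could defeat it.
* Biopsy admixture is modelled from a single sibling clone; real
  microbiopsies may mix more lineages.
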