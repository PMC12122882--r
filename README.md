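# clonarch

Clonal architecture simulation and mutation-burden estimation for
"hypomutated" tumours.

## The problem

Some cancers — most strikingly kidney tumours of newborns and infants —
appear to carry fewer somatic mutations than the normal tissue they arose
from. `clonarch` implements the inference machinery showing that this
apparent hypomutation can be an artefact of clonal architecture rather
than a genuinely low mutation rate. A tumour that grows like a normal
tissue has a *comb-like* phylogeny: an extremely short trunk of shared
mutations followed by many near-independent lineages, each with a long
private branch. Bulk whole-genome sequencing only detects mutations
carried by a large fraction of cells, so it sees little beyond the trunk;
single-molecule duplex (NanoSeq-style) sequencing calls mutations present
on one original DNA duplex — hence in a single cell — and recovers the
true per-cell burden. For a conventional *sweep* architecture (long
trunk, large subclones) the two methods agree.

The package is aimed at cancer-genomics methodologists who want to
reproduce, stress-test, or extend this style of analysis on fully
synthetic data with known ground truth.

## What it computes

For a site covered at depth $n$ in a sample with tumour purity $\rho$
where a fraction $f$ of tumour cells carry a heterozygous diploid
mutation, the mutant read count is modelled as
$X \sim \mathrm{Bin}(n,\; \tfrac{1}{2}\rho f)$; bulk detection requires
$X \ge 4$ with both strands represented. The duplex burden per diploid
genome is

$$\hat{B} = \frac{\text{consensus calls}}{\text{interrogated bundle-bases}} \times G_\mathrm{diploid},$$

with $G_\mathrm{diploid} = 6.2\times10^9$ bp and an exact Poisson
(Garwood) 95% interval; a bundle-base is interrogated iff it passes every
non-variant-dependent consensus filter (two reads per strand,
alignment-score margin > 50, at most 2 mismatches per read, at least 8 bp
from the read end). Phylogenies over clonal units (microbiopsies or
single-cell-derived organoids) are built by maximum parsimony on binary
presence characters (exhaustive and exact up to 8 units), mutations are
assigned to branches by maximum likelihood (expected VAF $\tfrac12\rho$
below the branch, $\epsilon$ elsewhere), and branch lengths are scaled by
$1/(1-\text{excluded genome fraction})$ for copy-number-discordant
regions. The *detected fraction* (bulk burden / per-cell burden)
classifies the architecture: comb below 0.5, sweep above 0.8.

Modules: `simulate_phylogeny()` / `preset_library()` /
`sample_biopsies()` / `bulk_piece_genotypes()` /
`simulate_duplex_bundles()` (simulator); `consensus_call()` /
`duplex_burden()` (duplex); `qc_filter()` / `downsample_to_depth()` /
`bulk_burden()` (bulk); `filter_germline()` / `filter_strand_imbalance()`
/ `filter_confident_somewhere()` / `exclude_cn_discordant()` /
`build_parsimony_tree()` / `assign_mutations_ml()` / `scale_branches()`
(phylogeny); `architecture_report()` (statistics);
`annotate_small_variants()` and friends (drivers); `run_end_to_end()`
(orchestration). See the vignette in `vignettes/clonal-architecture.Rmd`
for the models and the reasoning behind every default.

## Worked example

```r
library(clonarch)

cfg <- pipeline_config("neonatal_comb", seed = 1)
res <- run_end_to_end(cfg)
res$report
#> <architecture_report>
#>   class: comb (detected fraction 0.41)
#>   trunk 12, per-cell 61, bulk 25, duplex 82
#>   fold change 3.27, absolute difference 57
res$duplex
#> <burden_estimate> 81.7 mutations per diploid genome (duplex; 21 calls; 95% CI 50.5-124.8)
```

One simulated infant-type tumour: the generating tree had a 12-mutation
trunk and ~61 mutations per cell spread over 20 lineages. Bulk sequencing
of a tumour piece at 30X called 25 substitutions — the trunk plus noise-
level subclonal pickups — while the duplex estimate (82, CI 50–125)
recovers the per-cell burden; the 3.3-fold discrepancy with 57 additional
mutations is the hypomutation artefact, and the detected fraction of 0.41
classifies the architecture as comb. Running the same pipeline on
`preset_library("colorectal_sweep")` gives a fold change near 1 and a
sweep classification. All output files (VCF, BED, Newick trees for ground
truth and reconstruction, burden and architecture TSV/JSON, filter log)
are written when `out_dir` is given; reruns with the same configuration
are byte-identical.

A thin command-line wrapper ships in `inst/scripts/clonarch.R`:

```sh
Rscript inst/scripts/clonarch.R run-all --preset neonatal_comb --seed 1 --out out/
```

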