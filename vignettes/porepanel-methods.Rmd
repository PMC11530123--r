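---
title: "porepanel: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{porepanel: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porepanel)
```

# The problem

Nanopore adaptive sampling enriches a target panel in silico: each molecule's
first few hundred bases are compared in real time against a BED file of
target coordinates, and off-target molecules are ejected from the pore by
charge reversal. For a clinical gene panel this concentrates a single flow
cell's throughput on a small fraction of the genome, producing deep,
haplotype-resolvable coverage of every locus of interest while the
nonselective channels of a split flow cell continue to sequence genome-wide
background.

Three computational problems follow, and `porepanel` addresses each:

1. **Panel design and targeting QC.** The adaptive-sampling input is a set
   of gene intervals with a flanking buffer (default 50 kb per side, so
   molecules that begin outside a gene still carry it to full coverage).
   Whether the reference assembly actually supports that targeting is an
   empirical question: a locus with a near-identical duplicate elsewhere in
   the assembly loses its uniquely-mapped reads to the duplicate and appears
   starved. `porepanel` regresses observed on expected base fractions in
   log10 space, flags deficit loci, diagnoses the duplicate copy from
   supplementary-alignment evidence, and emits a hard-masked reference that
   repairs the targeting.
2. **Run metrics.** On-target enrichment (mean per-locus coverage over
   genome-wide background from the nonadaptive channels), phase breadth (the
   fraction of each gene's strict body covered by phase blocks), and the
   post hoc time at which a given variant pair first became jointly phased.
3. **Interpretation outputs.** Cis/trans classification of heterozygous
   variant pairs from phased genotypes, SV breakpoint spans, and focal
   hypomethylation clusters in per-site 5mC data.

# The targeting model

Let $f_i$ be locus $i$'s share of all targeted bases (its flanked target
length over the panel total; bases shared by overlapping flanked loci are
credited to the earlier-listed locus so $\sum_i f_i = 1$). Let $O_i$ be the
bases of primary, non-duplicate alignments with MAPQ at or above the
uniqueness threshold (default 1) apportioned to locus $i$ by the same
ownership rule, and $o_i = O_i / \sum O$ the observed fraction of all
observed bases (the off-target remainder completes the unit sum). Under
ideal targeting $o_i \propto f_i$, so ordinary least squares of
$\log_{10} o_i$ on $\log_{10} f_i$ has slope 1 and zero residuals; we fit

$$\log_{10} o_i = \alpha + \beta \log_{10} f_i + r_i$$

over loci with $O_i > 0$ and flag locus $i$ when
$r_i \le -z \cdot \hat\sigma$, with $\hat\sigma = \sqrt{\mathrm{RSS}/(n-2)}$
and $z = 2$ by default. The rule is one-sided: only deficits indicate a
targeting defect. Zero-observed loci cannot be log-transformed; they are
excluded from the fit and always flagged. Fractions rather than raw base
counts are regressed so the fit is library-size invariant (the slope is
unaffected either way; only the intercept differs).

Two statistical consequences shaped defaults:

* **Panel size bounds the flag statistic.** With a single outlier of
  leverage $h$ among $n$ loci, the internally studentised residual cannot
  exceed $\sqrt{(1-h)(n-2)}$, which is below 2 for $n = 6$ no matter how
  severe the deficit. A $z = 2$ flag is therefore only meaningful for panels
  of roughly ten loci and up; the bundled default scenario uses 12.
* **The flagged count is data.** The number of flagged loci is reported,
  never assumed; $z$ is a parameter.

## Duplicate diagnosis and masking

For a flagged locus, the pre-filter alignment stream (secondary and
supplementary records retained) is examined over its target. If
supplementary/secondary records carry at least half of the overlapping
aligned bases — the signature of a reference duplication absorbing the
locus's primaries — the primary alignments of those same reads are clustered
(gaps up to 10 kb merged, clusters with fewer than 3 supporting reads
dropped). Each cluster is then trimmed to the pileup region holding at least
25% of its maximum depth: a few molecules that genuinely originate inside
the duplicate copy run on into unique flanking sequence, and without the
trim they stretch the breakpoint call by up to a read length. This is the
usual consolidation of an interval call from read evidence.

Under the default `mask-duplicate-copy` policy the off-panel copy is
hard-masked with `N` (uppercase; soft masking would not stop an aligner);
`mask-in-panel` masks the in-panel supplementary footprint instead. A
candidate straddling a panel boundary is truncated to its off-panel part
with a warning recorded in the mask's provenance. Masked FASTA output is
wrapped at 60 columns with headers copied verbatim, so masking is
byte-deterministic and idempotent — properties the tests assert exactly.

# Run metrics

**Enrichment.** Per-locus coverage is aligned bases over the flanked target
divided by target length; the run-level target coverage is the unweighted
mean across loci, so small loci count as much as large ones. Background is
measured on the nonadaptive channels only: chromosomes are tiled with
non-overlapping 10-kb windows ("sliding window" is implemented as tiling —
stride equals width — so window means are independent; the stride is
configurable), windows overlapping any merged target are wholly excluded
(conservative, avoiding target bleed-through), and the mean per-window depth
is the background. Enrichment is the ratio; a zero background yields an
explicit "undefined" result rather than an error or an infinity.

**Phase breadth.** Phase blocks are derived from a phased VCF: one block per
(chromosome, PS) pair, spanning the first member variant's position to the
end of the last member's reference allele, in the package's uniform 0-based
half-open convention. Breadth for a gene is the union of block∩core lengths
over the strict gene body — the 50-kb capture flanks are deliberately
excluded. "Fully phased" means breadth exactly 1; a tolerance can be
supplied where rounding at block edges matters.

**Time to phase.** Records are scanned in start-time order. The answer is
the earliest time at which every query position is covered by at least
`min_support` haplotagged reads and all positions sit in one connected
component of phase sets, where a read links its phase set to each position
it covers and two records sharing a read id link their phase sets. The query
is a set of positions: pass the variant positions for the variant-scope
question, or a gene's core end positions for the gene-scope question — the
two scopes differ only in the input, not the algorithm.

# What the simulator states, and what a green test establishes

`synthetic_fixtures` generates every input from a seed: reference sequences
with planted duplications (copy mutated at rate 1 − identity), an
adaptive-sampling run, phased variants realizing requested phase breadths
and cis/trans labels, and a Beta-mixture methylome.

The run model is deliberately minimal:

* Accepted molecules start inside the merged targets and are drawn until
  each target interval reaches its planted depth in aligned bases; rejected
  molecules start off-target and are truncated to the 500-bp decision length
  with zero rejection latency (a latency parameter is reserved).
* Read lengths are log-normal with mean 7 kb and SD 2.5 kb — typical of a
  ligation library — and fully parameterized.
* A molecule originating in either interval of an active duplication is
  emitted as a primary record at the copy plus a supplementary record at the
  source, the signature a real aligner produces over assembly duplication
  artifacts. A duplication deactivates when at least half its copy is
  hard-masked, which is how masking repairs targeting in simulation.
* Methylomes place one site per CG dinucleotide; modified fractions are
  Beta(9, 1) (mean 0.9, the heavily methylated baseline) outside and
  Beta(1, 9) (mean 0.1) inside planted hypomethylated intervals; coverages
  are Poisson(20).

The default scenario is two 1.5-Mb chromosomes, twelve 20-40 kb loci with
10-kb flanks (~20% of the toy genome targeted), target depth 25x over
background 1.5x, one planted duplication covering most of one locus's
target, and one 2-kb planted hypomethylated interval. These are the
conditions the package's acceptance properties are evaluated under.

What the simulator does **not** emulate: nanopore error profiles and
basecalling, alignment ambiguity and MAPQ degradation (simulated primaries
carry MAPQ 60), rejection latency and pore blocking, chimeras beyond the
planted duplication signature, coverage biases, and real phasing-algorithm
behaviour (phase blocks are planted, not inferred). A green test therefore
establishes that the *computational layer* — counting, regression, flagging,
clustering, masking, interval arithmetic, classification — recovers planted
truth exactly or within stated tolerances; it says nothing about wet-lab or
basecaller performance.

# Numerical and convention choices

* Coordinates are 0-based half-open everywhere internally (BED native); VCF
  positions are converted at the ingestion boundary and printed 1-based in
  reports.
* "Reference bases consumed" by an alignment is reference-advancing CIGAR
  length (M/X/=/D), never read length; soft clips do not count. This is the
  convention under which per-base coverage is well defined.
* The hypomethylation detector is a run detector with three exposed knobs:
  site fraction at or below 0.25, at least 3 sites per cluster, inter-site
  gaps at most 500 bp. The source analysis gives no formal definition of a
  "focal cluster"; these defaults are declared in output metadata rather
  than inferred.
* Per-read modification calls are thresholded at probability 0.5; sites
  under 5x coverage are dropped before clustering.
* Ties and degenerate inputs: overlapping panel bases go to the
  earlier-listed locus (deterministic); empty panels, zero-length cores,
  zero background, and phased genotypes lacking a PS value each have a
  defined behaviour (error, error, "undefined", warning-and-ignore
  respectively).
* `expected_fractions` sums to 1 within 1e-12 by construction; observed-base
  accounting is conservative to the base because both sides of the
  regression use the same disjoint ownership intervals.

# Known limitations

A practical note on the flag rule: on an extremely clean run the residual SD
can shrink to a few thousandths of a log10 unit, at which point $z = 2$
flags loci whose coverage deviates by only a few percent. Such flags are
benign — `diagnose_duplicates` finds no supplementary signature and emits no
mask candidate for them — but they are why the flagged *count* is reported
as data rather than treated as a defect tally, and why each flagged locus is
examined individually before masking.


* Duplicate diagnosis is read-evidence-based only; the package never
  self-aligns the reference, so a duplication with no read support is
  invisible.
* Optical-duplicate detection, phasing, variant calling and SV calling are
  consumed from upstream tools, not reimplemented.
* cDNA (c.) variant names are labels only; genomic distances between
  cDNA-named variants require transcript annotation, which is out of scope.
* Pedigree (trio) consistency checking of cis/trans calls is not
  implemented; no operation takes pedigree input.
* The panel-size figure reported for a real panel counts merged bases
  (overlapping flanks once); the summed per-locus figure is also exposed
  since the convention used upstream is not stated.
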