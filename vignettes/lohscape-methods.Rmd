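---
title: "Detecting loss of heterozygosity from population allele frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting loss of heterozygosity from population allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohscape)
```

## The measurement model

lohscape infers heterozygosity and its loss from *pooled population
sequencing*: a population grown from a single founder is sequenced as one
sample, reads are mapped to a haploid reference, and a caller emits one
VCF record per site with a defined alternative allele. The per-site
**alternative allele frequency** (AAF = alternative reads / total reads)
then estimates the population allele frequency:

* a site heterozygous in the founder of a clonal (parthenogenetic)
  population stays at AAF ≈ 0.5 indefinitely;
* a site fixed for the alternative allele reads AAF ≈ 1.0;
* a site fixed for the *reference* allele produces **no record at all** —
  the caller is silent where reads match the reference.

That last asymmetry shapes the whole design. Loss of heterozygosity
toward the alternative allele is directly visible (AAF 0.5 → 1.0), but
loss toward the reference is visible only as a *SNP desert*: a long block
with no calls. Both signatures are used:

* `detect_hom_alt_tracts()` finds runs of calls with AAF ≥ 0.9;
* `detect_hom_ref_tracts()` finds call-free blocks of at least 100 kb;
* `dual_haplotype_reconcile()` closes the reference-ward blind spot by
  repeating the comparison with reads mapped to the *alternative*
  haplotype assembly, where reference-ward loss surfaces at AAF 1.0.

A further, orthogonal check: in a diploid assembly a region whose two
haplotypes collapsed into one contig receives both alleles' reads, so an
ancestral LOH region shows roughly **twice** the per-allele baseline
coverage. `doubling_test()` computes windowed depth ratios against the
median of out-of-tract windows and flags tracts whose ratio falls in
[1.6, 2.4].

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `min_qual` | 70 | Phred-like | stringent but not excessive; removes error-supported calls |
| `max_depth` | 50 (25x data) / 100 (21–54x data) | reads | repetitive sequence attracts excess depth; cutoff is per-site |
| `min_tract_bp` | 100,000 | bp | tract scale of interest; both tract classes use it |
| `hom_alt_aaf` | 0.9 | AAF | a truly fixed site at 21–25x often carries a stray reference read, so exact 1.0 is idealized |
| `het_band` | [0.3, 0.7] | AAF | binomial read-sampling spread around 0.5 at 21–54x |
| `min_hom_alt_sites` | 10 | sites | guards against isolated mis-calls spanning large gaps |
| `window_bp` | 10,000 | bp | ≥ 10 windows inside a minimum-length tract |
| `ratio_window` | [1.6, 2.4] | ratio | Poisson noise and mapping edge effects around 2.0 |
| `fp_tol` | 0.1% of shared SNPs | sites | see below |

Both filter thresholds are inclusive (`qual >= 70`, `depth <= 50`).
Coordinates are 1-based in VCF input/output and 0-based half-open in all
internal interval arithmetic and BED output.

### The run-interruption rule

A homozygous-alternative run is *supported* by sites with
AAF ≥ `hom_alt_aaf` and *broken* by any heterozygous-looking site
(AAF ≤ the upper edge of `het_band`). Sites in between — too low to
support fixation, far too high to be heterozygous — are treated as
non-informative: they neither break the run nor count toward its site
total or mean. The reason is quantitative: with Poisson depth around
21–50x and a 1% per-read miscall rate, a truly fixed site falls below
AAF 0.9 with probability ≈ 1e-4 (e.g. 5 reference reads out of 49). At
~1 marker per 100 bp that is one such site every 50–100 kb of genuinely
fixed sequence, so a rule in which *any* sub-threshold site breaks the
run would shatter every tract at exactly the length scale of interest,
while truly heterozygous sites (which fall below 0.7 essentially always)
still terminate runs where the biology does.

### The false-positive tolerance

A heterozygous site read at Poisson depth shows AAF ≥ 0.9 with
probability ≈ 2.7e-4 at 21x and ≈ 7e-5 at 25x (exact
binomial–Poisson computation), so a parent/progeny comparison over tens
of thousands of shared SNPs is expected to contain a handful of isolated
apparent LOH sites from read sampling alone. The default tolerance in
`dual_haplotype_reconcile()` — 0.1% of shared SNPs — sits an order of
magnitude above that noise floor and roughly two orders of magnitude
below the ~1,150 sites that the smallest reportable LOH event (100 kb at
1.15%/bp heterozygosity) would convert. Counts at or below the tolerance
are reported as "no ongoing LOH"; the sites themselves are still listed.

## What the simulator emulates — and what it does not

`simulate_scenario()` generates complete, ground-truthed inputs for three
reference designs:

* **f1** — a two-strain cross F1: fully heterozygous founder, selfing for
  5 generations in a population of 200, 2 contigs × 2 Mb at 1 marker per
  100 bp, 25x depth. Expected readout: AAF centered at 0.5 genome-wide
  and no tracts.
* **f2** — one F2 individual (two independent gametes of that F1, one
  obligate crossover per contig each) selfing for 3.7 generations, 50x
  depth, consistent with samples sequenced in the 21–54x range. The
  deeper coverage matters: at 25x the stray-reference-read rate at fixed
  sites is high enough (~1e-4/site, see above) that tract detection
  operates close to its breaking point, while at 50x the rate falls to
  ~1e-5 and fixed blocks behave as clean runs. Expected readout:
  homozygous-alternative tracts over alternative-fixed blocks and SNP
  deserts over reference-fixed blocks.
* **clonal** — parthenogenetic parent and progeny populations from one
  founder, 2 contigs × 1 Mb at 1.15 markers per 100 bp, 25x depth, with
  two planted collapsed homozygous-reference tracts (250 and 300 kb).
  Expected readout: no new LOH between parent and progeny; planted
  tracts recovered as SNP deserts with doubled coverage.

Sequencing noise is Poisson total depth with binomial allele sampling at
`f(1-e) + (1-f)e`, where `e` is a symmetric 1% per-read miscall rate.
Two QUAL models exist: a constant (the `sim_config()` default, 200) and
a depth-scaled "binomial" model — the Phred-scaled upper-tail probability
of the observed alternative-read count arising from miscalls alone. The
scenario presets use the binomial model, because with a constant QUAL the
quality filter cannot do its real-data job: single error reads at
homozygous-reference positions would survive filtering and salt every SNP
desert with spurious low-AAF calls. Under the binomial model such records
score QUAL ≈ 4–60 and the ≥ 70 filter removes them, while genuine
heterozygous sites at ≥ 21x score far above 70 (at 25x about 0.7% of het
sites fall below the cutoff — stringent but not excessive).

Deliberate simplifications, i.e. features of real data the simulator does
**not** model: mapping artifacts and repeat families (handled in real data
by the depth cutoff), indel errors, GC- or mappability-dependent coverage,
overdispersed (non-Poisson) depth, linkage during selfing frequency
propagation (each marker segregates independently; block structure is
simulated through `meiosis()` where it matters), and partial generations
(3.7 generations of culture time means 3 completed selfing rounds).
Passing tests on these simulations therefore demonstrate the *logic* of
the detectors under calibrated noise, not robustness to alignment
pathology — that burden stays with the upstream mapper/caller and the
depth filter.

The dual-haplotype reconciliation in the simulator uses an identity site
map (hap-2 emission swaps allele roles at the same marker coordinates).
Real haplotype pairs need a genuine coordinate correspondence from a
whole-genome alignment; `dual_haplotype_reconcile()` takes that map as
an explicit required argument for exactly this reason.

## Numerical and design choices

* **Gap convention.** A SNP desert excludes the bounding SNP positions
  themselves (they are evidence of heterozygosity) and is clipped to
  contig ends; a contig shorter than `min_tract_bp` can never yield a
  tract.
* **Matching key.** Parent/progeny SNPs pair on (contig, position,
  ref, alt); same-position records with conflicting alleles are dropped
  and counted, never force-paired. Filtering happens *before* matching.
* **Coverage baseline.** Median of out-of-tract window means — robust to
  residual repeats, and tract windows can never move it. The combined
  depth of multiple samples is summed raw before normalization; the
  doubling test is scale-invariant, so the choice only affects the
  baseline's units.
* **Headline rounding.** The mutation-accumulation report chains the
  1-decimal per-genome rate (0.2) into generations, then rounds years to
  2 significant figures, reproducing conventional back-of-envelope
  arithmetic; unrounded values are always reported alongside. The rate
  basis is haploid by default (rate = mu × haploid genome size); a
  diploid option doubles everything downstream, since a heterozygous site
  can arise on either haplotype.
* **Reproducibility.** Every generator takes a seed; a scenario is a pure
  function of (seed, config). Pipeline outputs are plain TSV/BED/JSON and
  re-running with identical inputs is byte-identical.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale: 2 contigs × 2 Mb (cross scenarios), 2 × 1 Mb
(clonal), 1 Mb instances for the brute-force oracle comparison, 500
replicates for Mendelian segregation checks, and 10^4-generation
mutation-accumulation replicates. These sizes give the statistical tests
5-sigma headroom while keeping the full suite around a minute of compute;
nothing in the implementation is specific to them, and the same functions
run unchanged on whole-genome VCFs.

## Known limitations

* Reference-ward LOH is invisible without the alternative-haplotype
  mapping; with only one reference, SNP deserts cannot distinguish
  ancestral homozygosity from assembly gaps or mapping dropout.
* The comparison makes no significance test for AAF shifts at individual
  sites; the unit of evidence is the tract / site-class count, not the
  single SNP.
* Tract boundaries are resolved to one inter-marker spacing at best.
* The accumulation simulator is infinite-sites with no back-mutation,
  selection, or drift loss; it brackets time scales, it does not date
  events.
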