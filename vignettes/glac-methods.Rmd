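---
title: "Locus–allele comparison across population stages: models and design"
author: "glacomp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-allele comparison across population stages: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glacomp)
```

## The problem

Domestication and breeding reshape a crop's gene pool in two distinct
ways. Quantitatively, allele frequencies drift and respond to selection;
this is what diversity (π), differentiation (F~ST~) and sweep scans
measure. Qualitatively, alleles disappear from the pool entirely or appear
in it for the first time, and loci lose or gain polymorphism altogether.
These "zero/one" changes are invisible to statistics that average over
frequencies, yet they are the part of evolution that actually changes what
the population *has*, not just how much of it.

Measuring them genome-wide needs two ingredients: a marker system that
carries multiple alleles per locus in gene and inter-gene regions alike,
and an ancestor→descendant sample design in which "appeared" and
"disappeared" have a direction. The package implements both for panels of
resequenced inbred accessions: multi-allelic SNPLDB markers built from SNP
linkage-disequilibrium blocks, and a fate classification of every allele
of the whole-sample universe across an ordered stage graph (e.g. wild
accessions → landraces → released cultivars, optionally with restoration
sources such as wild parents used directly in crosses).

## SNPLDB construction

**Input boundary.** Genotypes enter as a VCF of biallelic SNPs
(`readGenotypes()`); upstream read mapping and variant calling are out of
scope. Multi-allelic VCF records are dropped rather than split — the
marker's multi-allelism comes from haplotypes, and splitting records would
create phantom loci. The whole-sample minor allele frequency filter
(default ≥ 0.01, the conventional 1% cut) counts heterozygous calls as
half a dose of each allele over non-missing calls only.

**Linkage disequilibrium.** For an inbred (selfing) panel, two-site
haplotypes are read directly off accessions homozygous at both sites;
heterozygous or missing calls are skipped, never phased. |D′| =
|p~AB~ − p~A~p~B~| / D~max~ with the usual marginal bound. A pair is
*informative* when at least `minInformative` (default 5) joint calls are
usable and both sites segregate among them; a monomorphic usable subset
yields an undefined value, never a silent 0.

**Partition.** The reference block construction is only specified by its
D′ ≥ 0.70 threshold, so the package uses an explicit, testable
Gabriel-style rule: on each chromosome a multi-SNP block is a maximal
contiguous run of SNPs, grown greedily SNP by SNP, whose genomic span
stays within `maxSpanBp` (default 100 kb) and in which the proportion of
informative pairwise |D′| ≥ 0.70 values stays at or above
`strongPairProp` (default 0.95). The run closes at the first SNP whose
addition violates either condition; every SNP not absorbed into a run is
its own singleton locus. The partition is therefore exhaustive and
disjoint by construction. All four knobs are exposed; the defaults are the
package's documented stand-ins for unpublished reference internals.

**Haplotype alleles.** Per block and accession the allele is the binary
haplotype string over the constituent SNPs; any heterozygous or missing
constituent makes the locus call missing. Haplotypes rarer than
`rareThreshold` (default 0.01, mirroring the SNP MAF cut) are merged into
the Hamming-nearest frequent haplotype — ties resolve to the more frequent
target, residual ties to the lexicographically smallest — so sequencing
artifacts do not inflate the allele universe; merging never changes the
non-missing call count and can be disabled. Singleton loci keep the SNP's
two observed alleles.

## The fate taxonomy

With parent frequency $p$, child frequency $c$ and source frequencies
$s_i$, each universe allele receives exactly one category (see
`?classifyTransition` for the full predicate table). Three points deserve
emphasis:

* **Emergence vs restoration.** An allele absent from the parent but
  present in the child only counts as *emerged* (a new mutation) when it
  is also absent from every configured restoration source; otherwise it is
  *restored* — re-introduced from an earlier stage, e.g. wild germplasm
  used as a direct breeding parent. For first transitions the source list
  is empty and the distinction vanishes.
* **LPE vs LPR.** A first decrease from fixation ($p = 1$, $c < 1$) means
  a locus *gains* polymorphism (LPE) — but only if the locus was fixed in
  all sources too; if some source still segregated, the child merely
  *restores* polymorphism (LPR).
* **Ties.** $0 < p = c < 1$ is reported as its own `inherited_unchanged`
  category. The four ordinary-frequency subclasses of the reference
  presentation sum exactly to its "frequency changes" totals, leaving no
  tie class; with real data a tie is vanishingly rare, but with small
  simulated samples it is not, so ties are surfaced rather than silently
  binned into "increase".

Alleles of a locus with an undefined frequency (zero non-missing calls in
a needed population) are `unclassifiable`: itemised, excluded from
percentage denominators, never guessed.

Locus fates follow mechanically: a locus loses polymorphism exactly when
one of its alleles is LPD, gains it exactly when one is LPE — these two
identities (#LPD alleles = #disappeared loci, #LPE = #emerged loci) are
asserted in the test suite. Corner cases in which the child fixes an
allele the parent never carried, or breaks fixation without an LPE/LPR
allele, land in `fixed_replaced`, which Table-style summaries tally with
kept fixations but flag separately.

**Chains.** Along a stage path, per-allele category sequences yield the
successional flags: permanent exclusion (absent at every later stage —
vacuously true for an exclusion at the final transition), emergence
followed by inheritance, exclusion after an ordinary decrease, and
fixation after an ordinary increase. These are the quantities behind
statements like "91.88% of domestication-excluded alleles never
reappeared".

## Reporting conventions

* Frequency classes partition $[0,1]$ into $\{0\}$, $(0,0.1]$, …,
  $(0.8,0.9]$, $(0.9,1)$, $\{1\}$. Interior bins are right-closed (0.1
  falls in "0.0–0.1"); any consistent convention preserves all marginal
  sums. The "0.9–0.99" label denotes the open interval $(0.9,1)$: with the
  sample sizes this notation comes from, no attainable frequency lies
  strictly between 0.99 and 1, and implementing the open interval makes
  small simulated samples behave identically.
* In cross-tables, restored alleles appear in column "0" as a separate
  addend (a companion count matrix), never conflated with emerged ones.
* Per-year rates are count/years, and additionally per allele (or locus)
  of the universe; reports round to 2 decimals and 3 significant figures
  respectively, matching the field's table formatting, with raw values
  carried alongside.
* Composite zero/one percentages are reported as the sum of the rounded
  component percentages (e.g. 13.74 + 6.71 + 4.23 + 0.42 = 25.10), the
  convention used in the published tables this output mirrors; the raw
  ratio can differ in the last digit (25.09 here).
* Percentages use the classifiable universe as denominator;
  `unclassifiable` counts are printed next to every summary.

## Diversity, differentiation and sweeps

π and F~ST~ operate on haploid-equivalent calls (hets were already treated
as missing upstream), per constituent SNP: site π is the unbiased
$\frac{n}{n-1}(1-\sum_i p_i^2)$; F~ST~ is the Weir–Cockerham
variance-component estimator with components summed over alleles, the
locus value the ratio of components summed over its SNPs, and the genome
value the mean over loci. Negative F~ST~ estimates are reported as
computed (optional clamp). Both are verified against independent
enumeration/ANOVA oracles in the tests.

The sweep statistic itself (e.g. XP-CLR) is consumed, not computed: the
module's contract starts at a per-window score table. The threshold is the
$m$-th largest score with $m = \lceil fN \rceil$ (default $f = 0.05$),
ties included, so "top 5%" is reproducible bit-exactly; selected windows
that overlap or are book-ended merge into regions (sliding 100 kb/10 kb
windows overlap by construction). Overlap of fates with regions uses
interval intersection by default (containment is a documented option the
source presentation leaves ambiguous).

## The simulator: what it emulates and what it does not

`simulateHistory()` draws each locus's alleles from a nested ("staircase")
haplotype family $1^k0^{m-k}$, so every constituent SNP pair shows at most
three gametes and |D′| = 1 within a block, and spaces consecutive loci
further apart (150 kb) than the maximum block span — block recovery is
therefore exact by design and the planted truth is unambiguous. Stage
compositions are built by *exact counts*, not sampling: planted events
(exclusion, emergence, restoration, LPD, LPE, LPR, ordinary shifts)
realise their target frequencies exactly, background loci rescale their
parent frequencies to the child sample size, and optional drift moves a
binomial number of counts between segregating background alleles, clamped
so it can never create a zero/one change. Noise enters only as explicit
per-call heterozygous and missing probabilities. Defaults mirror the
motivating study's conditions: stages WA/LR/RC of 127/424/199 accessions,
5000-year and 100-year transitions, restoration from WA into RC, and event
numbers proportioned like the observed dynamics (exclusion ≈ 10–14% of
loci and fixation ≈ 10–15% per transition, emergence common only in the
first transition).

What passing the recovery tests shows: VCF round-tripping, block
partitioning, haplotype calling, frequency estimation and the fate
predicates compose correctly, and the classification is exact whenever
frequencies are. What it does not show: robustness to recombination
within blocks, LD decay, coalescent genealogy, genotyping error beyond
random missingness/heterozygosity, or population structure within stages —
real-data properties the staircase model deliberately omits.

## Numerical and degenerate-input choices

* Undefined quantities are `NA` plus a warning or an explicit flag —
  never silent zeros (monomorphic D′, same-allele-monomorphic F~ST~,
  π with n < 2, frequencies over zero non-missing calls).
* Rare-haplotype merge ties: frequency first, then lexicographic — fully
  deterministic.
* Catalogue order: descending whole-sample frequency, ties lexicographic.
* An all-missing locus is dropped with a warning; an empty chromosome
  yields an empty partition; an empty window set is an error.
* Every simulation requires an explicit seed; identical seeds give
  byte-identical output files.

## Problem sizes

The test suite and the acceptance script run the full pipeline at 1,000
loci × 5 stages × 300 accessions (the package's chosen validation scale,
about half a minute end to end) and the worked-example computations on the
full 559,611-allele published table inputs; the simulator's default 300
loci with the 750-accession stage design is used for the recovery
measurement. These sizes exercise every code path at realistic allele
counts while staying convenient for routine re-runs.

## Known limitations

* Outbred or phased data are unsupported: heterozygous calls become
  missing locus calls, which is correct for selfing panels only.
* The block rule is a documented stand-in for unpublished reference
  internals; block boundaries (not fate semantics) can differ from other
  SNPLDB constructions.
* Percentage denominators under heavy missingness depend on the
  unclassifiable-exclusion convention; the invariant identities, not
  absolute percentages, are the portable surface.
* Recombination as an evolutionary motivator (breaking linkage within
  blocks) is out of scope.
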