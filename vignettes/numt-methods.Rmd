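---
title: "NUMT detection, orthology and ancestry: models and design choices"
author: "numtkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NUMT detection, orthology and ancestry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtkit)
```

## The problem

Nuclear mitochondrial DNA segments (NUMTs) arise when fragments of the
mitogenome are captured at nuclear double-strand breaks. They are typically
non-functional, decay neutrally, and are gained and lost quickly over tens
of millions of years. That combination makes them attractive
presence–absence markers for phylogenetics — and makes their cross-species
orthology hard to establish, because neither the NUMT sequence nor its
non-coding flanks stay alignable between distant relatives. `numtkit`
implements a detection pipeline, statistics on where NUMTs come from and
where they land, a microsynteny-based orthology method with an analytic
error model, and presence–absence ancestral reconstruction on a
time-calibrated tree.

## Detection model

Input is a 12-column tabular hit list (outfmt-6 dialect) of a **linearized**
mitogenome (beginning with tRNA-Phe and ending with the D-loop) queried
against nuclear scaffolds. The package does not run the aligner; any local
aligner producing this format can sit upstream.

Filtering and merging parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `max_e` | 1e-3 | e-value ceiling for raw HSPs |
| `min_len` | 30 bp | minimum HSP length |
| `nuclear_gap_max` | 10 bp | nuclear gap below which continuing HSPs merge |
| `mt_gap_max` | 10 bp | allowed mitogenome gap/overlap of continuing HSPs |
| `min_contig` | 20 kb | contigs shorter than this are dropped (likely contamination/assembly error) |
| `block_gap` | 2 kb | NUMTs closer than this chain into a block |
| `identity_cut` | 98 % | identity above which a NUMT counts as recent |

Two HSPs merge when they lie on the same scaffold with the same orientation,
the nuclear gap is strictly below `nuclear_gap_max`, and the mitogenome
coordinates continue in the orientation-consistent direction within
`mt_gap_max`. The mitogenome side of that rule is symmetric with the nuclear
side by design: the merge criterion states the nuclear tolerance explicitly,
and we apply the same tolerance on the mitogenome, kept configurable. A
single insertion spanning the linearization boundary arrives as two HSPs
(one ending at the last mitogenome base, the next starting at base 1); these
merge across the circular boundary, at most once per NUMT, and the NUMT then
carries two mitogenome intervals. Opposite-orientation HSPs never merge —
inverted segments inside one insertion cannot be distinguished from two
independent insertions without raw-read evidence — while block assembly
deliberately ignores orientation. Merged identity is the
alignment-length-weighted mean of member HSP identities. After every filter,
NUMTs are renumbered densely in (scaffold order, start) order, so ids are
stable functions of the final call set.

Internally, nuclear intervals live in `GRanges` and mitogenome footprints in
`IRanges`, both 1-based inclusive, the native convention of those
containers; emitted BED is 0-based half-open and emitted GFF3 1-based
inclusive, and readers normalize accordingly.

## Origin statistics

Coverage profiles count, per mitogenome base, how many NUMT footprints
cover it. The analysis span is fixed at 16,000 bp — slightly short of a
typical mammalian mitogenome — because D-loop length varies across species
and would make windows non-comparable; the full-length profile remains
available for the per-species over-representation caller. Windows are 50 bp
(320 windows), summarized by the median per species; all 51,040 unordered
window pairs are compared across species with a two-sided Mann–Whitney test
and Benjamini–Hochberg control at FDR < 0.01. The rank-sum test uses the
normal approximation with tie and continuity correction (a small C++
kernel, since the null analysis repeats the 51,040 tests hundreds of
times), and the exact distribution when both samples have fewer than 8
observations and no ties. Two-sidedness is a deliberate choice; with no
directional hypothesis per window pair it is the conservative reading. All
species contribute to every window, including zero-coverage ones.

The null model reshuffles each NUMT's mitogenome start uniformly on
1..16,000 while keeping its length, wrapping footprints that run past the
span back to the start (circularity), and re-runs the entire window/test
pipeline per iteration. The observed significant-test count is compared to
the null distribution's quantiles. Over-represented regions are maximal
runs of bases whose coverage z-score (mean and SD over the full profile,
zeros included) exceeds 3.

## Genomic context

TE content of the 5 kb flanks is measured in ten 500 bp windows per side,
ordered outward; the background re-places every unit uniformly at random
(scaffolds weighted by eligible length — the weighting is not prescribed
anywhere, and length-proportional weighting matches a uniform-per-base
null), excluding 5 kb scaffold ends so both flanks stay on-scaffold, and
averages 1,000 iterations. Observed and background are compared per window
with a paired Wilcoxon test across species. "Intronic" means any overlap
with a protein-coding gene span; exon-level subtraction is not attempted,
and unannotated UTR insertions are classified intergenic — a known caveat
of mammalian annotation. Expression requires at least 2 junction-spanning
reads on *each* side (with ≥ 5 bp overhangs, enforced upstream) and strictly
more than 70 % read coverage. ORF status of a fully contained mitochondrial
protein-coding gene is judged under the standard nuclear code — the
relevant code for protein-coding potential after transfer to the nucleus —
with the vertebrate-mitochondrial translation reported alongside; the two
codes differ at exactly TGA, AGA, AGG and ATA.

## Synteny orthology and its error model

Each NUMT/block is anchored by the `k = 3` nearest protein-coding genes on
each side (by midpoint distance, nearest first); a gene containing the unit
is recorded as its host, not an anchor, and gene symbols occurring at
multiple loci are excluded as ambiguous. Two units from different species
are candidate orthologs when they share at least one anchor symbol and
their mitogenome footprints overlap reciprocally by at least 50 %
(wrap-aware, reciprocal-minimum). One shared anchor suffices: requiring
both sides would lose orthologs at local rearrangement or annotation gaps,
and the error model below prices the permissiveness. Candidates resolve to
a one-to-one matching greedily by descending overlap, then shared-anchor
count, then unit id — a deterministic, automated stand-in for manual
inspection of candidate pairs.

The chance that two random units are assigned as orthologs factorizes into
a synteny term and an overlap term:

$$\mathrm{rate} \;=\; \frac{2k-1}{G}\;\cdot\;\frac{2\,(L-\lceil fL\rceil)+1}{M}$$

The first factor is the probability that two units fall into the same
2k-gene window (a 2k-gene window spans 2k − 1 inter-gene intervals among G
genes); the second is the probability that two random L-bp segments on a
circular M-bp molecule overlap by at least ⌈fL⌉ bases. With G = 20,000,
L = 200 bp, M = 16,600 bp, k = 3 and f = 0.5 the rate is 3.03 × 10⁻⁶. The
expected number of chance pairs between two species is E = rate·N_a·N_b;
comparisons with E ≥ 1 are flagged unreliable and excluded from group
construction by default (switchable), since their pairs are plausibly all
noise. The factorization is kept behind a single function so a refined
model can be swapped in; a Monte-Carlo test verifies it at scaled-down
parameters.

## Ancestry

Ortholog groups are connected components of the union of all pairwise
assignments. A group is **ancestral** at an internal node when it has at
least one member species in each of the node's two child clades — which is
why the tree must be strictly bifurcating — and the rule is applied at every
node independently. The insertion rate of a species divides its individual
NUMTs having no ortholog in the sister clade by the age of its parent node.
"Most closely related species or monophyletic group" is operationalized as
the sister clade in the analysis tree. Post-insertion duplicates are not
subtracted (a tandem-duplicate detector exists for reporting, but duplicate
identification is unreliable without chromosome-level assemblies), so rates
are upper bounds. Ancestral counts operate on whatever units orthology used
(blocks by default in the pipeline), while rates use individual NUMTs; both
unit choices are the caller's.

## The simulator: what it emulates, and what it does not

`simulateDataset()` draws NUMT gains as a Poisson process on tree branches
(default 0.9 gains/Myr/lineage on a 6-taxon, 60-Myr-deep tree, giving ~200
events over its 220 Myr of total branch length), log-normal NUMT lengths
(median 200 bp, matching the error-model default, minimum 30 bp), uniform
or hotspot-biased mitogenome origins, per-copy loss (default 0.01/Myr) and
substitution decay (default 0.002/site/Myr, a mammal-like neutral rate).
Nuclear genomes are element lists — conserved gene order (120 shared gene
symbols over 3 scaffolds) with NUMT copies inserted between elements —
inherited along the tree, optionally shuffled by lineage-specific
inversions. Gaps between elements are 3 kb (so independent insertions stay
distinct at the 2 kb block threshold) except between co-inserted NUMT
copies (800 bp, so they assemble into blocks). TE intervals cover ~35 % of
each scaffold with log-normal lengths. HSP tables are emitted directly from
the truth with identity = 100·(1 − substitutions/length), split in two when
the footprint crosses the linearization boundary; wrap placements whose
pieces would fall under the 30 bp detection limit are re-drawn, since such
fragments are undetectable by construction.

The simulator makes the statistical structure the analyses assume — it does
not model indels, rate heterogeneity, segmental duplication, assembly
error, or concerted evolution. Passing tests therefore demonstrate
correctness of the algorithms under their stated model, not robustness to
every artifact of real assemblies; in particular the exact-coordinate
recovery of implanted NUMTs relies on substitution-only decay.

## Numerical and testing choices

Trees must be ultrametric within a relative tolerance of 1e-6. Rank-sum
p-values follow `wilcox.test`'s corrected normal approximation; identical
constant samples return p = 1 rather than an error. Zero-variance coverage
profiles yield no over-representation calls, with a warning. Chi-square
expected cells below 5 warn but still report. Greedy orthology ties break
lexicographically so results are order-independent and symmetric between
species. All stochastic stages take explicit seeds and are byte-reproducible.

Test problem sizes are chosen to exercise each property at meaningful power
while keeping the suite quick: merge and block oracles run on 1,000 and 200
random instances of up to 50 HSPs; the reshuffling-null calibration uses 10
species on a near-star tree (internal branches of 0.01 Myr make origins
effectively independent across species, which is the premise of the
uniform-origin null) with 200 iterations; ancestral recovery uses 20
six-taxon replicates; rate recovery 12 sister-pair replicates. The
uniform-origin calibration asserts the observed significant-test count at
or below the null's 95th percentile — an assertion that holds with 95 %
probability by construction and is pinned by a fixed seed.

## Known limitations

* Orthology depends on symbol-level gene annotation; species without it
  are excluded from orthology/ancestry (the pipeline logs the exclusion).
* The TE cumulative-coverage index is a per-scaffold integer vector, sized
  for the simulated scale rather than 3 Gb assemblies; swap in an
  interval-tree backend before applying the flank profiling to full
  mammalian genomes.
* The insertion-rate estimator inherits every upstream miss: undetected or
  unassigned orthologs inflate rates, and duplicates are not discounted.
* Presence–absence ancestral reconstruction is parsimony-flavored
  (presence in both child clades), not a likelihood model of gain/loss.
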