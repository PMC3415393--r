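---
title: "eQTL-based identity QC for matched expression and genotyping arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eQTL-based identity QC for matched expression and genotyping arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(badger)
```

## The problem

Large studies that profile the same individuals on expression arrays and
genotyping arrays accumulate sample-tracking errors: tubes swapped between
neighbouring wells, plates loaded rotated, a whole row of samples slipped by
one position, a foreign sample introduced. When the two platforms are meant
to measure the same people, the genetics itself can audit the bookkeeping.
Strong cis-eQTLs — and especially *cis-eQTL artefacts*, where a SNP under an
expression probe changes hybridisation efficiency — make the expression level
at a probe a noisy readout of the genotype at a nearby SNP. Given enough such
probe/SNP pairs, an expression array predicts a genotype fingerprint that
should match exactly one genotyping array: its own sample's.

This package implements that audit end to end: discovery of the informative
probe/SNP pairs, per-genotype density estimation, a score matrix between all
expression and genotype arrays, rank-based confirmation of the intended
pairings, graph-based resolution of the failures into concrete plating-error
hypotheses, and an iterative loop that applies confident corrections and
re-learns. Because the interesting behaviour only shows under known, planted
errors, the package ships a synthetic-cohort generator that plays the role of
the laboratory: it produces matched data with controlled eQTL structure,
population structure, tumour distortion and a ground-truth error ledger.

## The model

For eQTL pair $i$ (an expression probe and a SNP) and the three diploid
genotypes written as B-allele counts $g \in \{0, 1, 2\}$, kernel density
estimates $f_{g,i}$ of log2 expression are fitted per genotype class from
training pairs believed to be correctly matched. For expression array $j$
with level $e_{ij}$, the genotype posterior under equal priors is

$$ P(g \mid e_{ij}) = \frac{f_{g,i}(e_{ij})}{\sum_{g'} f_{g',i}(e_{ij})}, $$

and the predicted B-allele count is the posterior mean
$p_{ij} = \sum_g g\,P(g \mid e_{ij}) \in [0, 2]$. Equal priors are
deliberate: as the expression signal weakens the prediction tends to the
heterozygote (1), which is also the most likely direction of a genotype
miscall, so weak evidence is automatically punished least. Allele-frequency
priors would sharpen predictions but bias against minority genotypes; they
are not used.

The score between expression array $j$ and genotype array $k$ with observed
counts $o_{ik}$ is the sum over the eQTL set of squared differences,

$$ B_{jk} = \frac{I}{I_{jk}} \sum_{i\,:\,\text{both present}} (p_{ij} - o_{ik})^2, $$

where $I_{jk}$ counts the non-missing terms; the leading factor rescales to
the full set size $I$ so that cells with missing data remain comparable
(with complete data this is the plain sum). Low scores mean likely identity.
Ranking each row (1 = smallest; ties take the minimum rank so replicate
genotype arrays can all be rank 1) gives the rank matrix: every intended
pairing should sit at rank 1.

Per expression array, sorting its scores into order statistics
$B_{(1)} \le \dots \le B_{(m)}$ yields two diagnostics: the minimum score
$B_{(1)}$ (large when the sample appears on *no* genotype array) and the gap
$\Delta = B_{(g+1)} - B_{(1)}$, where $g$ is the largest number of replicate
genotype arrays expected; a large gap marks a confident match.

Pairs are pruned by their discrepancy $d_i$, the mean of
$(p_{ij} - o_{ik})^2$ over pairs currently believed well matched (the
reciprocal rank-1 pairs). A pair that predicts poorly even for correct
matches carries no identity information. The cutoff is placed in the middle
of the largest gap of the sorted $d_i$, but only when that gap dominates
(at least four times the median positive spacing) and only above the lower
quartile — otherwise the distribution is judged unimodal and nothing is
pruned. After pruning, scores are recomputed from the cached predicted and
observed matrices (exactly equivalent to subtracting the removed terms;
densities are not refitted).

## The iterative loop

`run_badger()` iterates: fit densities on the currently-trusted matches,
predict, score, rank, refine, propose corrections, apply the confident ones,
and return to the beginning with the full eQTL set reinstated. Trust comes
in two flavours. With a designated pilot (samples whose pairing is known to
be good), densities are always trained there and the cis scan is done once.
Without one, the first iteration trains on all intended pairs, and from then
on on the reciprocal rank-1 pairs of the previous iteration — mismatched
pairs pollute the class labels, and this bootstrap progressively cleans the
training set. The loop ends with a confirming iteration that proposes
nothing (or stops if the same correction set recurs).

### From ranks to corrections

Unresolved arrays (intended partner not rank 1) form a bipartite graph with
evidence edges where the rank falls below a threshold (default 3). The
rank-1 evidence defines a functional map on unresolved samples — sample $s$
points to the owner of the genotype array that best matches $s$'s expression
array. Its cycles are swaps and cyclic relabelings; maximal paths ending in
an orphan are slippage hypotheses, with the characteristic pair of orphan
arrays at the two ends. Disjoint 2-cycles that jointly reverse a contiguous
block are merged into a single correction, so the outer arrays of a reversed
block are not left behind once the middle swap is removed. In parallel, a
systematic search over each plate tests 180° rotation, row/column reversal
(strip reversal for 12-array chips), ±1 slips of the plate's sample
sequence, and content exchange with every same-platform plate, reporting any
transform that strictly increases the number of rank-1 intended pairings.

### Platform attribution

A pairing correction says *which* arrays belong together but not *where* the
error happened. The platform is attributed by provenance: if the affected
samples were processing neighbours (a contiguous run of the platform's
sample sequence, which runs across plate boundaries) on exactly one
platform, the error happened there and the correction is applied to that
platform's assignments. Neighbours on both — or on neither — leave the
source undetermined; the pairing is still corrected, applied by convention
on the genotype side (consistent with matching from expression arrays
towards a deduplicated genotype set), and labelled `undetermined` for
review.

### The acceptance policy

Unattended simulation needs an explicit stand-in for the human review the
method assumes between iterations. All gates are built from a per-array
robust separation
$z = (\mathrm{median} - \mathrm{min}) / \mathrm{mad}$ of the array's score
row, which self-calibrates: training contamination inflates matched scores
and compresses gaps globally, so any fixed absolute threshold (or multiple
of the typical matched score) fails either the clean or the contaminated
regime, while $z$ measures outlyingness against the array's own null scores.

* swaps/cycles: every member must be rank 1 after correction with
  $z \ge 4$ (`accept_z`). For ~100 genotype arrays the minimum of the null
  scores alone sits near $z \approx 2.5$, so 4 is decisive evidence.
* orphans: an array with $z < 3.5$ (`orphan_z`) singles out no genotype
  array at all — its sample is on no genotype array, or its own content is
  foreign.
* chains: at least three nodes (a 2-node chain cannot be told from a swap
  with one noisy member), contiguous on exactly one platform (the
  structural signature of a slip), interior members rank 1 with
  $z \ge 4$, and a terminal that is orphan-like or dead-ended. Because a
  chain orphans an array irreversibly, chains are only acted on in
  iterations where nothing else is pending.
* plate transforms: strictly positive gain in rank-1 pairings and no
  currently-correct pairing broken — except that a whole-plate transform
  composed with planted sample-level errors can leave a couple of pairs
  accidentally intact, so non-slip transforms tolerate losses when the gain
  is at least five times larger. Slip transforms never tolerate losses;
  partial slips belong to the chain mechanism.

These gates make the loop cautious by construction: under heavy corruption
(half the samples switched) only the clearest corrections clear $z \ge 4$ in
the first pass, the retrained densities sharpen, and the rest follow — so
resolution takes more than one productive iteration, while light corruption
resolves in a single pass.

## The synthetic cohort

`simulate_cohort()` emulates the study designs this method serves. Defaults
describe a 96-sample cohort: one full 8×12 genotyping plate filled
column-major, eight 12-array expression BeadChips filled in a seeded random
order constrained so that no two consecutive samples are also neighbours in
the genotype order — diverging the two layouts is precisely what makes
errors attributable, and a deterministic stride is avoided because its
arithmetic regularities can make one chip exactly closed under the plate
rotation pairing, creating artificial ambiguity between a genotype-plate
rotation and an expression-chip reversal.

Genotypes: ancestral MAF uniform on 0.2–0.5 (the method is meant to run on
common, well-genotyped SNPs), per-group allele frequencies drifted by a
Balding–Nichols Beta model with parameter $F$, Hardy–Weinberg within group,
Mendelian trios on request. Expression: per-probe baselines uniform on 7–10
log2 units (intergenic probes at a 5.5 background), a linear-additive shift
of `effect_size` (default 1 log2 unit) per B allele at true-eQTL probes,
Gaussian residual noise (`noise_sd`, default 0.3), and the effect zeroed in
groups whose `eqtl_active` flag is off — apparent eQTLs that simply do not
replicate in a minority group. Tumour genotype arrays collapse heterozygous
calls to a random homozygote with probability
`loh_rate × cellularity`: a pure tumour expresses its loss of
heterozygosity fully, stromal contamination rescues heterozygous calls.
Defaults `loh_rate = 0.3`, cellularity ~ Beta(5, 2) are field-plausible
placeholders, not estimates. Expression stays germline-driven for tumour
samples: the identity signal rides largely on tagging and hybridisation
artefacts tied to the germline sequence, while the tumour corrupts the
*calls*.

Planted errors (`inject_errors()`) cover neighbour swaps, k-cycles of
consecutive arrays, slippage by one position (the first array receives an
alien sample, the last sample goes unassayed), plate rotation and plate
swap, recorded replicates, aliens, empty arrays, and mass derangements
(disjoint random transpositions of a chosen number of samples — the
stress analogue of switching a large fraction of a cohort at once, kept
pairwise so corrections can be accepted incrementally the way an analyst
would). Every error comes with its exact inverse, so tests can demand exact
restoration of the truth.

What the generator does *not* emulate: intensity-level array artefacts,
copy-number segment structure, batch effects, sex chromosomes (sex is a
layout label only), linkage disequilibrium between SNPs, or realistic
minor-allele-frequency spectra. Passing tests therefore show that the
statistics and the resolution logic behave as designed under the assumed
generative model — not that any particular real study will reach the same
operating characteristics.

## Plate-layout design and quality metrics

The design module covers the sex-based diagnostics: an 8×12 plate has 172
orthogonal neighbour pairs, each an opportunity for a switch that a sex
check cannot see if the pair shares a sex. The blocked 1-2-2-2-1 pattern
(row blocks of sizes 1, 2, 2, 2, 1 with alternating phase, adjacent columns
complementary) leaves exactly 36 such blind pairs, three per column, and the
unequal end blocks break the 180° rotational symmetry that a 2-2-2-2
blocking (or the chequerboard, which attains the minimum of 0) would have.
Uniform random balanced layouts miss about 85 pairs on average
(analytically $172 \cdot 2\cdot\frac{48}{96}\cdot\frac{47}{95} = 85.09$),
and among 100 random plates the closest pair differs in about 30 wells —
d differing wells needing exactly d/2 simple switches to explain, since
mismatches pair off in balanced layouts and one switch fixes at most two
wells.

Array quality metrics predict whether a bad match is evidence of a plating
error or of a failed hybridisation: P95/P05 signal percentiles (linear
interpolation, pinned because scanner conventions differ) and the rank
separation between well-designed and intergenic probes, normalised by probe
count so it is comparable across platforms, invariant under monotone
intensity transforms, and *negative* on empty arrays whose background
structure favours the intergenic probes.

## Numerical choices

* Bandwidths: Silverman's rule per genotype class, floored at 0.05 log2
  units; an all-equal class is pinned to the floor (Silverman's zero-spread
  fallback would scale with the data's magnitude).
* Densities are stored as 256-point grids spanning ±4 bandwidths (for exact
  JSON round-trips) and evaluated by linear interpolation, zero outside;
  if every class evaluates to zero the posterior falls back to uniform over
  the available classes.
* Unavailable classes (fewer than 3 training arrays) contribute zero mass
  and the posterior renormalises over the rest.
* Probe–SNP distance is point-to-point (probe anchor to SNP position),
  window 1 Mb, association threshold $-\log_{10} p > 15$ via the 1-d.f.
  regression trend F-test; only perfect-tier probes are scanned.
* Ranks break ties with the minimum (replicates must all be rank 1);
  missing scores are excluded from ranking.
* Problem sizes in the test-suite simulations — 96-sample cohorts, 48-pilot
  training, 50–60 eQTL pairs, 20-cohort recovery sweeps, 20,000 random
  layouts — were chosen as the smallest sizes at which the method's
  operating characteristics are stable; separation scales roughly with the
  square root of the eQTL count, and below ~40 pairs confident automatic
  correction is genuinely not achievable, which is consistent with the
  method's reliance on a hundred-odd pairs in practice.

## Limitations

Attribution is impossible when affected samples are neighbours on both
platforms or on neither; the pairing is corrected but the sample-to-array
assignment may be wrong on the (arbitrarily chosen) genotype side. An alien
genotype array and an alien expression array for the same sample produce
the same orphan signature and cannot be distinguished from scores alone;
such cases are reported, not auto-corrected. A chance rank-1 match of an
orphaned array on its own intended partner (probability ~1/m) slips past
rank-based detection — the minimum-score diagnostics still flag it for
review. Cycles longer than `max_cycle_len` are left unresolved by design.
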