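# badger

Identity quality control for studies that run the same individuals on
expression arrays and genotyping arrays. Sample-tracking errors — swapped
tubes, rotated plates, sequences slipped by one position, foreign samples —
are inevitable in large studies; when two platforms measure the same people,
the genetics can audit the bookkeeping. `badger` predicts each expression
array's genotype fingerprint from strong cis-eQTLs (including cis-eQTL
artefacts, where a SNP under the probe perturbs hybridisation), scores it
against every genotyping array, and turns the failures into concrete,
platform-attributed plating-error hypotheses that an iterative loop can
apply and re-check.

## The statistic

For eQTL pair *i*, kernel densities *f*<sub>g,i</sub> of log2 expression are
fitted per genotype class (B-allele counts g = 0, 1, 2) on trusted matched
pairs. With equal priors, expression level *e*<sub>ij</sub> on array *j*
gives the posterior P(g | e) = f<sub>g</sub>(e) / Σ f<sub>g'</sub>(e) and a
predicted count p<sub>ij</sub> = Σ g·P(g | e) ∈ [0, 2]. The score against
genotype array *k* with observed counts o<sub>ik</sub> is the
missing-rescaled sum of squared differences

    B_jk = (I / I_jk) · Σ_i (p_ij − o_ik)²,

small when the arrays carry the same individual. Per expression array the
scores are ranked (intended partner should be rank 1) and summarised by the
minimum score B₍₁₎ (large ⇒ the sample is on no genotype array) and the gap
Δ = B₍g+1₎ − B₍₁₎ for replicate parameter g (large ⇒ confident match).
Pairs whose discrepancy d<sub>i</sub> (mean squared prediction error over
well-matched pairs) is too high are pruned at an automatic histogram-gap
cutoff and the scores cheaply recomputed. Unresolved arrays form a
bipartite graph whose cycles are swaps, whose orphan-terminated chains are
slippage, and a systematic per-plate search covers rotations, reversals,
slips and plate exchanges.

Everything is exercised on a bundled synthetic-cohort generator (matched
genotypes and expression with Balding–Nichols population structure, trios,
tumour loss-of-heterozygosity, and a planted-error ledger), so the whole
method is testable without any external data.

## Worked example

Simulate a 96-sample cohort with a planted expression-platform swap and a
genotype-platform slippage of four positions, then run the full loop:

```r
library(badger)

cfg <- cohort_config(seed = 7, error_spec = list(
  list(type = "swap", platform = "expression"),
  list(type = "slippage", platform = "genotype", length = 4)))
cohort <- simulate_cohort(cfg)

res <- run_badger(cohort$expr, cohort$geno, cohort$map)
#> iteration 1: 59 eQTLs, 6 mismatched pairs, 2 corrections proposed, 1 accepted
#> iteration 2: 58 eQTLs, 4 mismatched pairs, 1 corrections proposed, 1 accepted
#> iteration 3: 57 eQTLs, 0 mismatched pairs, 0 corrections proposed, 0 accepted

res$report
#> mixup_report: 2 correction(s), 0 unresolved pair(s), converged: TRUE
#>   [swap/expression] samples: S003, S005
#>   [chain/slippage/genotype] samples: S006, S007, S008, S009

maps_agree(res$map, cohort$true_map)
#> [1] TRUE
```

The log reads per iteration: 59 probe/SNP pairs cleared the cis scan
(−log10 p > 15 within 1 Mb), 6 intended pairings were not rank 1 (two from
the swap, four from the slippage), and one correction met the confidence
policy that round — the swap first; the slippage chain, which permanently
orphans an array, is deliberately deferred until nothing else is pending.
The final map equals the planted ground truth exactly: the swap was
attributed to the expression chip (the two samples were chip neighbours but
sat far apart on the genotyping plate), the slippage to the genotyping
plate, its first array flagged as carrying an alien sample and the last
sample marked never-genotyped.

Per-array diagnostics come from `delta_statistic(res$scores)`:

```r
head(delta_statistic(res$scores), 3)
#>   expression_array min_score      gap
#> 1            ES001  1.735503 35.42507
#> 2            ES002  2.663306 35.62210
#> 3            ES003  2.091793 32.00904
```

Minimum scores near 2 against a gap of ~35 to the next-best genotype array
are decisive matches; an array whose sample was never genotyped shows a
minimum score up at the level of the gap.

A thin command-line wrapper over the same functions ships at
`inst/cli/badger.R` (subcommands `simulate`, `discover-eqtls`, `score`,
`run`, `design-plate`, `layout-stats`, `qc`).

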