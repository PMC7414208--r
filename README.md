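# tastequiv

Equivalence inference for randomized, double-blind, single-sample taste
tests.

## The problem

Can consumers actually taste the difference between tap water and filtered
water? In the design this package analyses, each participant is randomized
to taste a *single* 200 ml sample — tap water from a public drinking
fountain or filtered water from a point-of-use (POU) dispenser, with equal
probability — and guesses which variety it was. The data reduce to a 2×2
contingency table: correct/incorrect guesses in each arm.

A conventional significance test can only demonstrate *non*-equivalence; a
non-significant result proves nothing. The inference implemented here is
built to positively establish equivalence. With

- **Se** (sensitivity) = P(reply "tap" | tap-water arm) = a/n₁,
- **Sp** (specificity) = P(reply "filtered" | filtered-water arm) = d/n₂,

distinguishability is measured by the odds ratio and the area under the
one-point ROC curve:

    OR  = Se/(1−Se) × Sp/(1−Sp)  =  (a·d)/(b·c)
    AUC = (Se + Sp)/2

OR = 1 (AUC = 0.5) means guesses carry no information about the water
variety. The OR axis is partitioned into **five regions**:

| region        | interpretation                        |
|---------------|---------------------------------------|
| OR > 2        | recognizable ability to distinguish   |
| 1 < OR ≤ 2    | negligible ability                    |
| OR = 1        | no ability                            |
| 0.5 ≤ OR < 1  | weak tendency to guess incorrectly    |
| OR < 0.5      | strong tendency to guess incorrectly  |

One-sided Wald tests on the log-OR at the outer boundaries (H: OR ≥ 2,
optionally the lenient OR ≥ 1.5; and H: OR ≤ 0.5) decide which outer
regions the data exclude; rejecting both establishes statistical
equivalence within [0.5, 2]. The **five-region confidence interval** is
the Wald interval truncated at any rejected outer boundary. The package
also provides a percentile bootstrap CI for the AUC, analytic and
Monte-Carlo power / minimal sample size for the boundary test, a
participant-level study simulator, and the embedded summary counts of the
randomized taste test conducted in the Taipei metropolis (278
participants, 139 per arm), including an exhaustive back-solver that
recovers subgroup cell counts from their printed 2-dp OR/AUC summaries.

## Worked example

```r
library(tastequiv)

t <- taipei_counts()$tables$all   # a=106, b=33, c=110, d=29
run_full_analysis(t, seed = 1, n_boot = 10000)
```

prints

```
Randomized single-sample taste test --- analysis report
input: aggregated 2x2 table

Replying "tap": 106 (76.3%) tap arm, 110 (79.1%) filtered arm, 216 (77.7%) overall
Se 0.76  Sp 0.21  OR 0.85  AUC 0.49  (log-OR -0.1663, SE 0.2886)
Five-region test on the odds ratio
  OR estimate 0.85, 95% five-region CI (0.50, 1.49)
  p[OR>=2] = 0.0015
  p[OR>=1.5] = 0.0238
  p[OR<=0.5] = 0.0340   (alpha = 0.05, one-sided)
  OR > 2 (recognizable ability)                           rejected
  1 < OR <= 2 (negligible ability)                        retained
  OR = 1 (no ability)                                     retained
  0.5 <= OR < 1 (weak tendency to guess incorrectly)      retained
  OR < 0.5 (strong tendency to guess incorrectly)         rejected
  conclusion: statistically equivalent within [0.5, 2]
AUC 0.49, 95% percentile bootstrap CI (0.44, 0.53)  [B = 10000, within_arm]
```

Read it as: participants replied "tap" at nearly the same rate in both
arms (76.3% vs 79.1%), so the estimated OR of 0.85 sits near the
no-ability point. Both outer regions are rejected at one-sided α = 0.05
(even the lenient OR > 1.5 region, p = 0.02), the five-region CI (0.5,
1.49) lies inside the equivalence region, and the AUC interval straddles
0.5: the two water varieties are statistically equivalent in taste.

Design-stage planning:

```r
min_sample_size(power_spec())
#> power 0.8002 at n = 206 (analytic)
power_at_n(power_spec(), 278)
#> power 0.8933 at n = 278 (analytic)
```

206 participants give 80% power to reject OR ≥ 2 when the truth is OR = 1;
the 278 actually interviewed give 89%.

A thin command-line wrapper over these functions is installed at
`inst/scripts/tastequiv-cli.R` (subcommands `simulate`, `analyze`,
`power`, `reproduce`).

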