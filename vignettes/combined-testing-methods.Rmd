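---
title: "Combined group-effect testing for miRNAs and their target gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined group-effect testing for miRNAs and their target gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirTarScore)
```

## The problem

A microRNA (miRNA) guides the RISC complex to a sequence-defined set of
target mRNAs and down-regulates them. When two groups of samples are
compared (treated vs control, two developmental stages, ...), the
biologically interesting events are often *simultaneous*: a miRNA shifts
between the groups **and** its target gene set shifts in the opposite
direction. Testing miRNA expression alone wastes this second stream of
evidence; testing target sets alone is blind to the miRNA itself and, as
shown below, can be badly miscalibrated when target sets overlap.

`mirTarScore` tests each (miRNA, target set) pair for a simultaneous
two-group effect by

1. feature-wise empirical-Bayes moderated *t* testing of the miRNA matrix
   and of the mRNA matrix (separately, since the two platforms have
   different noise scales),
2. one-sided gene-set testing of every miRNA's target set on the mRNA
   matrix, producing directional p-values $p^{set}_{up}$, $p^{set}_{down}$,
3. meta-analytic combination of the miRNA's one-sided p-value with the
   target set's p-value for the *opposite* direction, and
4. Benjamini–Hochberg selection on the resulting scores.

## Feature-wise moderated testing

For feature $g$ with group-mean difference $\hat\beta_g$ (group 2 minus
group 1, log2 units) and pooled variance $s_g^2$ on $d = n_1 + n_2 - 2$
degrees of freedom, the variance is shrunk toward an empirical-Bayes prior
$(d_0, s_0^2)$:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, \qquad
  \tilde t_g = \frac{\hat\beta_g}{\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$

referred to a Student distribution on $d_0 + d$ degrees of freedom. The
prior is estimated by moment matching on $e_g = \log s_g^2$: the excess of
$\mathrm{var}(e)$ over $\psi_1(d/2)$ identifies $d_0$ through
$\psi_1(d_0/2)$ (trigamma inversion by Newton iteration, tolerance
$10^{-8}$, initialized from the large-argument expansion), and the mean of
$e$ then identifies $s_0^2$. When the observed spread does not exceed the
sampling component, $d_0 = \infty$ and all features share $s_0^2$. With
$d_0 = 0$ the ordinary pooled two-sample *t* test is recovered — the unit
tests pin both limits, and the whole path is cross-checked against
`limma::eBayes` on simulated data.

"Up-regulated" always means *higher in group 2*; the second level of the
group factor (or the `levels` argument of `group_design()`) decides which
label that is, and the CLI log records it. $p_{up}$ is the upper-tail
probability, $p_{down} = 1 - p_{up}$ exactly.

## Gene-set tests

All set tests return a pair $(p^{set}_{up}, p^{set}_{down})$ per
(miRNA, set).

**Competitive, rank-based.** Gene-wise one-sided p-values are ranked over
all measured mRNAs (rank 1 = most significant in that direction; ties are
broken by feature id so results are reproducible).

* *Kolmogorov–Smirnov*: one-sided statistic
  $D^+ = \max_i (i/m - u_{(i)})$ on the normalized member ranks, with the
  asymptotic bound $p = e^{-2 m (D^+)^2}$. The bound is monotone and
  adequate for ranking sets, but conservative at the set sizes used here
  (5–30 genes), which costs the KS variant power relative to an exact tail
  — a known limitation discussed below.
* *Wilcoxon rank-sum*: normal approximation without continuity correction,
  so that $p^{set}_{up} + p^{set}_{down} = 1$ exactly (the two direction
  rankings are reverses of each other).
* *Fisher-exact enrichment*: genes with one-sided $p \le \tau$ (default
  $\tau = 0.05$, unadjusted; exposed as a flag since the source analyses do
  not fix it) are called DE, and over-representation inside the set is the
  one-sided hypergeometric tail of the 2×2 table.

**Self-contained.**

* *Quadratic-form global test* (`globalq`): score statistic
  $Q = (y-\bar y)^\top X X^\top (y-\bar y)$ with $y$ the 0/1 group
  indicator and $X$ the column-centered subset expression, referred to a
  sample-label permutation null. Global tests have no one-sided version, so
  the set is first split into its observed up- and down-moving halves
  (genes with exactly equal group means join neither half — ties were not
  observed in continuous data and the exclusion rule is the deterministic
  choice); each half provides one directional p-value. Splitting on the
  observed data introduces a mild selection bias, which is part of why
  self-contained testing inflates error rates below.
* *Rotation tests*: each gene's sample vector is reduced to a
  $(d+1)$-vector whose first coordinate carries the group contrast and
  whose remaining coordinates span the residual space. One random unit
  vector per iteration, uniform on the $(d+1)$-sphere and shared by all
  genes, replaces the effect coordinate — this preserves inter-gene
  correlation and is valid at small sample sizes where label permutations
  are too coarse. Full random orthogonal matrices are unnecessary for a
  single contrast. The self-contained *roast*-style statistic is the
  unweighted mean of the genes' normal scores (moderated *t* mapped through
  the Student CDF); the competitive *romer*-style statistic is the mean
  rank of the member genes among all measured genes. p-values use the
  add-one convention $(b+1)/(B+1)$, hence the floor $1/(B+1)$; the default
  $B = 1000$ makes p-values of $10^{-3}$ reachable. With a fixed seed the
  tests are bit-reproducible. Note that the mean-rank statistic is
  discrete: rotations can tie the observed value exactly, so the romer
  p-values sit slightly above the floor and the directional pair sums to
  one only up to the tie resolution.

Comparator global tests from the literature (ANCOVA-type and
repeated-measures global tests) are not reimplemented; the registry
(`register_set_test()`) lets users plug any external set test into the
pipeline, declaring whether its directional p-values are complementary.

## Combining the two streams

MiRNA and target set are expected to move inversely, so

$$p^{comb}_{up} = \mathrm{comb}(p^{mir}_{up},\, p^{set}_{down}), \qquad
  p^{comb}_{down} = \mathrm{comb}(p^{mir}_{down},\, p^{set}_{up}).$$

Two combiners are used, chosen automatically per set test:

* **Stouffer** (inverse normal), $1 - \Phi\!\big(\tfrac{1}{\sqrt2}
  (\Phi^{-1}(1-p_a) + \Phi^{-1}(1-p_b))\big)$, for tests whose directional
  p-values sum to one (Wilcoxon exactly; both rotation tests approximately);
* **Fisher**, the upper $\chi^2_4$ tail of $-2(\ln p_a + \ln p_b)$, for the
  others (KS, Fisher-exact, global Q).

The final score is

$$q = \min\{1,\ 2 \min(p^{comb}_{up}, p^{comb}_{down})\},$$

a two-sided summary of the more extreme pairing. This form was chosen
because it has the documented distributional behaviour of the method's
score: with the Stouffer branch and complementary inputs it reduces
algebraically to the two-sided normal p-value of the combined z-score, so
under the complete null it is uniform on $[0,1]$ (the test suite verifies a
Kolmogorov distance below 0.05 on 2000 simulated null miRNAs); with
rotation-based set tests it is slightly conservative; with the Fisher
branch it is left-skewed away from small values, i.e. conservative when
treated as a p-value. Scores are BH-adjusted across miRNAs and selection
uses the adjusted score. p-values are clipped at $10^{-300}$ before logs
and quantiles; this cannot change any decision at realistic resolutions.

A miRNA without a testable target set (absent from the set file, or fewer
than `min_set_size = 2` measured targets — the smallest set a gene-set test
can use) is never dropped: it is reported with its miRNA-only two-sided
p-value as score and flagged `no_set`.

## The synthetic-data generator

`draw_dataset()` emulates the two-platform microarray experiment:

* $n = 10$ samples per group; 200 miRNAs and 2000 mRNAs;
* baseline means drawn lognormal (meanlog 2, sdlog 0.5 — intensities
  around $e^2 \approx 7.4$ on the log2-expression scale);
* expression per group multivariate normal with unit marginal variance and
  one of three correlation structures: block-diagonal (blocks of 10,
  $\rho = 0.5$), AR(1) ($\rho = 0.5$), or an unstructured random
  correlation matrix (Wishart with $\dim + 10$ degrees of freedom, scaled
  to unit diagonal). Block and AR(1) draws use exact structure-aware
  recursions; the unstructured factor is computed once per study and its
  Cholesky reused, i.e. the covariance is treated as a fixed population
  parameter across replicate runs;
* 10% of miRNAs and 5% of mRNAs differentially expressed: half get
  $+\delta$ added to the group-2 mean, half $-\delta$, over a fold-change
  grid $\delta \in \{0,\dots,6\}$;
* a miRNA→target allocation with one set of 5–15 genes per miRNA.
  *Disjoint* sets partition a random subset of the mRNAs; *overlapping*
  sets form a circular chain in which each set shares half its members with
  the next, so sets of DE and non-DE miRNAs necessarily share genes. (A
  range of 5–15 rather than a larger one keeps 200 disjoint sets feasible
  inside 2000 mRNAs with headroom; the expected coverage is the full
  universe.)
* target degradation by a linear mean modification
  $\mu'_{jg} = \mu_{jg} - \beta \sum_i a_{ij} c_i \mu^{mir}_{ig}$ with
  $\beta = 0.5$ and per-miRNA factors $c_i \sim N(1, 0.1)$ shared across
  groups, means floored at 0.1. Because $c_i$ is shared, a *non-DE* miRNA
  modifies its targets identically in both groups and the group-null is
  preserved; a DE miRNA shifts its targets by $\mp \beta c_i \delta$,
  which is what the set tests detect.

What the generator does **not** emulate: probe-level artefacts,
non-Gaussian heavy tails, mean–variance dependence, missing values,
between-platform sample mismatches, or realistic target-prediction noise
(every simulated target is a true target). Passing simulations therefore
demonstrate calibration and relative power of the procedures under an
idealized co-expression model, not performance on any particular array
platform.

## What the simulation study shows

`run_study()` evaluates `mirna_only`, `set_only:<test>` and
`combined:<test>` selections on the *same* datasets (paired comparison),
reporting the mean realized false-discovery proportion (0/0 counted as 0)
and the average power rate TP / (number of truly DE miRNAs) per fold
change. The headline findings reproduced by the test suite and
`scripts/acceptance.R`:

* miRNA-wise moderated testing with BH keeps mean FDR at the 5% level at
  every fold change;
* combined testing based on the competitive rotation (romer) test stays at
  the level for disjoint and overlapping sets alike, at some cost in power
  (it is the conservative default);
* with overlapping sets, *self-contained* set-only selection (global Q)
  inflates the FDR dramatically at large fold changes — leaked signal from
  a DE neighbour's shared genes rejects the null miRNA's set — while
  Wilcoxon-based combined testing stays near the level;
* combined testing beats miRNA-only testing in power, with the Wilcoxon
  variant leading. Two deviations from ideal behaviour are expected and
  visible in the acceptance suite: the Fisher-exact-based combination
  inflates the FDR under overlapping sets (the $\chi^2_4$ combination lets
  a strong leaked set signal alone drive selection), and the KS variant
  gives up power because of the conservative asymptotic tail bound.

Study sizes in the packaged checks are 12–300 runs per fold change with
300–500 rotations — chosen as the point where Monte-Carlo standard errors
(~0.01–0.03 on an FDR) are small against the 5% level being verified; all
assertions carry explicit 2-standard-error allowances computed from the
same runs.

## Numerical and degenerate-input choices

* Quantile normalization uses the mean-of-order-statistics reference with
  tied values receiving the mean of their candidate values (deterministic
  and symmetric); ranks are preserved in the absence of ties.
* Zero pooled variances are excluded from the prior moment equations (the
  log is undefined) with a warning; a zero posterior variance with non-zero
  effect maps to a signed infinite statistic and p ∈ {0, 1}.
* Feature identifiers are matched exactly and case-sensitively — silent
  case-folding hides mapping bugs.
* An empty direction-split half of a set yields p = 1 with a warning
  rather than an error: a one-sided split can legitimately be empty.
* Permutation/rotation p-values never reach 0 by construction
  ($(b+1)/(B+1)$), keeping downstream logs and quantiles finite.

## Worked example

```{r example}
cfg <- simulation_config(n_per_group = 5, p_mir = 20, p_mrna = 200,
                         set_size_range = c(3, 6))
set.seed(7)
ds <- draw_dataset(cfg, delta = 3)
res <- run_pipeline(ds$mirna, ds$mrna, ds$design, ds$sets,
                    set_test = "wilcoxon", seed = 7)
head(res[order(res$score_adj),
         c("mirna", "set_size", "p_mir_up", "p_set_down", "score",
           "score_adj")])
# which selections are real?
sel <- res$mirna[res$score_adj <= 0.05]
truth <- names(ds$truth$de_mir)[ds$truth$de_mir != 0]
list(selected = sel, truly_de = truth)
```

## Known limitations

* Two-group designs only; no covariates, no multi-level factors, no
  matched miRNA/mRNA samples (the combination assumes the two p-value
  streams are independent, which matched designs violate).
* The score is a decision value, not always a p-value: exactly calibrated
  only for the Stouffer/Wilcoxon branch; conservative for rotation- and
  Fisher-branch variants.
* The KS tail bound and the normal Wilcoxon approximation trade exactness
  for speed and monotonicity.
* BH across miRNAs ignores the positive dependence created by overlapping
  target sets; the simulation study quantifies the consequences rather
  than correcting for them.
* Identifier spaces are the user's responsibility: target-set files must
  use the same (case-sensitive) mRNA identifiers as the expression matrix.
  Database target predictions given in gene space must be mapped to probe
  space (or the matrix rows renamed) before running the pipeline;
  `intersect_universe()` then handles whatever fails to match.
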