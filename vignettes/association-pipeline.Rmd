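---
title: "A five-step MARS/BIF pipeline for candidate-gene case-control association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A five-step MARS/BIF pipeline for candidate-gene case-control association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marsbif)
```

## The problem

Candidate-gene studies of athlete status compare genotype distributions at a
handful of SNPs between athletes (cases) and sedentary controls. Two things
make this harder than a per-SNP chi-squared screen: the inheritance mode of
each SNP is unknown (should a genotype count as exposed when it carries one
minor allele, two, or in proportion?), and the interesting biology may sit
in SNP×SNP or SNP×sex interactions that single-locus tests never see. With
five SNPs there are already dozens of candidate interaction terms, far too
many to test naively at n in the hundreds.

`marsbif` implements a five-step procedure for exactly this setting:

1. **Inheritance-model selection.** For each SNP, the dominant (minor-allele
   carrier), recessive (minor homozygote) and additive (allele count)
   encodings are each tested in a univariate logistic regression of
   case status; the encoding with the smallest Wald p wins, and the per-SNP
   minima are Benjamini–Hochberg adjusted across the SNP family.
2. **Interaction discovery by MARS.** The encoded SNPs plus sex enter a
   least-squares Multivariate Adaptive Regression Splines search (forward
   hinge-pair construction, backward GCV pruning, interaction degree ≤ 2,
   ≤ 100 basis functions). Before the search, pairwise linkage
   disequilibrium is screened: SNP pairs with r² above 0.8 are statistical
   proxies and are never allowed in the same model — one MARS run is made
   per pair member, excluding its partner.
3. **Logistic significance filter.** MARS proposes *covariate identities*
   (the variable set of each selected basis function, knots dropped). Each
   identity becomes one column of a joint logistic refit — the encoded
   column itself for main effects, the product column for interactions —
   and identities with Wald p > α (0.05) are discarded. MARS is thus a
   selector, not the inference engine.
4. **Bootstrap Inclusion Fraction.** The whole MARS search is rerun on B
   resamples of the rows (with replacement). The BIF of a surviving
   identity is the percentage of converged replicates whose MARS model
   proposes that exact identity; identities with BIF ≤ 50% are discarded.
   A covariate roughly uncorrelated with the others whose significance sits
   at the nominal α is proposed in about half of the resamples, so the 50%
   rule filters fragile selections.
5. **Effect estimation.** Every retained identity is translated into a
   genotype exposure rule and summarised as a 2×2 odds ratio with a Woolf
   95% confidence interval, overall and within elite / sub-elite case
   strata (controls are never stratified).

## Models and statistics

**Logistic engine.** `fit_logistic()` maximises the Bernoulli likelihood by
iteratively reweighted least squares (score max-norm < 1e-8, at most 50
iterations, step-halving). Standard errors come from the inverse observed
information, Wald p-values from the two-sided normal tail. Complete or
quasi-complete separation (a coefficient past ±15 on the log-odds scale
with boundary fitted probabilities) is *flagged*, not raised, so bootstrap
replicates that separate can be skipped and counted.

**MARS.** `mars_fit()` is classic least-squares MARS. The forward pass
repeatedly adds the reflected hinge pair max(0, x−t), max(0, t−x) — times
an existing parent basis — that most reduces the residual sum of squares,
with knots restricted to observed values; predictors with only two observed
values (encoded dominant/recessive genotypes, sex) enter as a single linear
indicator. The backward pass deletes basis functions one at a time and
keeps the subset minimising

GCV(M) = (RSS/n) / (1 − C(M)/n)², C(M) = M + penalty·(M−1)/2,

with penalty 3, the conventional value when interactions are allowed. A 0/1
response is fit by least squares deliberately: step 3 supplies the
likelihood-based inference, and the least-squares search keeps the
bootstrap affordable.

**Odds ratios.** The point estimate is the cross-product ratio (the
unconditional maximum-likelihood estimate for a 2×2 table); intervals are
Woolf's, exp(ln OR ± 1.959964·√(1/a + 1/b + 1/c + 1/d)). A single zero cell
triggers the Haldane–Anscombe 0.5 correction; two zero cells are an error.
Woolf intervals were chosen because they reproduce, after two-decimal
rounding, every published interval recomputable from the genotype count
fixtures shipped with the package.

**LD.** `ld_r2()` estimates two-locus haplotype frequencies from unphased
genotypes by EM over the double-heterozygote ambiguity (gene counting,
tolerance 1e-10, ≤ 1000 iterations) and reports
r² = D²/(p_A q_A p_B q_B). The screen runs on the full analysis sample
(cases plus controls): its purpose is collinearity control in the model,
not population inference.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | Wald retention threshold at step 3 |
| `bif_threshold` | 50 (%) | BIF retention threshold at step 4 |
| `B` | 10000 | bootstrap replicates (reference setting; exploratory runs use 200–1000) |
| `max_basis` | 100 | MARS basis functions, intercept included |
| `max_degree` | 2 | maximum interaction order |
| `penalty` | 3 | GCV cost per knot |
| `ld_threshold` | 0.8 (r²) | proxy-pair split threshold |
| `rel_tol` | 0.001 | forward-pass relative RSS stop |
| `max_missing` | 0.05 | per-SNP missingness QC ceiling |

Two defaults deserve comment. The forward stop `rel_tol = 0.001` is the
conventional MARS forward threshold: with an essentially-zero stop rule the
forward pass keeps absorbing collinear near-null products of the binary
encodings (we measured ~16 forward terms on a five-SNP cohort, with ~30% of
bootstrap replicates proposing some spurious interaction), which both slows
the bootstrap and muddies the backward pass. The `bif_count` switch selects
what a replicate must do for an identity to "appear": propose it
(`"appearance"`, the default) or propose it *and* find it significant in a
replicate-level refit (`"appearance_and_significant"`). Appearance counting
matches the definition of the BIF as the proportion of models containing
the variable; the stricter reading is available because the two differ
exactly for borderline covariates.

Identity matching in step 4 is deliberately **exact**: a replicate that
selects only `a:b` does not count as containing `a`. The alternative
(counting any term involving the variable) would make a variable's BIF at
least as large as the BIF of every interaction containing it, and thereby
could never drop a main effect while retaining its interaction — a
behaviour the method must allow. The cost of exactness is that a strong
covariate whose signal is split across near-collinear encodings (a carrier
indicator and its product with a very common second indicator) can have its
appearances scattered over several identities; borderline BIFs are
therefore genuinely unstable, and should be read as the stability
diagnostics they are rather than as sharp tests.

## The synthetic cohort generator

`simulate_cohort()` provides the ground truth every stage is tested
against. Haplotypes over the five SNPs are drawn from a pool constructed by
`simulate_haplotype_pool()`: targeted pairs attain
D = √(r²·p_a q_a·p_b q_b) exactly (an infeasible target errors with the
attainable bound), untargeted pairs sit at linkage equilibrium, and the
joint distribution is chained through the (acyclic) dependency graph of
targets. Individuals are two independent haplotypes — Hardy–Weinberg by
construction — plus a sex draw; case status follows a logistic model over
configured encodings, and sampling is by rejection until the case and
control quotas fill, matching the retrospective design whose odds ratios
the pipeline estimates.

Defaults mirror the cohort structure the pipeline is built for: 338 cases
and 603 controls, minor-allele frequencies chosen so the genotype class
proportions match the pooled control distribution of the emulated panel
(the declared "minor" allele of the two proxy SNPs is actually the commoner
one, frequency 0.58 — the generator permits this deliberately), one pair at
target r² = 0.96, 13% females, a carrier main effect and a two-SNP
interaction of realistic size. The generator does **not** model population
stratification, genotyping error, missingness, or Hardy–Weinberg departures
— so a green test suite says the statistics behave as designed on clean,
well-mixed data, not that the pipeline is robust to confounded cohorts.

Count-table fixtures (`athlete_cohort_fixture()`) are the complement: exact
deterministic expansions of published per-SNP genotype marginals, used to
replay 2×2 arithmetic. Published tables collapse heterozygote and
minor-homozygote classes, so the fixtures store a representative
heterozygote and *refuse* inheritance-model encodings, which are not
recoverable from a collapsed class; explicit genotype rules
(`odds_ratio_for_rule()`) are the supported path there. Joint genotypes
across SNPs were never published, so interaction odds ratios and BIF values
of the original study cannot be recomputed from fixtures — they are instead
validated in distribution on simulated cohorts.

## Numerical choices and degenerate inputs

- Forward-search tie-breaks are deterministic (earliest parent, lowest
  variable index, smallest knot), so a fixed seed makes entire pipeline
  runs, including the bootstrap, bit-reproducible.
- Candidate scoring works in Gram space against the orthonormal basis of
  the current model (the residual is orthogonal to it), and the backward
  pass evaluates subsets through the Gram matrix, making its cost
  independent of n.
- Monomorphic SNPs: HWE returns a flagged chi² = 0 result; r² is an error.
- Constant MARS response returns the intercept-only model; an all-case or
  all-control outcome is an error in the GLM and a skipped replicate in the
  bootstrap (excluded from the BIF denominator, which is reported as
  `b_effective`; fewer than B/2 surviving replicates abort).
- Encodings with an empty genotype class (no minor homozygote) are skipped
  in model selection; a SNP with all three encodings degenerate is an
  error.
- In the additive encoding there is no natural 2×2 exposure; the report
  collapses additive-model SNPs to the carrier indicator and labels the
  rule accordingly.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(simulation_config(seed = 7))
report <- run_pipeline(sim$cohort,
                       pipeline_config(case_groups = "sprint_power",
                                       B = 500, seed = 1))
report
tidy(report)      # covariate decisions: p, BIF, retention flags
autoplot(report)  # forest plot of retained covariates
```

Test-suite problem sizes are chosen to keep a full run affordable on one
core: simulation checks use n between 200 and 2000 with 10–40 seeds per
property, bootstrap checks use B between 50 and 1000, and the full-pipeline
recovery study uses 25 seeds at n = 900 and B = 500. The reference setting
B = 10000 changes only the Monte-Carlo error of the BIF, not its
definition.

## Known limitations

- The textbook heuristic that a covariate significant exactly at the
  nominal α is "selected in about 50% of bootstrap samples" comes from
  stepwise selection with an α-entry rule. GCV pruning with penalty 3 is
  stricter (its effective retention threshold corresponds to p ≈ 0.025),
  so in this package's own calibration checks a covariate conditioned to
  p ≈ 0.05 attains a BIF in the mid-30s to low-40s percent rather than
  50% — borderline covariates are penalised slightly harder than the
  heuristic suggests.
- The step-3 filter only ever sees covariates the GCV pruning kept, and a
  term that survives pruning is almost automatically significant at 0.05;
  the α gate therefore does little filtering on its own, and the burden of
  dropping spurious interactions falls on the BIF rule. Borderline null
  interactions (refit p between roughly 0.003 and 0.03) have BIF near 50%
  and are retained or dropped essentially by coin flip — a faithful
  property of the procedure, visible in any bootstrap-stability method.
- Exact identity counting makes individual BIF values sensitive to how the
  forward pass distributes signal across collinear encodings (see above).
- The LD split guarantees proxy SNPs never co-occur in a model but reports
  both splits' results; reconciling them is left to the analyst, as the
  two splits are the same evidence seen twice.
- No support for population structure adjustment, covariates beyond sex,
  haplotype-level association, or imputation; VCF ingest reads hard GT
  calls only.
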