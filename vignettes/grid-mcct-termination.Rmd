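---
title: "Termination criteria for between-item grid MCCTs: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Termination criteria for between-item grid MCCTs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridmcct)
```

## The problem

A grid multidimensional computerized classification test (MCCT) makes a
separate above/below decision on each of several latent traits — think of a
clinical inventory that must flag each subscale against its own cutoff, or
an achievement test issuing several pass/fail decisions at once.  Every
item loads on exactly one dimension (between-item multidimensionality).
The design question this package studies is the *termination criterion*:
after each response, should the test stop and classify a dimension, and if
the traits are correlated, should the likelihood ratio borrow strength from
the other dimension's items?

## Model and statistics

**Response model.**  Dichotomous responses follow the three-parameter
logistic model on the loaded dimension,
\(P_i(\theta) = c_i + (1-c_i)\,\mathrm{logistic}\{D\,a_i(\theta-b_i)\}\).
All functions take a `scaling` argument for the constant \(D\); the package
default is **1.7** (the classical logistic/normal-ogive calibration).  This
default is an empirical design choice: with \(D = 1.7\) the simulated
operating characteristics of the uncorrelated baseline condition match the
reference values the package's acceptance suite checks (PCC ≈ 86, total
ATL ≈ 34 at cutoffs (0,0)), while with \(D = 1\) tests become roughly 50%
longer (ATL ≈ 53) with ~40% of examinees forced at the maximum length —
far outside any plausible tolerance.  Pass `scaling = 1` to work on the
unscaled logit metric; every formula-level unit test exercises both.

**SPRT.**  For dimension \(d\) with cutoff \(\theta_0^{(d)}\) and
indifference half-width \(\delta\), the hypotheses place the trait at
\(\theta_L = \theta_0 - \delta\) versus \(\theta_U = \theta_0 + \delta\).
The likelihood ratio is compared with Wald's thresholds
\(A = (1-\beta)/\alpha\) and \(B = \beta/(1-\alpha)\): at or above \(A\)
classify *above*; strictly below \(B\) classify *below* (a ratio exactly at
\(B\) continues); otherwise administer another item.

**SPRT-SF vs SPRT-C.**  Under the between-item structure the non-target
factors of the likelihood cancel when non-target traits are held at their
provisional estimates, so the SF criterion reduces to a per-dimension SPRT
over that dimension's \(k_d\) items.  The C criterion instead evaluates
*every* administered item, imputing each non-target dimension at its
conditional-normal mean given the target trait sits at the tested bound:
with standard-normal margins \(E[\theta_q \mid \theta_d = a] = \rho a\) and
conditional variance \(1-\rho^2\) (e.g. cutoff 2, \(\delta = 0.2\),
\(\rho = 0.8\): the bounds 2.2 and 1.8 impute 1.76 and 1.44).  With
\(\rho = 0\) the imputed values coincide and C collapses to SF exactly —
the package tests this to \(10^{-12}\) and at the whole-trajectory level.

**The P-SPRT pre-rule.**  Conditional imputation helps only when the
examinee's position relative to the cutoffs is concordant with the
correlation.  After every response the pre-rule computes
\(\varphi = \rho\,(\hat\theta^{(1)}-\theta_0^{(1)})
(\hat\theta^{(2)}-\theta_0^{(2)})\) from the current bounded MLEs and uses
SPRT-C when \(\varphi > 0\), SPRT-SF otherwise (including \(\varphi = 0\),
so uninformative states default to the conservative rule).  \(\varphi\)
uses the *known* population correlation: the population model is treated as
known throughout, as is standard in this literature.

**Item selection.**  Segall-style Bayesian selection: the eligible
candidate maximising \(\det(\Sigma^{-1} + \sum I_j + I_{cand})\) with all
item information evaluated at the *cutoff vector* (classification-oriented
selection, not estimate-targeted CAT selection).  Under the between-item
structure each item's information matrix is rank one and diagonal, so the
rule reduces to comparing the best remaining candidate of each dimension
via the matrix-determinant lemma; determinant ties break to the lowest
item id.  Once a dimension is decided (and has met its 3-item minimum) its
items leave the pool, so the remaining length is spent where a decision is
still open.

**Forced classification.**  A dimension reaching the per-dimension maximum
undecided is classified toward the threshold whose log value the log
likelihood ratio is closer to: above when
\(|\log LR - \log A| < |\log LR - \log B|\), below otherwise, an exact tie
retaining the null (below).  The source literature's verbal description of
the sign convention is ambiguous (a literal reading of "positive …
indicates rejecting" conflicts with proximity-to-threshold); we adopt the
standard proximity rule and note the ambiguity here rather than guess an
intent.

## The administration loop

For each examinee: select an item, draw a response (correct iff a fresh
U(0,1) draw is strictly below \(P_i(\theta_{true})\)), update the MLE of
the administered dimension, then evaluate termination for *every* still
open dimension — under the pre-rule, \(\varphi\) and the criterion choice
are re-evaluated at every step ("in real time").  Decisions are gated
until a dimension has its minimum of 3 items; a dimension at the 30-item
maximum is forced.  The loop ends when all dimensions are decided and all
minimums are met, so total length lies in \([3D, 30D]\).

## The synthetic world

`generate_bank()` and `generate_examinees()` implement the stated
simulation design, which is also the package default everywhere:

| quantity | default | note |
|---|---|---|
| examinees per condition | 5000 | bivariate standard normal, correlation ρ |
| correlation ρ | {0, 0.3, 0.5, 0.8} | manipulated factor |
| bank | 300 items/dimension | `a ~ N(1, 0.25²)` (redrawn if ≤ 0), `b ~ U(−3.6, 3.6)`, `c ~ U(0, 0.3)` |
| cutoff pairs | nine pairs from (0,0) to (2,±2) | manipulated factor |
| δ, α, β | 0.2, 0.05, 0.05 | hence A = 19, B = 1/19 |
| length limits | 3–30 items per dimension | minimum is a content-validity floor |

Aggregates per condition: PCC (% of examinees correct on *both*
dimensions), ATL (mean total length), PCC-per-item (the ratio of the two
aggregates, not a mean of per-examinee ratios), mean LOSS
(100·misclassified + length, whose mean satisfies the exact identity
100(1 − PCC/100) + ATL), and the percentage of examinees forced at the
maximum on both dimensions.

What the generator does **not** emulate: real calibrated item banks
(parameter estimation error is absent — parameters are known truths),
model misfit, within-item multidimensionality, exposure control or content
constraints beyond the 3-item minimum, and response times.  A green test
therefore establishes that the *termination logic* behaves as specified in
an idealised 3PL world, not that the criteria are robust to calibration
error.

## Numerical choices

* **Likelihood ratios in log space.**  Products over up to 60 items are
  accumulated as log sums; user-facing functions report the ratio scale.
  During a condition the engine precomputes each item's additive log-LR
  contribution for either response under both criteria (these depend only
  on the bank, the bounds and ρ), so a test step is O(1).
* **MLE.**  Per-dimension bounded maximisation on \([-4, 4]\), tolerance
  \(10^{-6}\); perfect/zero patterns clamp to the bounds; dimensions
  without items return the population mean 0 (needed by \(\varphi\) before
  a dimension's first item).  Guessing can make short mixed-pattern
  likelihoods bimodal, so a 33-point grid scan brackets the global maximum
  before `optimize` refines it — plain `optimize` demonstrably converged to
  the wrong mode on random 10-item patterns (caught by the grid-search
  oracle test).
* **Degenerate inputs.**  δ = 0 gives a degenerate indifference region
  (allowed, tests both bounds equal); error rates outside (0, 0.5),
  nonpositive likelihood ratios, |ρ| ≥ 1, malformed banks and responses to
  unknown items raise descriptive errors naming the offending row where
  applicable.
* **Randomness.**  A base seed expands into a bank / examinees / responses
  seed triple, so criteria can be compared on identical data; at ρ = 0 the
  three criteria then produce bit-identical trajectories, which the tests
  assert.  Replaying a seed reproduces a full administration exactly.

## Known limitations

* The pre-rule and conditional imputation are validated for two dimensions
  only; the general-D formulas are present but untested beyond D = 2, and
  `criterion = "P"` refuses D ≠ 2.
* Simulated ATL at a given condition varies by roughly ±1.5 items across
  bank redraws (the quality of the few most informative items near a
  cutoff matters); comparisons between criteria should share a seed triple,
  as `run_study()` does.
* Whether items of an already-classified dimension should keep contributing
  to the other dimension's SPRT-C likelihood is underdetermined; the
  package includes them (every administered item enters), which the
  trajectory-equivalence tests pin down as the contract.
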