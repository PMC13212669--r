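---
title: "Covariate selection with false selection rate control for RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate selection with false selection rate control for RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsrcov)
```

## The problem

In RNA-seq differential expression (DE) analysis, the per-gene regression
model always contains the *primary variables* — a treatment factor, a design
blocking factor — because scientific interest or the experimental design
dictates it. Alongside them, studies routinely record many *candidate
covariates*: RNA quality measurements, cell-type concentrations in blood
samples, processing order, continuous phenotypes. Some of these are
*relevant* — associated with expression once the primary variables are
accounted for — and omitting them biases coefficient estimates and inflates
error variance. Others are *irrelevant*, and adjusting for them wastes
degrees of freedom and power. With 31 samples and a dozen candidate
covariates, which subset to adjust for is a genuine selection problem, and a
wrong answer propagates directly into the DE gene list.

`fsrcov` selects covariates by backward elimination while controlling the
**false selection rate (FSR)**: the expected proportion of selected
covariates that are truly irrelevant. The control is calibrated with
**pseudo-variables** — synthetic covariates known to be irrelevant by
construction. How often pseudo-variables survive selection estimates how
often real irrelevant covariates do.

## Per-gene model and moderated tests

Counts $c_{gi}$ (gene $g$, sample $i$) are transformed to log counts per
million with upper-quartile library sizes $R_i$ (the 75th percentile of each
sample's counts):

$$ y_{gi} = \log_2\!\left(\frac{c_{gi} + 0.5}{R_i + 1} \times 10^6\right). $$

For a model containing the primary variables and a covariate subset, each
gene follows a Gaussian linear model $y_g = X\beta_g + \varepsilon_g$ fitted
by weighted least squares with voom precision weights: a LOWESS trend (span
0.5, 3 robustness iterations) of the quarter-root residual variance
$s_g^{1/2}$ on the mean log count $\tilde c_g$ is evaluated at each fitted
log count, and the weight is the inverse fourth power of the trend value.
Residual variances are then shrunk by empirical Bayes towards a scaled
inverse-chi-square prior whose parameters $(d_0, s_0^2)$ come from
digamma/trigamma moment matching of $\log s_g^2$; tests of a coefficient
block use the moderated t (single column) or moderated F (categorical
block, $L-1$ indicator columns) with $d_0 + d$ degrees of freedom. For the
primary variable, p-values become q-values via Storey's rule with a
20-bin histogram estimate of the true-null proportion $\pi_0$, and genes
with $q \le 0.05$ are declared DE.

The whole chain is implemented in the package (`fit_voom()`,
`ebayes_moderate()`, `test_variable()`, `qvalues()`) and is verified in the
test suite against limma's `voom`/`lmFit`/`eBayes` to near machine
precision on shared fixtures, as well as against brute-force normal
equations, classical t-tests in the $d_0 = 0$ limit, and an $O(G^2)$
q-value enumeration.

## The relevance measure

A covariate tested against $G$ genes yields a vector of $G$ p-values. If the
covariate is irrelevant, that vector is approximately uniform; if relevant,
small p-values are overrepresented. The relevance measure is

$$ r(p) = \frac{\#\{p_g \le 0.05\}}{\max\{\#\{p_g \ge 0.75\}/5,\; 1\}}, $$

the ratio of the count of small p-values to one-fifth of the count of large
ones (both tails have expected mass $0.05G$ and $0.25G/5 = 0.05G$ under
uniformity, so $r \approx 1$ for irrelevant covariates). `backward_path()`
repeatedly fits the current model, computes $r$ for every remaining
candidate, removes the smallest (ties broken by declaration order, making
runs deterministic), and records $(``covariate", r)$ until none remain. For
a threshold $\lambda$, `select_at()` scans the removal sequence and returns
the first covariate whose recorded $r \ge \lambda$ together with everything
removed after it; $S(\lambda)$, the selected count, is a nonincreasing step
function. The recorded $r$ sequence need not be monotone, and this
stop-at-first-qualifying-removal rule is what makes the selected set
well defined in that case.

## Pseudo-variables and FSR estimation

Four generators produce $n \times k_P$ pseudo-variable sets $Z_b$:

* **WN** — i.i.d. standard normal entries;
* **RX** — $k_P$ randomly chosen columns of the expanded candidate-covariate
  design, all rows permuted by one shared random permutation;
* **OWN**, **ORX** — the same, then projected by $(I - H)$ where $H$ is the
  hat matrix of the intercept-augmented full design, so sample means and
  sample correlations with every real column are exactly zero.

The RX pool deliberately excludes primary-variable columns, so no copy of
the primary signal is injected; this is switchable by passing a custom pool
to `generate_rx()`. Orthogonalized variants require
$\mathrm{rank}(X) + k_P \le n - 1$, which is also the condition for backward
selection itself to start with a residual degree of freedom.

For each of $B$ sets, backward selection runs on the candidates plus
pseudo-variables. With $\bar I^*_P(\lambda)$ the mean number of selected
pseudo-variables and $\bar S_P(\lambda)$ the mean total selected, two
functionals of the FSR are estimated on the pseudo scale:

$$ \hat\alpha_{RE,P}(\lambda) = \frac{\bar I^*_P(\lambda)}{1 + \bar S_P(\lambda)},
\qquad
\hat\alpha_{ER,P}(\lambda) = \frac{\bar I^*_P(\lambda)}{1 + S(\lambda)}, $$

(RE = ratio of expectations, ER = expectation of ratios; $S(\lambda)$ from
the original, un-augmented path). Under the exchangeability assumptions —
pseudo-variables are selected like real irrelevant covariates, and relevant
covariates are unaffected by augmentation — the target FSR level $\alpha_0$
translates into a cutoff on the pseudo scale:
$c = k_P\alpha_0 / (k_P\alpha_0 + k_I)$ for RE and
$c = (k_P/k_I)\,\alpha_0$ for ER, where $k_I$ is the unknown number of
irrelevant candidates. The selection threshold is
$\hat\lambda_* = \inf\{\lambda : \hat\alpha_{\cdot,P}(\lambda) \le c\}$.

### Estimating $k_I$

$k_I$ and $\hat\lambda_*$ are coupled, and the package resolves them by a
fixed-point iteration (`estimate_ki_lambda()`): initialize $\hat k_I$ at the
total number of candidates $k_C$ (the conservative extreme), compute the
cutoff, take $\hat\lambda_*$ as the smallest qualifying grid value, update
$\hat k_I = k_C - S(\hat\lambda_*)$ floored at 1, and repeat until
$\hat k_I$ stabilizes (at most $k_C$ iterations; each update is a monotone
function of the previous, so cycling is not observed in practice and the
iteration cap is a hard stop). This iteration scheme is this package's own
design: it follows directly from the defining equations of the cutoffs, is
validated against the published selection table of the motivating pig
residual-feed-intake (RFI) blood RNA-seq analysis, and recovers
$k_I$ within $\pm 2$ on synthetic data in the test suite. If no grid point
meets the cutoff, $\hat\lambda_* = \infty$ and nothing is selected, with a
warning.

The $\lambda$ grid is the sorted union of every recorded $r$ value across
the original and augmented paths, plus 0. All estimated curves are step
functions whose jumps occur only at recorded $r$ values, so this grid is
lossless — the test suite checks that doubling the grid density never
changes the selected set. The infimum over a step function is realized as
the smallest qualifying grid point (left-continuous convention).

`fsr_select()` assembles the four steps — original path, $B$ augmented
paths, $(\hat k_I, \hat\lambda_*)$ estimation, final selection — and
`de_analysis()` runs the downstream DE analysis with the selected
covariates.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `alpha0` | 0.05 | Target FSR (proportion of selected covariates that are irrelevant). |
| `k_p` | 7 | Pseudo-variables per set. Larger is better for FSR control; the ceiling is $n - 1 - \mathrm{rank}(X)$ so one residual df remains. With $n = 31$, one binary primary variable and 13 candidate covariates (16 design columns), 7 is the maximum. |
| `B` | 100 | Pseudo-variable sets averaged in $\bar I^*_P$, $\bar S_P$. 100 gives stable curves; runtime is linear in `B`, and scaled-down values (10–20) are used in tests and the acceptance script. |
| `span` | 0.5 | LOWESS span of the mean-variance trend (the established voom default), with 3 robustness iterations. |
| `bins` | 20 | Histogram bins for $\pi_0$; right-closed intervals, $p = 1$ in the last bin. |

## Numerical choices

* 75th-percentile library sizes use type-7 (linear interpolation of order
  statistics) quantiles, fixed so results are bit-stable.
* Categorical variables use treatment contrasts against the first declared
  level; a variable with $L$ levels contributes exactly $L-1$ columns.
* The LOWESS trend is evaluated at arbitrary fitted log counts by linear
  interpolation, constant beyond the observed $\tilde c_g$ range, and
  floored at $10^{-6}$ before the $-4$ power so weights stay finite.
* Weights are computed once per model from the unweighted first pass (one
  voom pass), and recomputed from scratch for every reduced model during
  backward selection.
* $\pi_0$ is capped at 1 and floored at $1/G$; zero empirical excess
  variability of $\log s_g^2$ gives $d_0 = \infty$ (complete shrinkage to
  the common variance).
* Library sizes are computed on the matrix handed to the pipeline; gene
  filtering (`filter_genes()`, defaults mean count $\ge 8$ and at most
  $27n/31$ zeros) is an explicit, optional preprocessing step, never applied
  silently. Filtering before computing library sizes is the package's
  convention; both orders are trivially expressible.

## The synthetic-data generator

`sim_scenario()`/`simulate_counts()` generate data by inverting the
analysis model: per-gene coefficients, scaled error variances
$\sigma_g^2 \sim s_0^2 d_0/\chi^2_{d_0}$ (defaults $d_0 = 4$,
$s_0^2 = 1$, capped at $25 s_0^2$ — residual standard deviations beyond
five times the prior scale are not meaningful on the count scale), true
precision weights from a decreasing quarter-root trend in abundance (flat
outside log-count 0–16), Gaussian noise
$\varepsilon_{gi} \sim N(0, \sigma_g^2/w_{gi})$, and counts
$c_{gi} = \max\{0, \mathrm{round}(2^{y_{gi}}(R_i+1)/10^6 - 0.5)\}$
(nearest-integer rounding with a zero clamp). Defaults mirror the
motivating study's conditions: $n = 31$ samples, a balanced two-level
primary variable, 13 continuous candidate covariates, $G = 2000$ genes, an
80/20 EE/DE split on the primary variable (exact counts), standardized
effect sizes $N(0,1)\cdot\sigma_g$, and log-normal upper-quartile library
sizes around 300 with abundance intercepts calibrated so mean counts sit in
the $\ge 8$ filtered regime. Each relevant covariate carries nonzero
coefficients on 40% of genes — the original study inherited per-covariate
non-null fractions from a fit to the real RFI data, which is not
reproducible from parameters alone, so a single strongly-relevant regime
was fixed here. `make_confounded_covariate()` builds the regime where a
relevant covariate is strongly correlated with the primary variable
(population correlation $\rho$), which is where selection-free analyses
lose FDR control.

What the generator does *not* emulate: negative-binomial overdispersion at
the count level (noise is Gaussian on the log scale, exactly the analysis
model), single-cell dropout, correlated genes, batch structure beyond the
declared covariates, or the empirical parameter vectors of the RFI fit.
Passing calibration tests therefore demonstrates internal consistency of
the procedure under its own model class, not robustness to count-model
misspecification.

## Simulation harness and problem sizes

`run_study()` crosses the eight FSR variants with `Full` (adjust for
everything), `LineOnly` (no covariates) and `Oracle` (the true relevant
set), scoring per replicate: selection FSR $I/(1+S)$ and the count of
correctly selected covariates; and for DE, the empirical FDR
(false/max(1, discoveries) at $q \le 0.05$), the number of true positives,
and the partial AUC at FPR $\le 0.05$ standardized by 0.05 so 1 is perfect.
The empirical FSR is aggregated as the mean of per-replicate $I/(1+S)$ (the
ER functional); Monte-Carlo standard errors are sample SD over
$\sqrt{\text{replicates}}$.

The test suite exercises these at deliberately moderate sizes chosen once:
calibration of the eight variants on $k_R \in \{0, 2, 6\}$ uses $G = 500$,
$n = 31$, 8 candidates, $k_P = 4$, $B = 15$, 15 replicates; null relevance
calibration uses 300 single-covariate replicates at $G = 400$; $k_I$
recovery uses the 2-relevant/11-null scenario at $G = 400$, $B = 10$, 40
replicates. The acceptance script uses the larger spec of 50 replicates at
$G = 1000$ with 13 candidates, $k_P = 7$, $B = 20$.

## Known limitations

* Runtime is dominated by refitting voom for every reduced model in every
  augmented path ($O(B \cdot k_C \cdot (k_C + k_P))$ model fits); the
  per-gene weighted solves are batched in compiled code, and paths across
  $b$ are independent, hence trivially parallelizable, but the package
  itself runs serially.
* The FSR guarantees are calibrated, not exact: they rest on the
  exchangeability of pseudo-variables with real irrelevant covariates (the
  test suite checks removal-rank exchangeability empirically on null data).
* Forward selection — needed when the design has more columns than samples —
  is out of scope; only WN/RX pseudo-variables would apply there.
* Measurement error in covariates and unmeasured (surrogate) variables are
  not modeled.
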