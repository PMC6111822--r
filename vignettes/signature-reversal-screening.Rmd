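---
title: "Prognostic signatures and drug signature-reversal screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic signatures and drug signature-reversal screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigrev)
```

# The analysis in one paragraph

A driver gene (the motivating case is osteopontin, the *SPP1* gene product,
in colorectal cancer) is prognostic when patients whose tumours express it
highly survive shorter. `sigrev` implements the dry-lab chain that turns
such an observation into drug candidates: (i) dichotomize each expression
cohort at the median of the driver and compare survival between the halves;
(ii) find the genes most consistently up-regulated alongside the driver
across two independent cohorts, and assemble driver + co-regulated genes
into a query signature; (iii) screen that signature against a library of
per-drug reference expression profiles, scoring each drug by how strongly
it *reverses* the signature, with a permutation null, a leave-one-out
stability test and significance control at one expected false positive.
Every stage is also available against synthetic cohorts and libraries with
known planted structure, so the whole chain is testable without any
external download.

# Survival: median split, product-limit curve, restricted mean

`median_split()` labels a sample "high" when its expression of the
stratifying gene is strictly above the cohort median, "low" otherwise
(ties at the median fall in "low"; the rule is deterministic and matches
the convention that "high" means strictly above the cut-off).

`km_estimate()` computes the product-limit estimator

$$\hat S(t) = \prod_{t_i \le t} \left(1 - \frac{d_i}{n_i}\right),$$

with Greenwood's variance
$\hat S(t)^2 \sum_{t_i \le t} d_i / \{n_i (n_i - d_i)\}$. "Mean survival
time" is reported as the *restricted* mean survival time (RMST), the area
under $\hat S$ up to a truncation time $\tau$,

$$\widehat{\mathrm{RMST}}(\tau) = \int_0^\tau \hat S(t)\,dt,$$

computed exactly as a sum of rectangle areas. This is the convention of
the clinical-statistics packages that print a "mean survival" with a
confidence interval; the unrestricted mean is not identified under
censoring. $\tau$ defaults to the largest observed time and is
configurable — when two groups are compared their RMSTs should share one
$\tau$ (as `survival_report()` does). The RMST standard error is

$$\widehat{\mathrm{se}}^2 = \sum_{t_i \le \tau}
  A_i^2\, \frac{d_i}{n_i (n_i - d_i)}, \qquad
  A_i = \int_{t_i}^{\tau} \hat S(t)\,dt,$$

and `mean_survival_ci()` builds a symmetric normal-approximation interval
on the RMST scale (no log transform), matching the symmetric intervals
typically reported alongside KM mean survival times. The product-limit
components come from `survival::survfit()`; the log-rank comparison is
`survival::survdiff()` behind `logrank_test()`.

# Signature derivation across cohorts

`rank_differential_genes()` contrasts the high and low groups with a
per-gene Welch two-sample *t* statistic and ranks genes by descending
statistic (rank 1 = most up-regulated in the driver-high group). Welch
rather than pooled-variance *t* because array variances are rarely equal
between groups; the statistic is only used for ranking, so no
multiple-testing correction is applied — the signature is a fixed top-*k*
set, not a significance-thresholded one.

`consistent_top_genes()` scores each gene shared by all cohorts by its
*worst* rank across them and keeps the *k* best. This maximin rule is the
operational meaning of "differential consistently in both datasets": a
gene must be near the top everywhere, and a gene that is first in one
cohort but five-hundredth in the other loses to one that is third in
both. Ties break by rank sum, then lexicographically. The driver itself
is excluded from the ranking and re-added first by `build_signature()`,
giving the driver + 15 co-regulated genes signature (m = 16) of the
motivating analysis; all signs default to +1 because the co-genes are
co-up-regulated.

# Connectivity scoring

Reference profiles encode, per drug and replicate, every gene of a
universe of size $G$ as a *signed rank*: the gene most differentially
expressed after treatment has rank magnitude $G$, the least has 1, and
the sign records the direction of regulation. For a query signature
$\{(g_j, s_j)\}_{j=1}^m$ the connection strength against one profile is

$$c = \sum_{j=1}^m s_j \cdot \mathrm{rank}(g_j),$$

normalized by the maximum attainable sum $\sum_{i=0}^{m-1}(G-i)$ so the
normalized score lies in $[-1, 1]$. Strongly negative $c$ means the drug
down-regulates what the signature up-regulates (and vice versa) — it
*reverses* the signature. The screen is one-tailed on the negative side
because only reversing (inhibitory) drugs are of interest; the positive
tail is available for mimicry screens.

## Null model

The null treats the signature as $m$ genes drawn uniformly without
replacement from the profile, signs fixed at +1 (actual signs are
absorbed into the profile's signed ranks). The exact first two moments
are

$$\mu = m\,\bar r, \qquad
  \sigma^2 = m\,\mathrm{Var}_{\mathrm{pop}}(r)\,\frac{G-m}{G-1},$$

with the finite-population correction. Three evaluation modes share
these moments:

* **analytic** (default): $z = (c-\mu)/\sigma$, $p = \Phi(z)$. Adequate
  in the CLT regime ($G \gtrsim 100$, the scale of real libraries).
* **monte_carlo**: seeded random gene sets;
  $p = (1 + \#\{C \le c\})/(1 + n_{\mathrm{draws}})$, never zero.
* **exact**: full enumeration of the $\binom{G}{m}$ gene sets, feasible
  up to $10^5$ sets; used as the oracle in the test suite. The reported
  tail fraction is floored at one over the number of sets so $p > 0$
  also holds for signed signatures whose score is below every
  enumerated all-positive set.

Replicates of one drug are combined by summing: $c_\mathrm{total} =
\sum_i c_i$ with $\mu_\mathrm{total} = \sum_i \mu_i$ and
$\sigma^2_\mathrm{total} = \sum_i \sigma^2_i$ (independence). For $n$
concordant replicates this reproduces the $\sqrt{n}$ gain of averaging.
Whether real reference systems sum or average replicate scores is not
observable from published outputs; the rule is isolated in
`score_drug()` and pinned by unit tests. In Monte-Carlo and exact mode
the null draws one gene set shared by all replicates, evaluated on the
per-gene sums of the replicate ranks; its variance differs from the
summed analytic moments only by the empirical cross-replicate
covariance, which is $O(G^{-1/2})$ for null drugs.

## Significance, stability, ranking

With $N$ drugs screened, `significance_threshold(N)` returns exactly
$1/N$ — for $N = 1432$ that is $0.000698$, printed to one significant
figure as .0007 — so the *expected number of falsely significant drugs is
one* regardless of $N$. With $n_\mathrm{sig}$ drugs passing, the expected
false-discovery rate is $1/n_\mathrm{sig}$ (`expected_false_discovery()`);
95 significant drugs give about 1%.

`perturbation_stability()` deletes each signature gene in turn, re-scores
the drug under each of the $m$ leave-one-out signatures, and reports the
fraction still significant. Stability 1 marks connections not driven by
any single gene; "passing the perturbation test" means stability = 1.
`rank_drugs()` orders by ascending p, then descending stability, then
ascending z (most negative first), with the drug id as a final
deterministic tie-break — the order used in the results table and plot.
The significance plot draws drugs against $-\log_{10} p$ with the
threshold line at $-\log_{10}(1/N)$ ($3.16$ for $N = 1432$), green for
significant fully-stable drugs, red for significant unstable ones.

# The synthetic-data generator

`simulate_cohort()` emulates the statistical skeleton the analysis
relies on: a standard-normal driver; a block of `block_size` genes
(default 15) with correlation `block_coupling` to the driver
($x = \rho\,d + \sqrt{1-\rho^2}\,\varepsilon$); one anti-correlated gene
(the E-cadherin analogue); independent noise genes; everything shifted
by +8.0 to sit on a log2-intensity-like scale. Survival is exponential
proportional hazards, $h = h_0 e^{\beta d}$, the simplest model
consistent with "high driver expression shortens survival" and the one
with closed-form restricted means for sanity checks. Defaults
($\beta = 0.7$, $h_0 = 0.01$/month, 20% censoring, cohorts of a few
hundred samples) give the clear but not degenerate group separation seen
in real prognostic cohorts.

Censoring thins each sample independently with probability
`censor_rate`, observing it at a uniform fraction of its own event time.
Note this mechanism is *dependent* censoring (the censoring time is a
fraction of the event time), which the product-limit estimator does not
assume; at the default 20% rate the induced RMST bias is small but
visible (~+8% in simulation). The CI-coverage checks in the test suite
therefore use independent exponential censoring, the estimator's
assumption; the generator keeps the thinning mechanism because it is
simple, seed-deterministic, and irrelevant for rank- and sign-based
checks.

`simulate_reference_library()` draws i.i.d. normal per-gene differential
statistics per replicate and converts them to signed ranks; planted
reversers have the signature genes' statistics shifted by
$-\text{strength} \times s_j$ before ranking. At strength 3 and
$G = 1000$ a planted reverser's signature genes land near rank magnitude
$-G$, giving $z \approx -7$ per replicate — comfortably past the 1/1432
threshold, which is why recovery of planted reversers with stability 1
is a sharp, reproducible property. The generator does not attempt
platform noise models, batch effects, or L1000-style landmark
imputation: passing tests show the statistical machinery is correct, not
that any particular biological library would reproduce a given drug
list.

# Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` use: 200 null libraries of 50
drugs over 400 genes for the type-I check (mean significant count ≈ 1);
a 120-drug library over 1000 genes with five planted reversers at
strength 3 for recovery; two cohorts of 220–226 samples, 300–400 genes,
coupling 0.6–0.75 for block recovery; 600 cohorts of 80 samples for RMST
coverage; exhaustive enumeration oracles at $G \le 8$. These sizes make
every property sharp (3-standard-error bands) while each run stays in
seconds.

Other numerical choices: probe collapsing keeps the probe with the
highest mean expression (max-mean rule; ties to the lexicographically
smaller probe id) — how real platforms summarize multi-probe genes is
platform-specific, so the rule is documented and swappable; cohort
samples are restricted to the intersection of expression and clinical
files (patients without clinical annotation cannot enter survival
analysis); Greenwood terms where the whole risk set dies are set to
zero; Monte-Carlo p-values use the $(1+k)/(1+n)$ estimator so they are
never zero; all generators and Monte-Carlo draws take one integer seed
from which all randomness flows, so identical configs reproduce outputs
byte-for-byte.

# Known limitations

* The real endpoint definitions (disease-specific vs overall survival)
  and probe summarizations of public cohorts vary; this package models a
  single generic endpoint and a documented collapsing rule.
* The analytic null is a normal approximation; at small $G$ or extreme
  tails use `null_method = "monte_carlo"` or `"exact"`.
* Published drug-level z-scores from proprietary-scale reference
  libraries are not reproducible here; what the package reproduces is
  the scoring framework, its calibration, and its behaviour on libraries
  with known ground truth.
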