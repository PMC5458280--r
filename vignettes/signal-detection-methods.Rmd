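---
title: "Methods: disproportionality signal detection, pooled across report years"
author: "pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection, pooled across report years}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event reporting systems (FAERS and its openFDA
interface being the canonical example) collect case reports, each indexed
by the patient's indication, the drugs used, and the observed reactions
coded as MedDRA-style preferred terms. Within an indication cohort — here
the motivating case is non-small cell lung cancer — one asks whether
reports mentioning a study drug (carboplatin) report a hematologic event
(anaemia, neutropenia, thrombocytopenia) disproportionately often compared
with reports of all other therapies. `pvsignal` implements that analysis
end to end, plus a gene-set over-representation stage for interpreting a
drug's interacting genes, and a synthetic report generator so that every
stage can be validated offline with known ground truth.

## The disproportionality model

For each receipt year $i$ the cohort is cross-classified into a 2x2 table:
$a_i$ exposed-with-event, $b_i$ exposed-without, $c_i$ unexposed-with,
$d_i$ unexposed-without. The reporting odds ratio and its Woolf
(log-scale) variance are

$$\mathrm{ROR}_i = \frac{a_i d_i}{b_i c_i}, \qquad
  v_i = \frac1{a_i}+\frac1{b_i}+\frac1{c_i}+\frac1{d_i},$$

with the Wald interval $\exp(y_i \pm z_{1-\alpha/2}\sqrt{v_i})$ on
$y_i = \log \mathrm{ROR}_i$. A lower 95% bound strictly above 1.00 flags a
signal. If any cell is zero the Haldane–Anscombe correction adds 0.5 to
all four cells of that stratum; a stratum whose raw table has an empty
exposure or control arm is excluded from pooling entirely (its corrected
estimate would be pure artifact), with a logged warning.

## Pooling across years

Heterogeneity between years is assessed with Cochran's
$Q = \sum_i w_i (y_i - \hat y)^2$, $w_i = 1/v_i$, referred to
$\chi^2_{k-1}$, summarised as $I^2 = 100\,(Q - df)/Q$ (floored at zero)
and as the DerSimonian–Laird moment estimate
$\hat\tau^2 = \max\{0, (Q - df)/(\sum w - \sum w^2/\sum w)\}$.

When the Q-test p-value falls below 0.05 the pooled estimate uses the
random-effects DerSimonian–Laird weights $w_i^* = 1/(v_i + \hat\tau^2)$;
otherwise the fixed-effects Mantel–Haenszel estimator
$\widehat{OR}_{MH} = \sum_i (a_i d_i / T_i) \big/ \sum_i (b_i c_i / T_i)$
is used, with the Robins–Breslow–Greenland variance for its logarithm
(which reduces exactly to the Woolf variance for a single stratum — a
property the tests exploit). Knapp–Hartung or REML variants are
deliberately not offered: the method core mirrors the named classical
estimators, and offering variants would change the stated analysis.
Leave-one-out sensitivity re-pools each $k-1$ subset under the *same*
model family as the full analysis; the model is a perturbation target, not
re-selected per subset.

Reporting bias is assessed by the classic Egger regression: the
standardized effect $y_i/\mathrm{se}_i$ is regressed on precision
$1/\mathrm{se}_i$ by unweighted OLS and the intercept is tested on $k-2$
df. Funnel coordinates (effect vs. standard error, vertical axis drawn
increasing downward) are emitted as data; no plotting layer is imposed.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `years` | 2004:2015 | calendar years | the study window; also the stratification key |
| `level` | 0.95 | — | Wald CI level, $z = 1.959964$ |
| `het_alpha` | 0.05 | — | Q-test threshold driving model selection |
| enrichment `alpha` | 0.01 | — | selection threshold on BH-adjusted p |
| `p_exposure` | 0.2 | probability | generator: matches the ~3907/19901 exposed fraction of the motivating cohort |
| `p_event_unexposed` | 0.05 | probability | generator: baseline reporting rate of one hematologic PT among cohort reports; not stated by the source study, chosen once as realistic |
| `true_log_or` | log(2.27) | log odds ratio | generator: the motivating pooled anemia ROR |
| `tau` | 0.2 | sd of log OR | generator: moderate between-year heterogeneity, consistent with the I² range (51–75%) the motivating study reports |

## What the generator emulates — and what it does not

`simulate_reports()` draws, per year, a true log ROR
$\theta_i \sim N(\mu, \tau^2)$; each report is independently exposed with
`p_exposure`, and the exposed event probability is defined on the odds
scale, $\mathrm{odds}_1 = e^{\theta_i}\,\mathrm{odds}_0$, so that $\mu$ is
*exactly* the log ROR of the generating process and parameter recovery is
a sharp test. Reports carry the study indication, decoy co-medications
from a fixed vocabulary, and decoy reactions; a `duplicate_rate` flag
re-emits reports under their original id to exercise deduplication. All
randomness flows through one seed, and the caller's RNG state is restored.

It does **not** emulate: multi-manufacturer duplicate clusters, stacked
polypharmacy correlations, indication misclassification, secular coding
drift, or dose information. A green parameter-recovery test therefore
establishes that the *estimators* are correct under the stated sampling
model — not that real FAERS extracts are free of the confounding the
source literature itself cautions about.

## Numerical and design choices

- **Exact matching** of normalized index terms (uppercase, collapsed
  whitespace), never substring matching, which would silently inflate
  counts (`"ANAEMIA"` occurs inside `"HAEMOLYTIC ANAEMIA"`).
- **Deduplication keeps the last occurrence** of a report id, following
  the superseding-case-version convention of FAERS; reports with an
  unparseable receipt year are dropped and counted, never imputed, because
  year is the stratification key.
- **Tie-breaks and boundaries are strict**: model selection switches to
  random effects only for p *strictly* below `het_alpha`; the signal flag
  requires the lower bound *strictly* above 1; enrichment selection
  requires adjusted p *strictly* below `alpha`.
- The hypergeometric upper tail is computed by `stats::phyper`, which
  accumulates in log space and remains accurate for tails near 1e-50;
  tests verify it against exhaustive enumeration over every configuration
  with a universe of at most 30 genes.
- **Reference-size recovery** inverts printed two-decimal enrichment
  ratios: since ratio $= kN/(nK)$, each printed row confines the unknown
  universe size $N$ to an integer interval. The implementation checks the
  half-away-from-zero rounding in pure integer arithmetic
  ($\lfloor (200kN + nK)/(2nK) \rfloor$), immune to floating-point
  boundary error. For the bundled carboplatin pathway table the four
  largest cancer rows pin $N$ uniquely, and that single $N$ reproduces all
  fourteen printed ratios — the package's strongest exactness check.
- The BH family size equals the number of categories supplied. When
  re-analysing a published table that is only "a portion" of the pathways
  actually tested, equality with printed adjusted p-values cannot be
  asserted — only the bound raw $p \le$ adjusted $p$ (step-up adjustment
  never decreases a p-value), and that is what the acceptance checks use.
- BH re-adjustment is *not* idempotent on arbitrary lists (re-adjusting
  multiplies by $m/\mathrm{rank}$ again); it is a fixed point on tied-block
  outputs, and the tests assert exactly that.

## Known limitations

- **Egger's test is anticonservative on sparse, equal-sized strata.**
  With yearly tables, the estimated Woolf standard error is mechanically
  correlated with the estimate; when all years have similar volumes and
  few events, the precision axis is driven by that noise and the false
  asymmetry rate can be very large (we observed ~94% at 12x800 reports
  with a 5% baseline event rate). The null-behaviour test therefore states
  a world with growing yearly volumes and denser events, where the
  normal-theory behaviour holds. Interpret Egger flags on sparse real
  extracts with caution.
- DerSimonian–Laird interval coverage is known to dip slightly below
  nominal for small $k$ with moderate heterogeneity; the recovery test's
  ≥90% coverage criterion reflects that.
- The pipeline computes only stratified-then-pooled estimates; a crude
  (year-collapsed) table is written to the run log for diagnostics but is
  never reported as a result.
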