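---
title: "Ranking hospital departments by cross-infection risk: the hybrid DEMATEL-WSM model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking hospital departments by cross-infection risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dematelwsm)
```

## The decision problem

Nosocomial infections spread between the departments of a healthcare
facility, and the facility's department configuration is one of the levers
management controls. The question this package answers is: *given structured
expert judgment, which departments should be proposed for elimination or for
reinforced hygiene policies?* Two kinds of evidence enter the decision:
pairwise judgments of how strongly each department transmits infection to
each other department, and managerial criteria (demand, profitability,
staffing, building standards, ...) scored per department. The pipeline fuses
them in four steps: panel aggregation, DEMATEL, risk mapping, and a
weighted-sum ranking.

## Model and assumptions

### Rank-weighted panel aggregation

Experts are organised in two clusters — infection-control and managerial —
and each expert carries an integer rank $r_k \ge 1$ ("unbalanced
expertise"). Every judgment is aggregated cell-wise as
$$Z_{ij} = \frac{\sum_k r_k X^k_{ij}}{\sum_k r_k},$$
a rank-weighted arithmetic mean. The divisor $\sum_k r_k$ is a design
choice: it keeps aggregates on the original elicitation scales (0–4 for
influence ratings, 0–100 for criterion values), which matters because the
risk row is later compared against 0–100 managerial scores. DEMATEL itself
is invariant to this choice — any common rescaling of $Z$ cancels in the
normalisation — so only the weighted-sum side is affected. The two clusters
are aggregated independently; their ranks are never compared across
clusters. Consensus entries need not be integers.

The assumed judgment model is simple: experts are exchangeable up to their
rank weight, and ranks act multiplicatively on judgments. No
outlier-handling or consensus-convergence step is modelled; the aggregation
is a single weighted mean.

### DEMATEL

With $S = \max_i \sum_j Z_{ij}$ (the largest row sum), the normalised
direct-relation matrix is $D = Z/S$; every entry of $D$ lies in $[0, 1]$
and its largest row sum is exactly 1. A variant normalisation
$S = \max(\max_i \sum_j Z_{ij},\ \max_j \sum_i Z_{ij})$ is available
(`variant = "max_row_col"`) but off by default, as the row-sum rule is the
one the pipeline's own elicitation uses.

Total influence — direct plus every indirect path — is the geometric series
$D + D^2 + \dots$, which converges iff the spectral radius $\rho(D) < 1$,
giving the closed form
$$T = D (I - D)^{-1}.$$
`total_relation()` checks $\rho(D)$ via `eigen()` and refuses
non-convergent inputs with an explicit message; the inverse is never formed
explicitly, the system $(I - D)^\top T^\top = D^\top$ is solved densely
instead for conditioning. An independent evaluation path,
`total_relation_series()`, sums the series by repeated multiplication and
is used in the tests to confirm the solve to below $10^{-9}$ in the
max norm.

Row sums $R_i$ of $T$ measure influence dispatched, column sums $C_i$
influence received. The *prominence* $R + C$ and *relation* $R - C$ follow;
$\sum_i (R_i - C_i) = 0$ holds identically and is asserted to $10^{-9}$.
Departments with $R - C > 0$ form the cause group, $R - C < 0$ the effect
group. A relation within $10^{-9}$ of zero is classified *neutral*: group
membership is defined only for strictly signed relations, and a symmetric
$T$ would otherwise be assigned arbitrarily. The argmax and argmin of
$R - C$ are flagged master dispatcher and master receiver; exact ties go to
the first department in canonical order and are recorded in a `tie_note`
attribute rather than silently.

### From relations to an infection-risk criterion

The case study this package packages as fixtures derived a 0–100 infection
risk row from the DEMATEL chart by expert curation, without stating a
formula; the printed row is not even monotone in $|R - C|$. The package
therefore ships three mappings and treats the choice as an explicit
parameter of `dematel_to_risk_scores()`:

* `abs_minmax` (default): $100 \cdot (|R-C| - \min)/(\max - \min)$. The
  magnitude is used because both strong causes *and* strong receivers are
  risky — the case study flags ICU2 (strongest cause) and jaw-and-face
  surgery (strongest receiver) alike. If all magnitudes coincide the spread
  is degenerate and every department scores 50, with a warning.
* `rank_based`: ranks of $|R-C|$ evenly spaced on $[0, 100]$ — robust when
  magnitudes are heavily skewed.
* `manual`: a curated row passed through verbatim (this is how the fixture's
  printed row enters the weighted-sum stage).

### Modified weighted-sum model

Raw criterion weights live on 0–100; `inject_risk_criterion()` appends the
risk row with its own raw weight (default 100, the maximum — the case
study's choice, expressing that infection risk dominates any single
managerial criterion) and renormalises jointly:
$W'_x = W_x / \sum_x W_x$. Scores are
$\mathrm{WS}(A_x) = \sum_y W'_y V_{yx}$; with normalised weights and values
in $[0, 100]$, totals stay in $[0, 100]$. All criteria point the same
direction — a value near 100 argues for elimination — so no benefit/cost
flipping exists in the engine; mixed-direction criteria are out of scope.
Ranking uses a stable descending sort, so tied departments keep canonical
order. The shortlist length `top_k` defaults to 4, matching the case
study's reported choice, but is an ordinary parameter with no claim that 4
is intrinsic to the method.

## Tunable parameters at a glance

| parameter | where | default | meaning |
|---|---|---|---|
| `rank` | `expert_panel()` | — | integer expertise weight, multiplies judgments |
| `variant` | `normalize_direct_relation()` | `"max_row"` | DEMATEL scale constant rule |
| `tol` | `classify_cause_effect()` | `1e-9` | zero-relation band for neutral class |
| `mode` | `dematel_to_risk_scores()` | `"abs_minmax"` | relation-to-risk mapping |
| `risk_weight` | `inject_risk_criterion()` | 100 | raw weight of the risk criterion (0–100 scale) |
| `top_k` | `run_pipeline()` | 4 | shortlist length |

## The synthetic generator

`generate_case()` emulates the structure of the case study: 20 departments,
7 + 7 experts, ranks drawn from {1, 2, 3} with probabilities (3, 5, 6)/14 —
the pooled rank frequencies of the study's 14-expert panel — and 12
managerial criteria. Influence ratings are categorical on {0,…,4} with a
configurable probability of zero (`influence_sparsity`, default 0.3,
reflecting that many department pairs have no direct infection pathway);
weights and values are uniform on [0, 100]. These are scale-faithful but
distribution-agnostic choices: the sources specify only the scales, not the
distributions.

What the generator deliberately does **not** emulate: correlated judgments
among experts of the same cluster, systematic rating styles (leniency,
central tendency), epidemiologically structured transmission (e.g. ICU-like
hubs arise only via `generate_planted_structure()`), and non-uniform
criterion values. Passing tests on synthetic data therefore demonstrate
algorithmic correctness — aggregation arithmetic, series convergence,
conservation, classification, ranking — not robustness of the elicitation
itself on real panels.

`generate_planted_structure()` builds ground-truth cases: planted
dispatchers rate high outgoing and receive zero incoming influence,
receivers the reverse, and at zero background noise recovery of the master
roles is provably exact (the planted row dominates $R$ while its column is
empty). The test suite requires 100% recovery across 50 seeds.

## Numerical choices and degenerate inputs

* All-zero consensus matrices (possible at `influence_sparsity = 1`) make
  $S = 0$; normalisation stops with an explicit error rather than dividing.
* $\rho(D) \ge 1$ (in practice only for contrived inputs such as symmetric
  permutation-like matrices whose rows all sum to the maximum) is refused
  with a message naming the convergence condition.
* Comparisons with zero use absolute tolerance $10^{-9}$ throughout.
* Weighted-sum reports round to 2 decimals; full precision is kept
  internally.
* An all-zero managerial weight vector is allowed to exist transiently
  (before risk injection); scoring it is an error.

## Fixtures and their caveats

The two packaged fixtures transcribe the case-study tables *exactly as
printed*, preserving their mixed precision (most total-relation columns
carry 2 decimals, four carry 4) and a criterion weight whose printed
normalised value is implausibly large (the weights column sums to ≈1.368;
shifting that one weight's decimal point restores ≈1.000). Nothing is
corrected, and the loader's `notes` field documents both. Consequences for
verification: the four 4-decimal columns reproduce the printed $R - C$
exactly at 3 decimals, and the printed weighted cells reproduce the printed
totals within ±0.01 for most departments — but not all; one column's
printed cells are internally inconsistent with its printed total by ≈0.4,
which the test suite reports rather than hides. The raw expert matrices
behind the tables were never published, so the upstream half of the
pipeline (aggregation, normalisation, inversion) is validated by its
property suite, not by end-to-end reproduction.

## Problem sizes used in the checks

The property suite runs the inverse-versus-series comparison on 100 random
systems of dimension 3–20 (200 series terms, agreement below $10^{-9}$),
conservation on the same systems, scale invariance at factors
{0.1, 3, 17}, and planted-structure recovery on 50 seeded 10-department,
2-expert panels. These sizes give sub-minute runtimes while covering the
dimension range the method is used at; the case-study computations are on
the full 20 × 20 fixtures.

## Known limitations

* The relation-to-risk mapping is a modelling choice; the default is
  defensible but not canonical, and analysts replicating a curated risk row
  should use `manual` mode.
* Benefit-type criteria (where high values argue *against* elimination)
  are not supported; all criteria must be oriented as elimination pressure
  before entry.
* DEMATEL digraph visualisation (threshold-pruned impact-relation maps) and
  fuzzy-scale variants are out of scope; plotting is limited to the
  $R - C$ and WS bar charts.
* Group sizes beyond a few dozen experts pose no computational issue, but
  the rank-weighting scheme itself assumes small panels with
  manager-assigned ranks.
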