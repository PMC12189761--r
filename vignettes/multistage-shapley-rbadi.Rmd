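---
title: "Multi-stage Shapley attribution and the Regional Brain Aging Disparity Index: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stage Shapley attribution and the RBADI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbadi)
```

# Overview

`rbadi` explains a brain-age prediction as a vector of per-region Shapley
attributions computed exactly within a hierarchical partition of the
feature space, and standardizes those attributions against an age-matched
healthy reference to yield the Regional Brain Aging Disparity Index
(RBADI). This vignette records the model, the design decisions behind the
implementation, the synthetic data generator used for validation, and the
known limitations.

# The attribution model

## Coalitions and the value function

Let the atlas have $L$ leaves (regions). A coalition $S$ of leaves is
evaluated by predicting on a hybrid payload: leaves in $S$ carry the
subject's observed features, leaves outside $S$ are replaced by a
*reference* payload. The value of the coalition is the model's predicted
age on that hybrid, $v(S) = f(x_S, r_{\bar S})$.

Two masking references are supported:

- **cohort mean** (default): each masked leaf takes the mean feature value
  over a cohort, via `cohort_reference()`. Masking toward the data
  manifold keeps hybrid payloads in the regime the model was trained on.
- **zeros**: each masked leaf is set to 0 (`reference_payload(...,
  provenance = "zero")`). Simple and cohort-free, but hybrid payloads can
  be far off-manifold for models sensitive to global intensity.

Either way, the reference's provenance is recorded in the result manifest
so downstream curves refuse to mix attributions computed under different
schemes (the partition-tree hash is checked likewise).

## The staged game

Exact Shapley values over $L = 116$ leaves need $2^{116} \approx 8.3
\times 10^{34}$ evaluations. Instead, leaves are organized in a tree:
8 anatomical sets (temporal, frontal, prefrontal, parietal, occipital,
subcortical, cerebellar hemispheres, cerebellar vermis) at level 1, split
into hemisphere subsets at level 2, with the atlas leaves below. An exact
game is solved at every internal node among its children:

- **Stage 1** — the 8 sets play a game where the empty coalition is
  assigned the cohort baseline $E_0$ (the mean chronological age of the
  reference cohort) *without a model call*, and the full coalition is the
  actual prediction $v(\mathrm{full})$. Shapley values
  $\phi(\mathrm{set})$ satisfy efficiency:
  $\sum_{\text{sets}} \phi = v(\mathrm{full}) - E_0$.
- **Stage $s > 1$** — for a node $p$ with $m$ children, the children play
  a game whose empty coalition takes the **adjusted baseline**
  $v(\mathrm{full}) - \phi(p)$, again without a model call. Crucially, all
  leaves *outside* $p$'s subtree are held at the **subject's** values in
  every coalition payload of this game. Under this construction the full
  coalition of $p$'s game evaluates to exactly $v(\mathrm{full})$, so the
  game's total worth is $\phi(p)$, and Shapley efficiency *within the
  game* becomes the hierarchical-consistency identity
  $\sum_{c \in \mathrm{children}(p)} \phi(c) = \phi(p)$ — an exact
  identity, not an approximation. Holding out-of-subtree leaves at the
  reference instead would break this identity whenever the predictor is
  non-additive; that alternative reading was therefore rejected.
- Nodes with a single child (e.g. the vermis at the hemisphere level,
  which has no left/right split) are pass-throughs: the child inherits
  $\phi$ at zero cost.

Within a game of $m$ players the combinatorial weight
$|S|!\,(m-|S|-1)!/m!$ is computed as $1/(m \binom{m-1}{|S|})$, which is
exact in double precision for $m \le 20$ (all binomials are below
$2^{53}$); a `max_game_size = 20` guard refuses larger games rather than
silently losing precision. Subsets are enumerated by bitmask.

## Operation counts and caching

For the default partition the per-subject cost under the staged
convention is $2^8 = 256$ (stage 1), $7 \times 2^2 = 28$ (stage 2,
7 two-player hemisphere games), and
$2(2^{10}+2^{4}+2^{12}+2^{8}+2^{6}+2^{5}+2^{9}) + 2^8 = 12{,}256$
(stage 3), totalling 12,540 versus $2^{116}$ naively — a reduction of
$\lfloor \log_{10}(2^{116}/12{,}540) \rfloor = 30$ orders of magnitude.
`count_operations(tree, "paper")` reproduces this arithmetic for any
tree; $2^{116}$ itself is rendered exactly with a small decimal
big-integer routine and reductions are computed in log space, since both
overflow naive integer arithmetic.

The implementation additionally recognizes that every game's full-member
coalition activates all atlas leaves (out-of-subtree leaves are at subject
values), so it coincides with the one shared full-payload prediction.
The *distinct* model-call count is therefore $\sum_g (2^{m_g} - 2) + 1$
(12,495 for the default tree), available as
`count_operations(tree, "cached")`. A memoizing cache keyed on the active
leaf set plus an evaluation accountant make this auditable at run time;
the test suite asserts the accountant matches the analytic count on every
tree shape it exercises, for both the scalar and the batched predictor
path.

## Exactness and approximation error

If the predictor decomposes additively across the level-1 sets (including
arbitrary non-linearities *within* a set), the staged attributions equal
the flat exact Shapley values over all $L$ leaves; the test suite verifies
this to $10^{-8}$ years against an independently written flat brute-force
implementation and a permutation-enumeration oracle. When interactions
*cross* set boundaries, staged and flat values differ. The deviation is
not confined to the interacting leaves: the adjusted baseline distributes
each game's discrepancy across that game's members, so all leaves of the
two interacting level-1 sets can shift, while leaves of untouched sets
still match the flat game exactly. The efficiency and consistency
identities continue to hold exactly in either case — the approximation
redistributes credit, it never leaks it.

## Baseline coherence and the null-player axiom

The construction admits any declared baseline $E_0$, but the null-player
axiom (a leaf the model ignores gets $\phi = 0$) holds exactly only when
$E_0 = v(\text{reference})$, i.e. the declared baseline equals the model's
prediction on the fully masked payload. Otherwise the gap
$v(\text{reference}) - E_0$ enters on the empty-to-singleton transitions
and spreads $1/L$ per leaf — including ignored leaves. For the same
reason, the textbook closed form for a linear model
$\phi_j = w_j (x_j - r_j)$ acquires a correction term:

$$\phi_j = w_j\,(x_j - r_j) + \frac{v(r) - E_0}{L},$$

which is what `linear_shapley_oracle()` implements (verified against both
brute-force and permutation enumeration). With cohort-mean masking and
$E_0$ set to the cohort's mean age the two coincide up to the surrogate's
calibration error. This is an inherent property of declaring an external
baseline, not an implementation artifact, and is worth keeping in mind
when interpreting near-zero attributions.

# The RBADI

Raw Shapley attributions confound regional abnormality with normal aging:
an old subject has large positive $\phi$ everywhere. The RBADI removes
the normal-aging component by standardizing against healthy peers of the
same age.

Given attributions for a strictly healthy cohort, `build_reference()`
constructs the age-standard curve on the integer grid spanned by the
cohort's rounded ages:

$$\phi_{\mathrm{std}}(l, a) = \frac{1}{|N_a|} \sum_{i \in N_a}
  \phi_i(l), \qquad
  N_a = \{\, i : a - w \le \mathrm{round}(\mathrm{age}_i) \le a + w \,\}$$

— a **pooled** mean over all subjects in the window (each subject weighted
equally), not a mean of per-age means; with unbalanced age sampling the
two differ, and the pooled form is the one under which a window-0 curve
exactly mean-centers its own building cohort (a property the tests pin to
$10^{-12}$). If $|N_a|$ falls below `min_n` (default 10) the window widens
symmetrically until the count is met, and the widened half-width is
recorded per age in `window_used`. Ages are rounded half away from zero
(`round_half_away()`), avoiding banker's-rounding surprises at `.5`. A
subject outside the curve's age range is evaluated at the nearest grid
age and flagged `clamped` rather than extrapolated.

The subject's index is then simply

$$\mathrm{RBADI}_l = \phi_l - \phi_{\mathrm{std}}(l,
  \mathrm{round}(\mathrm{age})),$$

in years: the attribution surplus of region $l$ relative to age-matched
healthy peers. When the index subject belongs to the reference cohort,
their own attribution is included in the curve (no leave-one-out); with
the default `min_n = 10` the self-contribution is at most $1/10$ of the
window mean and shrinks with cohort size.

# The synthetic cohort generator

All validation runs on simulated data with known ground truth; the
defaults are fixed study conditions, not tuning knobs.

- **Ages** uniform on $[45, 82]$, matching a typical adult structural
  cohort.
- **Features**: leaf $l$ of subject $i$ is
  $x_{il} = 0.8 - 0.01\,(\mathrm{age}_i - 63.5) +
  \varepsilon_{il},\; \varepsilon_{il} \sim \mathcal N(0, 0.11^2)$ — a
  gray-matter-density-like scale with uniform atrophy of 0.01 units/year
  around the age-range midpoint 63.5.
- **Linear surrogate**: weights $w_l = 1/(L\,\beta_l)$ with intercept
  chosen so the noise-free prediction recovers chronological age exactly;
  $E_0 = 63.5$. With `noise_sd = 0.11` the surrogate's mean absolute
  error lands in the 2–3-year regime typical of published brain-age
  models on healthy test data, so identity and recovery tests run under
  realistic signal-to-noise.
- **Non-additive surrogates** for approximation-error studies:
  `within_set_nonlinear` (a quadratic term confined to one level-1 set —
  staged must still equal flat) and `cross_set_interaction` (a product of
  two leaves in different level-1 sets — staged must deviate from flat in
  a characterized way).
- **Effect injection**: `inject_effect()` shifts target leaves in a
  labelled subgroup either in feature units or in attribution units
  (`mode = "phi"` divides the shift by the surrogate's weights, giving
  direct control of the induced $\phi$ displacement in years).
- **Toy tree**: 3 sets × 2 hemispheres × 2 leaves = 12 leaves — the
  smallest shape exercising all three stages while keeping the flat
  $2^{12}$ brute force affordable as an oracle.

Random draws are made under `with_seed()`, which saves and restores the
global RNG state, so library calls never perturb a caller's stream.

The end-to-end recovery experiment — inject a $+0.5$-year attribution
shift at one region in half of a 400-subject cohort, build the reference
curve from the healthy half only, and check that the injected region has
the largest positive group-mean RBADI — succeeds in $\ge 95\%$ of 40
independent replicates in the acceptance suite.

# Problem sizes and runtime

On a single CPU: a 12-leaf toy-tree multistage run takes a few
milliseconds (a 400-subject cohort ≈ 2.3 s); the full 116-leaf default
tree ≈ 1.6 s per subject (12,495 distinct evaluations through the batched
predictor path); the flat $2^{12}$ brute force ≈ 25 ms. The unit suite
runs in under 5 s, the acceptance suite in under 2 minutes.

# Design decisions

- **Base-R/S3 throughout**; `jsonlite`/`yaml` for interchange formats,
  `tools::md5sum` for canonical tree hashing. The Shapley machinery,
  partition algebra, and RBADI are original — no available package
  implements hierarchical staged Shapley, so the independent oracles are
  the separately written flat brute force and permutation enumeration.
- **The region→set mapping is data, not code.** The default AAL-116
  assignment ships as editable TSV/YAML resources under `inst/extdata`.
  Published sources state only the per-hemisphere counts
  (10/4/12/8/6/5/9 per set plus 8 vermis regions); the exact region list
  per set (e.g. insula under subcortical, anterior cingulate under
  prefrontal) is a documented assumption, and construction-time
  validation enforces only the count multiset, disjointness, and full
  coverage.
- **Tolerances**: identities are checked at $10^{-6}$ years; results
  breaching $10\times$ the tolerance carry a warning flag in their
  diagnostics rather than erroring, since a violation signals a
  misconfigured predictor the user should inspect.
- **Numerics**: Shapley weights via binomials (exact for $m \le 20$);
  $2^{116}$ via decimal doubling; reductions in log space; file
  round-trips use 17-significant-digit formatting for bit-exact
  read/write of doubles.

# Limitations

- With predictors whose interactions cross level-1 set boundaries, staged
  attributions approximate flat Shapley values; the error is bounded in
  practice but not theoretically characterized here beyond the
  untouched-set exactness result above.
- The null-player axiom requires the coherent baseline
  $E_0 = v(\text{reference})$; with an externally declared $E_0$ every
  leaf absorbs $(v(r) - E_0)/L$.
- Cohort-mean masking produces hybrid payloads that no real brain
  exhibits; models very sensitive to inter-regional covariance may
  behave unexpectedly on them.
- The reference curve assumes the healthy cohort densely samples the age
  range; window widening handles thin ages but cannot manufacture
  information at unobserved extremes (clamping is flagged, never
  extrapolated).
- Reference curves include the index subject when they overlap the
  building cohort (no leave-one-out option yet).
- Games are capped at 20 players; partitions with wider nodes must be
  refined before use.
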