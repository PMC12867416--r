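---
title: "Guild dynamics in case/control microbiome cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guild dynamics in case/control microbiome cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guildnet)
```

## The problem this package addresses

Case/control microbiome studies usually compare taxa one at a time. guildnet
instead asks how *groups* of co-occurring organisms — guilds — reorganize
between a healthy and a diseased state, whether a stable core guild persists
across both, and whether transitional ("grey zone") samples sit between the
two ecologies. The pipeline is: compositional preprocessing, per-condition
co-occurrence networks, a cross-condition stable network, guild discovery,
permutation null models and robustness analysis on sub-networks,
classifier-based sample stratification, and a cross-cohort epidemiological
summary of guild abundance.

## Preprocessing model and assumptions

Counts from amplicon sequencing are compositional: only relative information
is meaningful, and sequencing depth varies by orders of magnitude. The
defaults state one world:

* **Depth filter** (`filter_samples_by_depth`, 10,000 reads): samples
  *strictly below* the threshold are dropped; a sample at exactly 10,000 is
  kept. Below roughly this depth, prevalence estimates for rare OTUs become
  unreliable.
* **OTU filter** (`filter_otus`): an OTU is removed iff prevalence < 10%
  *or* mean relative abundance < 5e-5. Both comparisons are exclusive, and
  prevalence counts strictly positive entries. The filter is idempotent.
* **CLR transform** (`clr_transform`): `log(x + 0.5)` centered per sample.
  The half-count pseudocount is the standard correction that keeps zeros
  finite without dominating the transform; the row-centering makes the
  result scale-invariant (closure). Rank correlations downstream inherit
  robustness to the pseudocount choice.
* **Rarefaction** (`rarefy_table`) is available but **off by default**: the
  upstream practice of "rarefy then normalize" is ambiguous about ordering,
  rarefaction discards data, and CLR followed by rank correlation does not
  require equal depths. Users who want the rarefied route can run it
  explicitly before `clr_transform`.

## Co-occurrence networks

Edges are Spearman rank correlations between CLR-transformed OTUs, with
p-values from the t approximation on `n - 2` degrees of freedom and
average-rank ties. An edge requires BH-adjusted `q < 0.05` (strict) **and**
`|rho| >= 0.3` (inclusive), exactly as printed in the field convention the
package follows. Design choices worth knowing:

* BH runs **once across all pairs** of a network, not per node — no
  stratification is stated by the convention, and a single family keeps the
  FDR interpretable.
* A constant OTU has no defined rank correlation; such pairs are reported
  `NA` and can never become edges. They are never coerced to 0.
* `|rho| = 1` gives a degenerate p of 0; it is floored at machine epsilon so
  the BH step stays well-defined.
* Isolated nodes are dropped by default, so reported node counts mean
  "connected OTUs" (consistent with published node counts sitting well below
  post-filter OTU counts); `retain_isolates = TRUE` keeps them.
* Raising `rho_min` or lowering `fdr_alpha` can only remove edges
  (monotonicity), and results are invariant to sample order.

The stable network (`stable_network`) keeps an edge iff it is significant in
*both* condition networks with the *same sign*; magnitudes may differ. Sign
agreement is the default because an association that flips direction between
conditions is evidence of rewiring, not stability. The laxer both-significant
variant sits behind `require_sign = FALSE`.

## Guild discovery

`detect_guilds` maximizes modularity with the multilevel (Louvain) heuristic
on `|rho|` weights, seeded and with vertices inserted in lexicographic order
so results are reproducible. No algorithm is canonical for this task; Louvain
was chosen because it is standard, fast, resolution-parameterized and
seed-controllable. **The number of guilds is an outcome**, not a parameter —
a published count of seven guilds on real data is not a target the simulator
tries to hit. Guilds below `min_size = 3` members are merged into the
neighbor guild with the largest connecting weight (rather than dropped) so
that guild-abundance additivity holds exactly.

`modularity_q` implements Newman–Girvan `Q = sum_g [e_g/m - (d_g/2m)^2]`
directly (unweighted by default) and is tested against igraph's independent
implementation; `zipi` implements within-module degree z-scores (population
sd; `zi = 0` for degenerate modules) and participation coefficients
(`pi = 0` for isolated nodes). Guild abundance is the **sum** of member
relative abundances (a guild is more abundant if its members are, jointly);
the mean variant is available via `method = "mean"`.

`bridging_subgraph` isolates only cross-group edges between two node sets;
its default partition for modularity is the induced two-block split, because
the question it answers is whether two groups have fused into one module
(low Q) or remain separate communities (high Q).

## Null models and robustness

`subset_permutation_test` draws node subsets of the observed size uniformly
from the background network and computes metrics on induced subgraphs. This
is deliberately **not** an edge-rewiring null: the question is "is this
particular set of nodes unusual *within this network*", so the graph stays
fixed and the node set is randomized. The two-sided p-value uses +1
smoothing, `(1 + 2 min(#null >= obs, #null <= obs)) / (n_perm + 1)`, so it
is never zero; a zero null sd is flagged degenerate rather than producing an
infinite z. Degree centralities inside subgraphs are normalized by subgraph
size (`k - 1`) — the natural scale for comparing an induced subgraph with
equally sized random ones.

`robustness_curve` removes nodes in static descending initial-degree order
(id as tie-break) or in random order averaged over seeded shuffles, tracking
the largest connected component relative to its initial size. Static order
is the default because the stated procedure ranks "by degree centrality"
once; adaptive recomputation sits behind `adaptive = TRUE`. The AUC of the
curve summarizes vulnerability; on hub-dominated graphs targeted attack is
never gentler than random attack.

## Sample stratification and the grey zone

The classifier stage is standard machine learning, treated as a pluggable
component behind a fixed contract (fit on train, probabilities on test):
stratified 7:3 split, standardization on training statistics, SMOTE to a 1:1
ratio when imbalanced (`k = 5` neighbors; synthetic points are convex
combinations of minority neighbors), L1-penalized logistic feature selection
(inverse strength C = 0.1, translated to a lasso penalty `1/(nC)`), then a
cross-validated classifier. This environment provides no random-forest
implementation, so the default downstream model is ridge-penalized logistic
regression with CV-chosen penalty, and linear discriminant analysis serves
as the second model for cross-model grey-zone concordance. Nothing in the
package's claims depends on the specific classifier; only the probability
contract matters.

Zone rules follow the operational (Methods-style) definition: grey iff
`0.4 <= P <= 0.6` regardless of label; clear zones require label concordance
(`P >= 0.7` and clinically case; `P <= 0.3` and clinically control). The
gaps `(0.3, 0.4)` and `(0.6, 0.7)` and label-discordant extremes are
`unassigned` and excluded from three-group contrasts — the source convention
never classifies them, and silently folding them into a zone would blur the
contrast the grey zone is meant to sharpen. Published prose elsewhere uses
strict inequalities for the clear zones; `strict = TRUE` switches to that
reading, and the default follows the operational definition.

## Epidemiology

`dichotomize_by_median` sends ties at the median to "low", keeping "high"
strictly above the median — the conservative direction for enrichment
claims. `odds_ratio_2x2` applies the Haldane–Anscombe 0.5 correction only
when a zero cell exists, leaving exact tables untouched.
`fixed_effect_meta` is inverse-variance pooling with normal 95% CIs,
Cochran's Q and `I^2 = max(0, (Q - df)/Q) * 100`; identical replicated
cohorts give `I^2 = 0` exactly. Only the fixed-effect model is implemented —
random-effects pooling is an explicit non-goal. `adjusted_group_difference`
is ordinary least squares with named rejection of collinear covariates.

## What the simulator emulates — and what it does not

`generate_cohort` draws latent Gaussian vectors with block covariance
(blocks = guilds, within-block correlation per condition, background
correlation elsewhere), maps them through softmax to a composition, and
samples counts multinomially at negative-binomial depths (mean 30,000,
dispersion 10 — so the 10,000-read filter is occasionally exercised). The
logistic-normal construction was chosen over a Dirichlet because
co-occurrence methods operate on correlation, and only the latent-Gaussian
route lets correlation be planted per block. Grey samples are **mixtures of
the two condition means** (`lambda * mu_case + (1 - lambda) * mu_control`,
covariances mixed likewise), not a third latent class: the grey zone is
modeled as an ecological transition between the two states, and their
clinical labels are drawn `Bernoulli(lambda)` to emulate the clinically
mixed composition of that zone. Offspring tables couple to maternal samples
through a convex combination of the maternal CLR profile and an independent
control-state draw.

The planted odds ratio is defined at the pooled median split of the latent
guild abundance and computed by seeded Monte Carlo (`implied_odds_ratio`);
`calibrate_guild_shift` root-finds the latent mean shift for a target OR
using common random numbers. Calibration happens once, before any replicate
is generated, and is never revisited after seeing test outcomes.

Real data differ in ways the simulator does not attempt: batch effects
across cohorts, phylogenetic correlation of abundances, zero-inflation
beyond the multinomial, within-subject time series, and taxonomy. A green
test therefore establishes that the *pipeline* recovers planted structure
under its own stated assumptions — not that any biological claim about a
real cohort is reproduced.

## Numerical choices and degenerate inputs

* All RNG flows through explicit seeds; internal sub-seeds are derived
  deterministically and kept below 2^31.
* Spearman p-values use the t approximation (exact permutation p-values are
  out of scope); the brute-force rank-formula oracle bounds the correlation
  itself at 1e-12.
* `bin_misclassification` requires bin edges that strictly increase from 0
  to 1 (no overlaps, no gaps); the threshold call is `P >= 0.5`.
* Empty structures are errors where silence would corrupt downstream
  statistics ("no stable edges", "empty feature set", one-class AUC), and
  flagged results where emptiness is informative (empty bridging subgraph,
  degenerate permutation null).
* Jaccard of two empty sets is 1 in `zone_concordance` (identical grey
  sets) but 0 per-node in `neighbor_jaccard` (an isolated node shares no
  neighborhood evidence); each convention is the informative one for its
  question.

## Scaled-down simulations in the test suite

The acceptance tests run at the stated scales (10 seeds for guild recovery,
500 calibration repetitions, 100 odds-ratio replicates, 20 robustness
instances). A few *unit* tests scale down reference simulations (30 seeds
instead of 100 for null centering and OLS coverage) to keep the default
suite fast; each such test notes the scaling inline.

## Known limitations

* "Sociality" between two condition networks is implemented as
  neighbor-set Jaccard; an alternative presence-profile Jaccard matrix is
  provided separately (`presence_jaccard_matrix`) without claiming
  equivalence, since the published usage is ambiguous between the two.
* The classifier grid is small and documented; exhaustive hyperparameter
  search, SHAP attribution and automated ensembling are out of scope.
* Univariate neonatal risk ORs are supported as computations
  (`odds_ratio_2x2`) but have no reference values to compare against
  without the underlying tables.
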