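---
title: "Assessing cross-species conservation of gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing cross-species conservation of gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossec)
```

## The problem

Whether a gene's expression program has been conserved between two species
cannot be read off by comparing raw intensities: arrays, probes and
platforms differ, so cross-species comparisons must be indirect. Two
families of methods dominate. *Corresponding-tissue* methods compare a
gene's expression pattern over tissues judged biologically equivalent in
the two species. *Co-expression reference-set* methods avoid matched
tissues entirely: they ask whether a gene co-varies with a reference set of
1-1 orthologs in the same way in both species, so they apply to any pair of
expression compendia, even with disjoint condition panels.

`crossec` implements one corresponding-tissue method and three
co-expression methods, their divergence (Euclidean-distance) counterparts,
the null controls used to show that orthologs score non-randomly, the
agreement statistics used to compare methods with one another, and a
simulator of paired two-species expression data with known per-gene
conservation so that every claim in this document is testable by code in
this package.

## Scores

**Corresponding-tissue EC** (`liao_zhang_ec`). Over $n$ corresponding
tissues, each profile is normalized to relative abundance,
$s_{ij} = E_{ij} / \sum_{j=1}^{n} E_{ij}$, which removes gene- and
platform-specific intensity scale. The expression conservation of ortholog
pair $i$ is the Pearson correlation of its two RA vectors; the divergence
counterpart (`liao_zhang_distance`) is the Euclidean distance between them,
which lives in $[0, \sqrt 2]$ on the probability simplex.

**Co-expression ECs.** Both species' matrices are restricted to the $k$
1-1 ortholog pairs and row-aligned. Each is converted to a $k \times k$
pairwise correlation matrix (PCM) of Pearson correlations between gene
profiles over *all* conditions of that species (`pairwise_correlation_matrix`).
Row $i$ of a PCM describes how ortholog $i$ co-varies with every reference
ortholog. Three scores compare row $i$ across species:

* `dutilh_ec`: plain Pearson correlation of the two rows over the whole
  ortholog set (WOS);
* `icc`: iterative weighted refinement — reference ortholog $j$ receives a
  weight derived from its own EC at the previous iteration, and every EC is
  recomputed as a weighted Pearson correlation (`weighted_pearson`),
  repeating until the largest EC change falls below a tolerance;
* `essien_ec`: the reference set is restricted to nodes of conserved
  co-expression networks (CCNs) — orthologs that have at least one partner
  with which they are significantly co-expressed in *both* species
  (`identify_ccn_nodes`), significance being calibrated per species against
  an empirical background of 20,000 random gene-pair correlations
  (`background_correlations`, `correlation_threshold`).

`coexpr_distance` gives the Euclidean counterpart over the same reference
positions.

## Numerical and design choices

Choices the underlying literature leaves open are fixed as follows.

* **Self-exclusion.** Both PCM diagonals are exactly 1 by construction and
  carry no cross-species information, so position $j = i$ is excluded from
  every row comparison (all methods, consistently). Including it would
  shift every EC upward by the same mechanism and inflate agreement between
  methods.
* **ICC weights.** Weights are previous-iteration ECs clamped at 0
  (`weight_floor`), so reference orthologs that appear anti-conserved get no
  weight rather than a negative one, which would make the weighted
  correlation incoherent as a weighting scheme. `(EC+1)/2` ("shifted") and
  raw variants are available; invalid ECs always get weight 0. Iteration 0
  uses uniform weights and is *exactly* the whole-ortholog-set EC — this
  identity is tested.
* **Convergence.** The max-norm of the EC change, tolerance `1e-3`, at most
  100 iterations, recorded per iteration in the returned history. Max-norm
  is the strictest elementwise criterion, so "converged" is a conservative
  claim. On the default simulation the fit converges in about 5 iterations.
* **CCN edges.** "Significantly correlated" is implemented as a strict
  inequality against the per-species background quantile threshold. Strictness
  only matters at ties; it guarantees that thresholds of exactly 1 give no
  edges. Background pairs are drawn with replacement (collisions are
  immaterial at 20,000 draws), degenerate constant-profile draws are
  skipped and counted, and the quantile is the linear-interpolation
  (type-7) definition.
* **Expression floor.** Intensities that never reach the floor (default
  200, the conventional summarized-intensity cutoff) in one species cause
  the ortholog *pair* to be dropped from both matrices. Masking individual
  low values instead would create incomplete vectors, which every
  correlation here forbids; the filter's purpose — keeping noise-dominated
  profiles out of correlation estimates — is served by removing
  never-expressed genes. Removal is always pair-synchronized so the two
  matrices keep identical row sets.
* **Undefined scores.** A pair whose RA vector is constant, whose profile
  is all zero, or whose PCM row is constant over the reference positions
  gets `valid = FALSE` and a missing EC — never 0, which would contaminate
  distribution summaries. Agreement statistics use complete cases only.
* **Whole-data vs common-tissue test.** `compare_tissue_subsets` uses
  Welch's unequal-variance two-sample t-test (the safer default when only
  "two-sample t-test" is specified); no multiple-testing correction is
  applied and p-values are reported raw.
* **Determinism.** Every correlation sums over ascending reference index;
  every stochastic stage takes an explicit seed; `run_full_comparison`
  derives per-stage seeds from the global seed and the stage name, so
  adding a stage never perturbs another stage's stream and reruns are
  byte-identical.

## Null controls

Two negative controls mirror how conservation claims are validated:

* `random_pair_ec` scores a random gene pairing (a seeded uniform
  permutation of the B side, fixed points allowed and counted) with exactly
  the reference positions — and, for ICC, the final fitted weights — that
  the ortholog analysis used. Forcing the identity permutation reproduces
  the ortholog ECs exactly.
* `permute_reference_orthology` breaks the orthology *inside the reference
  set* by permuting the columns of the species-B PCM; feeding the result to
  any co-expression method should, and in the tests does, abolish the
  ortholog-versus-random separation.

A practical caution encoded in the acceptance tests: all $k$ null ECs from
one draw share a single permutation, so they are cross-correlated and the
mean of one draw fluctuates several times more than the naive
$\mathrm{sd}/\sqrt{k}$ suggests. Null means are therefore estimated by
averaging several independently seeded draws before being compared to the
$3\,\mathrm{SE}$ band.

## The simulator

`simulate_paired_expression` draws from a latent-module model: $m$ module
activities per tissue (standard normal), species B inheriting A's
activities on corresponding tissues up to a `tissue_evolution_sd`
perturbation ("common tissues are not the same tissues"), standard-normal
module loadings per gene, conserved genes keeping identical loadings and
diverged genes having a fraction `divergence_d` of their species-B program
replaced. Intensities are $\exp(\text{signal} + \text{noise})$ — strictly
positive, right-skewed, multiplicative noise — and each array is then
globally scaled to a common trimmed-mean target (`intensity_scale`), the
normalization step of MAS 5.0-style summarization. Without that scaling
step, tissues whose module activities are extreme would have elevated
intensities for *every* gene (since
$\mathrm{E}[e^{\ell \cdot a}] = e^{\lVert a\rVert^2/2}$), a shared array
effect absent from real summarized data that would make randomly paired
genes correlate positively ($\approx +0.05$ at the defaults) and
mis-calibrate every null.

Defaults — $k = 500$ pairs, 30 and 24 tissues with 20 corresponding, $m=8$
modules, half the genes conserved, full divergence for the rest,
`tissue_evolution_sd = 0.2`, log-scale noise 0.3, intensity scale 1000,
seed 7 — are sized so an entire analysis runs in seconds while keeping the
proportions of a real two-species tissue compendium (a minority of tissues
corresponding, a reference set large enough for stable PCM rows).

The `divergence_scope = "noncommon"` option concentrates divergence in
species-B tissues outside the corresponding panel. This is the regime in
which corresponding-tissue analyses are blind to real divergence: ECs
computed from all conditions then disagree with ECs computed from the
common tissues only (agreement $r \approx 0.3$ at $k=300$, 12 of 30
tissues corresponding, full divergence), while with divergence visible
everywhere and a generous common panel the two agree at $r > 0.9$. The
information-loss tests use those two configurations.

What the simulator does *not* emulate: probe-level effects and
cross-hybridization, platform-specific mean-variance relationships,
phylogenetic structure across more than two species, and correlated
tissue-sampling noise. Passing tests therefore demonstrate correctness and
calibration of the estimators under a clean module-structured log-normal
world, not performance guarantees on any particular real compendium.

## A complete run

```{r, eval = FALSE}
out <- run_full_comparison(sim_config(), out_dir = "results", seed = 1)
out$summary            # EC distribution means/sds: orthologs vs nulls
out$agreement          # pairwise method agreement (Pearson, Spearman)
out$subset_comparison  # whole-data vs common-tissue ECs per method
out$recovery           # AUC of each method against the simulated truth
```

On the default simulation all four methods separate orthologs from random
pairs decisively (AUC against the simulated labels ≈ 0.97), the
co-expression methods agree with each other more strongly than any of them
agrees with the corresponding-tissue method, and CCN node sets shrink, and
stay nested, as the background quantile rises — the qualitative structure
expected of a sound implementation.

## Limitations

Scores are global over the condition panel: a gene whose divergence is
confined to a few tissues can score as conserved (the `"noncommon"`
simulations quantify exactly this). Correlation-based EC and
Euclidean-distance divergence need not agree — distance depends on the
scale and dimension of the compared vectors — which is why both are
reported rather than merged. CCN node sets, and therefore `essien_ec`,
depend on the background sample and its quantile; at small $k$ or strict
quantiles the reference set can become too small to be usable (fewer than
4 nodes is an error by design).
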