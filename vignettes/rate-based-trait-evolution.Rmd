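---
title: "Rate-based trait evolution: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-based trait evolution: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the tunable parameters and
why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and the numerical and design decisions that were
genuinely open. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## 1. The multiplicative rate model

The observable is a genes × branches matrix of per-gene branch lengths
$b_{gj}$ (substitutions/site), assumed to factor as

$$b_{gj} = R_j \, r_g \, e_{gj},$$

with $R_j$ a branch-wide rate multiplier (generation length, mutagen
exposure, everything that moves the whole genome's rate on a lineage),
$r_g$ a gene-specific multiplier (the gene's overall level of functional
constraint), and $e_{gj}$ the gene–branch interaction — the residual,
lineage-specific acceleration or deceleration of one gene on one branch.
The biological premise is that shifts in a trait change the selective
constraints on trait-related genes, so lineages with similar trait values
show similar interaction patterns in those genes.

**Estimator.** The factorization is fit as a two-way additive model in log
space, $\log(b_{gj}+\varepsilon) = \mu + \alpha_g + \beta_j + \gamma_{gj}$,
by least squares: row/column means for complete data, alternating row and
column centering iterated to a $10^{-10}$ change tolerance (cap 500
iterations) when entries are missing. This is the minimal estimator
consistent with a pure product model; it is exact (residual-free
reconstruction) and closed-form for complete data. `stats::medpolish` is
available via `method = "median-polish"` for outlier-heavy matrices, but
its effects satisfy median rather than mean centering, so the default
remains least squares. Identifiability is fixed by
$\overline{\alpha} = 0$ and $\overline{\beta} = 0$ (so
$\overline{\log R}$ equals the fitted grand mean), which makes the
interactions doubly centered and comparable across genes.

**Pseudocount.** Gene trees routinely contain zero-length branches, and
$\log 0$ must be avoided; $\varepsilon = 10^{-9}$ substitutions/site
(recorded in the output) is far below any resolvable branch length, so it
perturbs $\log b$ by at most $\varepsilon / b$ — negligible relative to
branch-length estimation error. Analyses that need the decomposition to be
numerically exact on synthetic data (e.g. the recovery checks in the test
suite) pass a smaller $\varepsilon$ explicitly.

**Branch, not node.** Every downstream object is keyed by *branch*:
rate fluctuation is a property of a lineage segment, not of a time point.
Branch identifiers are pure functions of the topology (the taxon name for a
terminal branch, the sorted descendant-leafset string for an internal one),
so they survive newick rotation and can join matrices, trait tables and
predictions across modules.

**Missing taxa in gene trees.** When a gene tree lacks taxa, one of its
branches may correspond to a path of several species-tree branches. The
package assigns the observed length to the most tipward species branch of
the path and records the others as missing — the conservative choice, since
any rule for splitting the length across the path would be invented.
Interactions missing after this mapping are filled, by default, with
$\log e = 0$ ("no deviation", unbiased under the centering constraints);
a per-gene-mean fill is available.

## 2. Trait models and ancestral prediction

Traits observed at terminal branches are regressed on the interaction
features $x_{jg} = \log e_{gj}$, standardized per gene **on the fitting
branches only** (the same constants are then applied to internal branches,
keeping ancestral predictions on the fitted scale). Continuous traits are
modelled as $\log y = \beta_0 + x^\top\beta$ with squared-error loss —
the natural log, since the trait values (days, grams, counts) are positive
and effects are multiplicative; binary traits use logistic deviance. The
L1 penalty shrinks non-informative genes to exactly zero, so the non-zero
set doubles as the list of candidate trait-related genes.

* **Penalty selection.** $k$-fold cross-validation ($k = 10$, explicit
  seeded fold assignment) with `lambda.min` as the default; the 1-SE rule
  is a flag. For *selection-oriented* studies the package's own acceptance
  experiments use the 1-SE rule: under a pure null the CV-minimum routinely
  admits a handful-to-a-dozen noise genes (an expected property of
  `lambda.min`, which optimizes prediction, not support recovery), whereas
  the 1-SE rule keeps null selections near zero at no measurable cost in
  recall in the package's recovery simulations.
* **Coefficients** are reported on the standardized-feature scale —
  unitless, comparable across genes.
* **Missing trait values** exclude their branches from fitting; the fitted
  model then imputes them (provenance flag `imputed`). Ancestral
  predictions carry `predicted-ancestral`. Provenance lets any later
  analysis choose which rows it trusts.
* **Binary calls** threshold the logistic probability at 0.5;
  probabilities are always retained.
* No post-selection inference is attempted: the reported quantities are
  penalized point estimates, and p-values for selected coefficients would
  be invalid without sample splitting, which the modest taxon counts of
  comparative datasets cannot afford.

## 3. Trait coevolution network

Correlations are computed over terminal *and* predicted-ancestral rows —
including reconstructed ancestors deliberately dilutes phylogenetic
pseudo-replication among close relatives, though it is no substitute for a
formal phylogenetic regression (see §7). Continuous traits enter on the log
scale, binary traits as 0/1 numerics; multi-state categories (e.g. diet)
are expanded to one-vs-rest indicators with `one_vs_rest()`. Partial
correlations come from the inverse of the complete-case correlation matrix,
$\rho_{ij\cdot\text{rest}} = -P_{ij}/\sqrt{P_{ii}P_{jj}}$; the matrix's
condition number is reported and a singular matrix is a hard error naming
the remedy (drop a redundant trait).

The network itself is the maximum-weight spanning forest under BIC edge
gains: adding edge $(i,j)$ to an empty Gaussian graphical model improves
the log-likelihood by $-\tfrac{n}{2}\log(1-r_{ij}^2)$ at a one-parameter
cost, giving gain $w_{ij} = -n\log(1-r_{ij}^2) - \log n$ on the BIC scale.
Kruskal's algorithm with positive-gain edges (ties broken by the
lexicographic trait-name pair, so output is order-independent) yields the
minimum-BIC forest — the Chow–Liu tree family restricted exactly as a
sparse "minimum-BIC graph" requires. General decomposable models (which
could add cliques) are deliberately out of scope; the forest is the
minimal class consistent with the sparse networks this analysis is meant
to produce, and on 4-node instances the test suite verifies it against an
exhaustive search over all forests.

## 4. Correlated evolution of binary trait pairs

The joint states of a trait pair (A, B) are ordered (00, 01, 10, 11); the
rate matrix forbids simultaneous double transitions, so 8 rates remain in
the dependent model and 4 in the independent one (each trait's gain/loss
rates blind to the other's state). Rates are in events per Ma because the
tree is time-calibrated. The likelihood is Felsenstein pruning with
per-branch $P(t) = e^{Qt}$; the kernel (C++, Armadillo) diagonalizes $Q$
once per likelihood evaluation and reconstructs each branch's $P(t)$ from
the eigendecomposition, falling back to a Padé scaling-and-squaring
`expmat` per branch when the eigenbasis is ill-conditioned
(reciprocal condition number below $10^{-8}$); zero-duration branches use
the exact identity matrix. Conditional likelihoods are rescaled per node,
so deep trees cannot underflow.

* **Root distribution:** uniform over the four states by default (the
  generator draws the root the same way); the stationary distribution of
  $Q$ can be supplied instead via the `pi` argument.
* **ML:** L-BFGS-B on log rates, bounds $[10^{-8}, 10^3]$/Ma, with seeded
  log-uniform restarts on $[10^{-3}, 10]$/Ma; the best restart is kept and
  its convergence status reported.
* **Test:** $2\Delta\ell$ against $\chi^2_4$ (8 vs 4 free rates). The
  statistic is clamped at 0 (nested models).
* **MCMC:** a fixed-dimension Metropolis–Hastings sampler — componentwise
  log-normal random-walk proposals, independent exponential priors (mean
  1/Ma by default, stated in the output), scale adaptation towards a
  20–50 % acceptance rate during burn-in *only*, so the post-burn-in chain
  has a fixed kernel. A reversible-jump sampler over rate-grouping
  partitions is intentionally not provided: model-averaging over groupings
  is a device for rate regularization, and the scientific question — which
  transitions are asymmetric — is answerable from fixed-dimension
  estimates. Harmonic-mean marginal likelihoods are also deliberately
  absent (they are notoriously unstable); model comparison goes through
  the LRT.

## 5. The synthetic-data generator

Every pipeline stage is exercised against data with known truth:

* **Trees** — forward Gillespie birth–death conditioned on reaching
  `n_taxa` extant lineages, with the present drawn as the waiting time to
  the next event (so no zero-length pendant edges); extinct lineages
  pruned, unifurcations collapsed. Under pure birth the expected depth is
  $\lambda^{-1}\sum_{k=2}^{n} 1/k$, which the tests verify empirically.
* **Latent traits** — Brownian motion on the log scale; the branch-level
  value is the Brownian-bridge draw at the branch *midpoint*, matching the
  convention that traits attach to branches. Terminal observed traits are
  $e^z$.
* **Interactions** — $\log e_{gj} = \gamma_g \tilde z_j + N(0,\sigma_e^2)$
  for a sparse causal gene set ($\tilde z$ the standardized latent trait),
  pure noise otherwise, then doubly centered so the truth satisfies the
  decomposition's identifiability constraints exactly. Branch effects are
  log-normal around $10^{-1.3}$ substitutions/site; gene effects log-normal,
  centered.
* **Trait tables** — Gaussian samples over a declared dependence forest
  (each child = $\rho\,\text{parent} + \sqrt{1-\rho^2}\,\epsilon$), with
  declared binary columns thresholded at their median.
* **CTMC tips** — exact stochastic simulation along branches (exponential
  waiting times), so recorded event lists can be checked for the absence
  of dual transitions and for empirical-rate agreement.

Defaults mirror the mammalian study scale the pipeline emulates (89 taxa,
1204 genes in `simulate_paper_like()`); test presets are much smaller.
What the generator does **not** emulate: alignment-level estimation noise
in branch lengths (interaction noise is log-normal, with no heavy-tail
option exercised by default), gene-tree discordance from incomplete lineage
sorting (gene trees share the species topology by construction), and
correlated noise across genes. Passing tests therefore demonstrate
correctness of the inference machinery under the stated model, not
robustness to all failure modes of real phylogenomic data.

## 6. Acceptance-study designs and problem sizes

The property studies run by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` use these fixed designs:

* **Decomposition exactness:** 40 taxa × 60 genes complete (recovery vs
  generating truth), and a 40 × 25 matrix with 15 % missing cells compared
  against a sum-contrast least-squares oracle.
* **Likelihood oracles:** 50 random 4-taxon instances against brute-force
  enumeration over internal states; 10 random 20-taxon trees for the
  independent-model factorization identity.
* **CTMC calibration:** 200-taxon trees, baseline 0.05 transitions/Ma for
  all four rates — the labile-behavioural-trait regime, giving on the order
  of 10² transition events per tree, enough for the $\chi^2_4$ asymptotics
  to be meaningful. A design-stage sweep showed the LRT grows visibly
  anticonservative when events are scarce (sparser baselines), which is a
  finite-sample property of the 8-vs-4 comparison, not an implementation
  artifact — the fits were verified to sit at their global optima. Power
  uses the single-transition strong-dependence scenario
  $q_{01\to11} = 5\times$ baseline; 50 null and 20 power replicates.
* **Rate recovery:** all four rates 1.0/Ma on 500-taxon trees of ~100 Ma
  depth. Note this scenario is largely *saturated* — with $2qt \gg 1$ on
  most branches, tip states are near-stationary and the rate magnitude is
  informed only by the youngest cherries, so ML estimates scatter widely
  around the truth; at 0.05–0.1 events/Ma on the same trees recovery within
  a factor of 2 is essentially certain. The reported fraction should be
  read with that identifiability caveat.
* **Sparse recovery:** 100 taxa, 300 genes, 20 causal, $\gamma = 1.0$,
  $\sigma_e = 0.4$ (signal-to-noise 2.5 on the interaction scale), 20
  replicates, 1-SE penalty; nulls identical with 0 causal genes.
* **Network oracles:** residual-regression partials on 6-trait instances;
  exhaustive-forest comparison on 20 4-trait instances; 5-trait chain
  ($\rho = 0.6$, $n = 1000$) structure recovery.
* **Paper-scale sanity:** one 89 × 1204 run; the selected-predictor count
  is checked only for its order of magnitude (tens, not thousands).

These sizes keep the full suite within minutes on a single CPU while
leaving each study enough replicates for its pass band.

## 7. Known limitations

* **No phylogenetic regression.** Neither the LASSO stage nor the
  correlation network applies GLS/independent-contrasts corrections;
  including predicted ancestors reduces, but does not remove,
  phylogenetic non-independence. This mirrors the analysis the package
  reimplements and is a documented modelling choice, not an endorsement.
* **Binary traits as numerics.** Partial correlations treat 0/1 traits as
  Gaussian; a mixed conditional-Gaussian model would be more principled
  but is out of scope. Sign conventions flip with the coding; magnitudes
  do not.
* **Forest-only networks.** Trait dependence structures with cycles are
  represented by their best forest approximation.
* **Selection, not inference.** Non-zero LASSO coefficients are candidate
  genes, with no error control on the selected set.
* **LRT calibration depends on event counts**, and ML rate magnitudes are
  unidentifiable in the saturated regime (§6). For sparse trait data, the
  MCMC posterior (with its explicit prior) is the more honest summary.
* **Gene trees must match the species topology** on shared taxa; genuinely
  discordant genes are skipped, not reconciled.
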