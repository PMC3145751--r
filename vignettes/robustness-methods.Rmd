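---
title: "Methods: how phylorobust measures phylogenetic robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how phylorobust measures phylogenetic robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phylorobust` quantifies how much of a phylogenetic reconstruction
survives systematic perturbation of its input data. This vignette is the
package's own account of the models and procedures it implements, the
parameters that matter, the design decisions that were genuinely open,
and the limits of what its synthetic benchmarks can show.

## 1. The likelihood engine

Everything downstream of the raw alignment — site-rate classification,
per-site log-likelihoods for topology tests — rests on a
Felsenstein-pruning engine for time-reversible substitution models with
discrete-gamma rate variation.

A model is a symmetric exchangeability matrix `S`, stationary
frequencies `π`, and a gamma shape `α` discretized into `k`
equal-probability categories. The rate matrix is `Q = S·diag(π)`,
rescaled so `−Σ π_i Q_ii = 1`; branch lengths are therefore in expected
substitutions per site. Transition probabilities come from one symmetric
eigendecomposition of `diag(√π)·Q·diag(1/√π)` per model, reused for
every branch and rate category. For nucleotides the engine is GTR (with
Jukes–Cantor as the uniform special case); for proteins it uses the
published LG and WAG exchangeabilities and frequencies.

Category rates use the **mean** (not median) discretization: with bin
boundaries at the `j/k` gamma quantiles, the rate of category `j` is its
conditional mean, computed through the incomplete-gamma identity, so the
category rates always average exactly 1. The mean method matches the
behaviour of the widely used ML implementations; the median method
systematically rescales total tree length, which would leak into the
tree-length comparisons the pipeline reports.

Numerically, partial likelihood vectors are rescaled per node whenever
their column maximum falls below 1e-80, with the logs accumulated
separately — the standard guard against underflow on trees with
hundreds of taxa. Gap, `?`, and ambiguity characters are marginalized:
a gap contributes a partial vector of ones, an ambiguity code the
indicator of its compatible states. A column of only gaps therefore has
likelihood exactly 1 (log-likelihood 0). The engine is validated against
exhaustive state enumeration on 4–5-taxon instances (tolerance 1e-10)
and against an independent ML implementation, and it satisfies the
pulley principle: re-rooting never changes any site likelihood.

## 2. Site-rate classification and stripping

Per-column rate classes are assigned by empirical Bayes. With the
per-category likelihoods `L[c,j]` from the engine and a uniform prior
over the `k = 8` categories, the posterior is
`P(j|c) = L[c,j] / Σ_m L[c,m]`; each column reports its posterior-mean
rate and its MAP class, labeled 0 (slowest) through 7 (fastest).
**Posterior ties break toward the slower class** — the conservative
choice, since mislabeling a slow site as fast would strip it. The MAP
rule itself was an open choice (a thresholded-posterior rule is equally
defensible); MAP is implemented because it makes the stripping cascade a
deterministic function of the classification.

Stripping removes the columns of the fastest classes — {7}, then {7,6},
then {7,6,5} — and by default only inside nucleotide partitions:
fast-site saturation is primarily an rDNA phenomenon in two-partition
rDNA+protein datasets, and the protein partition is left intact. The
classification is computed on a fixed input tree with fixed branch
lengths (the best available reconstruction); branch lengths are not
re-optimized. The gamma shape can be estimated first with
`fit_gamma_shape` (Brent search, tolerance 1e-4); on 16 taxa × 1000
sites simulated at α = 0.5 the estimate lands near the truth and the
posterior-mean rates correlate with the true simulated rates at
Spearman ρ > 0.8 (recomputed by `scripts/acceptance.R`).

## 3. Tree-quality metrics

**Tree length** is the sum of branch lengths. **Treeness** is the
fraction of tree length in internal branches, computed on the unrooted
topology (a root bisecting an edge would otherwise split one internal
edge in two). Low treeness means most inferred change sits on terminal
branches — substitutions that inform no grouping.

**Root-to-tip lengths** root the tree on the outgroup's stem edge,
split at its midpoint, then measure the path to every leaf. When the
input tree is already rooted at the outgroup split, the stem is the
outgroup-side root edge as given; when the tree arrives unrooted, the
stem is the full edge separating outgroup from ingroup and the root
bisects it evenly. Long-branch ranking averages these values over all
supplied reconstructions, skipping trees that lack a taxon, with ties
broken by label so the removal list is reproducible.

**Leaf stability** scores each taxon X over quartets {X,a,b,c}: across
the bootstrap tree set, the three unrooted resolutions of the quartet
have frequencies f1 ≥ f2 ≥ f3 (trees missing any of the four taxa are
skipped for that quartet — per-quartet renormalization), and the
quartet scores f1 − f2. Stability(X) is the mean over its quartets.
The *difference* variant is the default because it degrades smoothly:
a quartet split 50/50 between two resolutions scores 0 whether or not
the third resolution ever occurs. The *max* (f1) and *entropy* variants
are available behind a flag; the literature defines several variants and
the difference form is this package's documented choice. Quartet
resolution inside a tree uses the four-point condition on topological
(unit-branch-length) distances, which is exact for binary trees and
counts unresolved quartets for no resolution.

Exact enumeration covers all C(n,4) quartets when that count is below
2×10^6; beyond that, `m` quartets are sampled per taxon with a seeded
stream (default 1000·n overall). On 12-taxon, 200-tree benchmarks the
sampled estimator stays within 0.02 of exact enumeration.

The per-reconstruction summary is the mean stability over taxa with a
95% normal-approximation CI **across taxa** (1.96·sd/√n). An
alternative reading — a CI across bootstrap replicates — would measure
resampling noise instead of taxon heterogeneity; across-taxa is
implemented because the quantity being compared between dataset
variants is "how consistently placed is a typical taxon".

**Clade support** asks, per tree, whether the hypothesis members
present in that tree form one side of a bipartition of the unrooted
topology (so support is invariant to complementation). The support
table renders each hypothesis × reconstruction cell as an integer
percentage, `nm` when the members are present but not monophyletic in
that reconstruction's best tree, or `-` when fewer than two members are
sampled; raw unrounded percentages stay available in an attribute.

## 4. Topology tests

All tests run on a candidates × sites matrix of per-site
log-likelihoods, resampled by RELL: each bootstrap replicate draws
`⌈r·S⌉` columns with replacement and sums them — crucially, the *same*
column draw for every candidate, which preserves the between-candidate
correlation that the centered test statistics depend on.

The weighted KH test compares each candidate to the ML candidate (the
ML candidate itself is compared to the runner-up), standardizing the
observed log-likelihood difference and the centered replicate
differences by the replicate standard deviation. The weighted SH test
keeps the same observed statistic but corrects for multiple comparisons
in the null: it maximizes the standardized centered differences over
all candidates. This formulation guarantees `p_wsh ≥ p_wkh` for every
candidate — the defining conservativeness of the SH family — which
would not be guaranteed if the observed statistic were also
re-maximized. Candidates with identical rows (zero-variance
differences) receive p = 1 by convention.

The AU test runs RELL at ten scales `r = 0.5 … 1.4`, records the
bootstrap probability BP(r) of each candidate being best (ties split
evenly), applies the continuity correction `1/(2·B)` at BP of 0 or 1,
and fits `z(r) = qnorm(1 − BP(r))` to `d·√r + c/√r` by weighted least
squares with delta-method binomial weights; `p_au = 1 − Φ(d − c)`.
When BP is degenerate at every scale the fit cannot identify `d` and
`c`, and p is reported as 0 or 1 with a degenerate-fit flag. The scale
set and correction are implementation-dependent across established
tools; the defaults here are documented and overridable.

Calibration (recomputed by the acceptance script): on exchangeable-null
matrices the weighted KH test rejects at close to its nominal 10% level
(500 datasets), and two identical candidates each get `p_au ≈ 0.5`, the
symmetric fixed point of the multiscale fit.

## 5. The experiment pipeline and its stand-in inference

`run_experiment` builds the variant grid in dependency order: base →
rate-stripped (−7, −76, −765) → long-branch-removed (−LB) →
unstable-removed (−us) → combined (−LB−us) → environmental-pool (+Env).
The long-branch and unstable removal lists are **frozen from the base
variant's trees** before any derived variant is built, so derived
variants answer "what happens when *these* taxa leave" rather than
re-ranking on shifting ground. The outgroup is never eligible for
removal.

Inference inside the pipeline is Jukes–Cantor distances + neighbor
joining + column bootstrap — a deliberate, clearly labeled stand-in for
full ML/Bayesian inference, chosen so the whole grid runs in minutes on
one CPU. The `ingest` argument accepts externally inferred best trees
and bootstrap sets per variant, so the same grid, metrics, and reports
can wrap RAxML/MrBayes output when users run those themselves. The
distance stand-in applies the 4-state correction to the pooled mismatch
proportion even on mixed nucleotide+protein data; this is not a
likelihood-grade protein distance and is not meant to be. Saturated
pairs (mismatch ≥ 0.75) are capped at a configurable 5
substitutions/site with a warning; pairs sharing no scored columns are
an error in direct use, but inside the pipeline's inference (best tree
and bootstrap replicates alike) they are capped instead — with very
fragmentary taxa in the data such pairs can arise at any seed, their
mutual distance is genuinely uninformative, and capping is the only
sensible continuation. Negative NJ branch lengths are clamped to
zero with the deficit moved to the sibling edge, preserving path
lengths through the parent node.

A grid of arbitrary variants is configurable; the default synthetic
grid has 8. (Published comparative studies often report more —
combinations of masking strategies and taxon grids — and the same
machinery expresses those as additional variants.)

## 6. What the synthetic generator emulates — and what it does not

The generator is the package's definition of the study conditions, and
its defaults are fixed:

- **Tree**: Yule ingroup of 40 taxa conditioned on n, rescaled to
  root-to-tip depth 0.8 substitutions/site, plus a single outgroup on a
  stem of the same depth. Depth 0.8 gives terminal branches long enough
  that a ×10 scaling is unambiguous while keeping distances below the
  saturation cap.
- **Sequences**: 1000 nucleotide columns under GTR+Γ (α = 0.5, k = 8 —
  strong rate heterogeneity, the regime where fast-site stripping is
  meaningful) and 300 protein columns under LG+Γ (α = 0.5, k = 4),
  with true per-site rates and classes recorded.
- **Long-branch taxa**: the 5 ingroup tips with the longest terminal
  branches, scaled ×10. Choosing the longest-terminal tips (rather than
  random ones) makes the planted condition dominate stochastic
  branch-length variation, so detection failures indicate method
  errors, not generator noise.
- **Rogue taxa**: 3 tips made *fragmentary* — all but 6% of their
  columns erased. This mirrors the empirically common source of rogue
  behaviour (partial environmental reads, taxa sequenced for one gene
  only) and produces placement instability without creating a long
  branch, keeping the two planted conditions separable by the two
  detectors. An alternative operationalization, prune-and-regraft
  wandering applied directly to tree sets (`inject_rogue`), is used for
  fixtures that need a rogue with a *known* stability rank.
- **Environmental pool**: copies of reference sequences at controlled
  identities {1.0, 0.99, 0.90}, so a 0.98 dereplication threshold has a
  known right answer.
- **Bootstrap depth**: 200 replicates per variant; leaf stability uses
  12 000 sampled quartets per variant. These sizes keep the full grid
  under a minute per seed while leaving the stability ranking stable
  enough to reproduce across reruns.

Randomness is split into per-operation streams (`derive_seed` hashes
the user seed with the operation name), so inserting a stage into a
workflow never perturbs the draws of other stages, and identical
configurations are bit-identical.

What passing tests on this generator do **not** show: the simulator has
no indels or alignment error (columns are homologous by construction),
no compositional heterogeneity or heterotachy (one stationary
reversible process per partition), no model misspecification (data are
scored under the generating family), and rogue taxa arise only from
missing data, not from genuine conflicting signal such as paralogy or
recombination. Real datasets violate all of these; results here
establish internal correctness of the pipeline, not robustness of any
biological conclusion.

## 7. Interfaces and scope

The package's interface is its exported functions, this vignette, and
`scripts/acceptance.R`; as an R analysis library its users script it
directly, so no shell CLI is shipped. File formats are FASTA and
relaxed sequential PHYLIP for alignments (with a TSV sidecar mapping
kept columns to original 1-based coordinates through stripping),
multi-tree Newick for tree sets (supports read from internal node
labels), YAML for clade-hypothesis lists, and TSV/Markdown/JSON for
reports, with the JSON round-tripping to an equal report. NEXUS,
alignment construction, and automated masking are out of scope; masked
site lists are consumed as input, never inferred.

## 8. Known limitations

- The NJ stand-in underestimates support for short internal edges
  relative to ML; grid comparisons remain meaningful because every
  variant uses the same inference, but absolute support values are not
  comparable to published ML bootstraps.
- Greedy dereplication is order-dependent (input order by default,
  longest-first optionally), like the tools it mirrors.
- The AU implementation uses fixed default scales and a simple
  continuity correction; p-values near the rejection boundary deserve
  confirmation with a dedicated tool.
- `fit_gamma_shape` optimizes the shape only; joint estimation of
  exchangeabilities, frequencies, and branch lengths is deliberately
  out of scope, since classification needs only a reasonable fixed
  model and tree.
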