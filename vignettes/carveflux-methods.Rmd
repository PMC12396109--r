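---
title: "Methods: carving, flux sampling and metabolic gene scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carving, flux sampling and metabolic gene scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carveflux)
```

# The model and its assumptions

`carveflux` treats metabolism under the standard constraint-based
assumptions: mass-action at quasi-steady state, so that any achievable
metabolic state is a flux vector $v$ with $Sv = 0$ inside the bounds
$lb \le v \le ub$, where $S$ is the stoichiometric matrix of a
genome-scale metabolic model (GEM). The set of such vectors is a convex
polytope; everything downstream — sampling, correlation scores, mean
fluxes — is a statement about this polytope, not about kinetics. Two
further assumptions are inherited from the input side:

* the universal model (Recon3D-like, SBML L3/fbc or COBRA JSON) is
  taken as given, including its medium/exchange bounds (overridable by
  a medium TSV but never inferred);
* the expressed-gene lists are treated as binary presence evidence.
  Expression *levels* influence nothing beyond the threshold filter;
  this mirrors the carving protocol's use of gene lists rather than a
  weighted objective.

# Expression filtering

Filtering is deliberately conservative and per condition: one expressed
list, and hence one carved model, per condition. The default rule keeps
a gene when its CPM exceeds `min_count / median(library size) * 1e6`
(defaults `min_count = 10` counts) in at least `ceil(min_prop * n)` of
the condition's samples (`min_prop = 0.7`) and its total count reaches
`min_total_count = 15`. These defaults mirror the widely used
`filterByExpr` heuristic; `min_prop` applied to the condition's own
sample count replaces that tool's group-size logic, which is ambiguous
for multi-group designs — the choice is configurable. Two simpler rules
(raw count, plain CPM cutoff) are selectable for sensitivity analyses.
Library size is the raw column sum: the inputs are UMI counts, for
which composition-normalization factors have no obvious justification
and would change only the cutoff scale.

# Carving

The context-specific model is the optimum of a mixed-integer program:
inclusion indicator $y_r$ per reaction, flux coupling
$lb_r y_r \le v_r \le ub_r y_r$, steady state, a functionality floor
$v_{bio} \ge f_{min} \cdot v^{max}_{bio}$, and an activation constraint
forcing every *included, gene-supported* reaction to carry at least
`flux_activation_eps` absolute flux, so the objective cannot collect
rewards for reactions that are structurally unable to run. Weights:
`+1` for a GPR evaluating TRUE, `-penalty_absent` (default 1) for
FALSE, `-penalty_nogpr` (default 0.01) for GPR-less reactions. The
defaults make one supported reaction worth more than the parsimony cost
of dozens of GPR-less carriers, which matches the intent of top-down
carving: keep expressed metabolism, drag along only the transport and
exchange backbone it needs. `f_min = 0.1` keeps carved models
functional without forcing near-optimal growth, which expressed-gene
evidence alone cannot justify; both are configuration, not convention.

Numerically the MIP is solved by branch-and-bound on the binaries over
an LP relaxation. Three choices matter:

* **LP solver.** A dense two-phase primal simplex with Bland's rule is
  implemented in the package. Bland's rule is slower than steepest-edge
  pivoting but cycle-free and fully deterministic, which makes carving
  reproducible bit for bit; at the problem sizes this package targets
  for exact solving (tens of reactions after fixing binaries), dense
  tableaus are faster than any sparse machinery.
* **Activation of reversible reactions** is linearized with a direction
  indicator and big-M constants equal to the reaction's own bounds, the
  tightest valid choice.
* **Integrality acceptance.** A relaxation solution that looks integral
  (binaries within 1e-6 of 0/1) is never accepted directly: with big-M
  bounds, $y = 10^{-7}$ still admits $|v| \approx 10^{-4}$ of phantom
  flux. Every candidate is re-verified by re-solving the LP with the
  binaries fixed at their rounded values; the incumbent objective is
  evaluated on the rounded binaries exactly. Ties between equally
  optimal subnetworks are broken by the deterministic search order; the
  carve report records the objective so ties can be detected.

Blocked reactions (flux-variability range inside `[-tol, tol]`,
`tol = 1e-9`) are removed before sampling; otherwise the polytope is
degenerate along those axes and hit-and-run directions collapse.

# Flux sampling

The global sampler is artificial-centering hit-and-run: directions are
drawn from stored points (warmup vertices plus previously recorded
samples) minus the running center, the step is uniform on the feasible
segment, and every `thinning`-th iterate is recorded. Warmup is
`2 * n_reactions` LP vertices, the FVA corners first. Default
`thinning = 100` balances autocorrelation against runtime at the
package's test scale (models of roughly 5–50 reactions, chains of
5,000–150,000 recorded samples); production-scale runs on real GEMs
conventionally use much larger thinning, which is a config value, not a
code change.

One numerical hazard deserves a note: the centering feedback *amplifies*
rounding error orthogonal to the steady-state subspace exponentially
(each step can multiply the off-subspace component by
$|t| / \lVert p - c \rVert$, which routinely exceeds 1). The chain is
therefore re-projected onto the null space of $S$ every 50 steps and
before every record, using an orthogonal projector precomputed by SVD.
Without this, chains silently leave $Sv = 0$ after a few hundred steps;
with it, the residual stays at machine precision. For the same reason
points are never clamped to bounds — clamping leaves the subspace — and
bound feasibility is instead guaranteed by the segment computation.

The corner sampler solves one LP per sample with independent
standard-normal objective coefficients, emphasizing extreme phenotypes.
Corner samples are vertices, not a Markov chain, so they are excluded
from convergence testing; both samplers feed the same scoring.

Convergence control follows the two classical diagnostics. Geweke's
$z$ compares the first 10% and last 50% of each reaction's chain,
with segment variances estimated by the spectral density at frequency
zero (Bartlett lag window over 4% of the segment; the plain variance is
available and the report records which ran). Raftery–Lewis is the
published two-state Markov procedure: binarize at the empirical
$q$-quantile ($q = 0.025$), find the smallest thinning at which a
first-order chain beats a second-order one by BIC, and convert the
transition probabilities into a required length (with
$N = q(1-q)(\Phi^{-1}((s+1)/2)/r)^2 \approx 3746$ as the iid floor at
the defaults $r = 0.005$, $s = 0.95$). Sampling stops when 95% of
non-constant reactions pass $|z| < 1.96$ *and* the chain exceeds the
largest Raftery–Lewis requirement among the 50 highest-variance
reactions, or at `max_samples` (150,000) with `converged = FALSE`
reported rather than raised. The thresholds (1.96, 95%, top-50) are
package choices: the diagnostics themselves are standard, but no
canonical stopping rule exists, so the report always carries the full
per-reaction evidence.

Determinism: all randomness flows from one user-visible seed; the C++
chain core uses R's own RNG stream, so identical (model, config, seed)
gives bit-identical sample matrices, and batch continuation is part of
the same stream.

# Reaction and gene scoring

The Reaction Cumulative Correlation score of reaction $i$ is
$\sum_j |\mathrm{corr}(v_i, v_j)|$ over *all* $j$, self-correlation
included, with the convention that zero-variance columns correlate 0
with everything — including themselves. This is the only reading under
which the score's range $[0, N_{reactions}]$ is attained at both ends:
a constant-flux reaction scores exactly 0 and a reaction perfectly
coupled to every other scores exactly $N$. Pearson correlation is the
default ("correlation" unqualified); Spearman is selectable.

Mean flux per reaction (mol·kgDW⁻¹·h⁻¹) is the usage measure. Condition
comparisons use Welch's unequal-variance $t$ on strided subsamples (the
stride chosen so at most 1,000 values per side enter the test) because
hit-and-run draws are autocorrelated and per-sample tests would
overstate significance; the stride is recorded in the table's metadata
and the caveat stands — these $p$-values rank evidence within a run
rather than calibrate error rates. Reactions absent from one carved
model are compared against an identically-zero column (union
semantics): absence *is* the carving signal, and membership flags let
users restrict to the intersection. Degenerate conventions: two
constant columns give $p = 1$ when their means agree and $p = 0$
otherwise; one constant column is tested one-sample against its value.

Projection to genes is by GPR membership — any gene appearing anywhere
in the rule is involved; AND/OR structure does not weight membership.
The default aggregation over a gene's reactions takes the value of
largest magnitude with its sign (a gene is as important as its most
important reaction); `mean` and `sum` are selectable, and the
unaggregated gene × reaction long table is always emitted so no choice
destroys information. The gene-level $p$-value is that of the
best reaction, not a combination: combining overlapping, autocorrelated
tests honestly is out of scope and flagged as such. Signature selection
applies the conventional thresholds (|Δ| > 0.5 flux units, $P < 0.05$,
directional) at the *gene* level after projection; a config flag moves
the Δ-filter to reaction level for users who prefer pre-filtering.

Enrichment: hypergeometric upper-tail ORA with Benjamini–Hochberg
adjustment, with the carved models' gene union as the default universe
— testing model genes against a whole-genome universe would
manufacture enrichment from model membership alone. GSEA is pre-ranked
(weight exponent 1) with gene-label permutations, since the input is
one score per gene, not per-sample expression; NES normalizes by the
mean |null ES| of matching sign and the permutation $p$ carries a +1
pseudocount.

# The synthetic-data generator

`toy_universal_model()` builds a linear uptake→backbone→biomass chain
with unit stoichiometry (maximal biomass = the uptake bound, default
10 flux units), distinct single-gene GPRs on internal reactions, and
optional alternative routes. `synthetic_counts()` draws
negative-binomial UMI counts, mean 200 for expressed genes versus 1 for
silent ones at dispersion 10 — a separation chosen so the expression
filter is essentially never the failing component in end-to-end tests
(filter-focused tests tighten it deliberately).

The default two-condition fixture plants one branch spanning the full
backbone (first to last backbone metabolite) whose gene is expressed
only in condition A. The full span is an identifiability decision, not
a convenience: a partial bypass between interior metabolites changes
the sampled throughput distribution of the *shared* upstream and
downstream reactions (on the branched side their mean rises — e.g. a
single full-span branch shifts total throughput from uniform mean 5 to
triangle-distribution mean 20/3), so non-branch genes would genuinely
cross the +0.5 selection threshold and "exact recovery" would be the
wrong ground truth to demand. With the full-span branch, the positive
flux differences are confined to the branch gene while backbone genes
shift negative — the planted signature is exactly recoverable, which is
what the end-to-end tests assert.

What the generator does **not** emulate: sequencing artifacts, barcode
collisions, dropout, gene-length effects, correlated gene modules,
partially expressed GPR complexes, realistic GEM-scale degeneracy
(thousands of reactions, extensive alternate optima) or biologically
calibrated flux bounds. Passing tests demonstrate algorithmic
correctness on polytopes small enough for exhaustive oracles — MILP
enumeration up to 8 reactions, brute-force RCC at 50 × 20 — not
statistical performance on real transcriptomes against Recon3D.

# Known limitations

* Exact enumeration-verified carving is only feasible at toy scale; on
  real GEMs the same branch-and-bound runs but exactness claims rest on
  the algorithm, not on an oracle, and runtime grows with the number of
  fractional binaries.
* No loopless-flux correction: thermodynamically infeasible cycles can
  inflate both RCC and mean-flux estimates on models that contain them.
* No identifier mapping: counts must be keyed on the model's gene
  namespace (exact string match after whitespace trimming).
* The differential $p$-values inherit sampler autocorrelation; treat
  them as ranking scores (the package applies no reaction-level
  multiple-testing correction by design — correction happens at the
  gene/pathway level).
* No gap-filling and no ensemble carving; one deterministic model per
  condition.
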