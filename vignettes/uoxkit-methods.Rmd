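---
title: "Models and methods in uoxkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in uoxkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uoxkit)
```

`uoxkit` packages three analyses around the evolutionary repurposing of
vertebrate uricase: a differential amino-acid composition scan across
orthogroups, ancestral reconstruction of cysteine presence/absence with
per-branch gain/loss counting, and kinetic modelling of the uricase
reaction chain. This vignette records the models, their assumptions, the
parameters that matter, and the design decisions taken where more than one
defensible choice existed.

## Orthologous composition scan

**Model.** Each sequence is summarized by its composition over the 20
standard amino acids, as fractions of the counted length. Ambiguity
letters (X, B, Z, U, J, O) and the stop symbol are excluded from both
numerator and denominator, so fractions always sum to 1; the excluded
tally is kept per row. "Content" enters the statistics as a fraction
rather than a raw count because fold changes must be invariant to sequence
length; raw counts remain available through `residueCounts()` for
per-sequence cysteine tallies.

For a clade pair (A, B), each orthogroup × amino acid gives the arithmetic
means of per-sequence fractions per clade, `log2(mean_A / mean_B)`, and a
two-sided unequal-variance (Welch) *t*-test p-value. Welch is the default
because clade dispersions differ in practice; a pooled-variance option is
provided (`pooled = TRUE`). Rows where a statistic is undefined — fewer
than two sequences in a clade, zero variance in both groups, or a zero
group mean — are emitted with `NA` and classified `ns`, never silently
dropped. No pseudocount is added by default, since pseudocounts distort
rare residues such as Cys and Trp; an optional pseudocount of half the
smallest nonzero fraction can be switched on.

**Thresholds.** The volcano classification uses a raw p-value cutoff of
1e-16 and a log2 fold-change cutoff of ±1. No multiple-testing correction
alters the classification (the raw cutoff is already extreme); a
Bonferroni column is appended for reference only.

**Filtering.** `filterOrthogroups()` retains orthogroups that are
single-copy in every represented species and present in at least 90% of
the species universe. The universe is the explicit species list of the
clade map, not the species observed in the data, so the presence rule is
deterministic. Clade assignment is an explicit input file; no taxonomy
service is consulted at run time.

## Ancestral cysteine gain/loss

**Recoding.** Full 20-state ancestral sequence reconstruction is not
attempted. Each alignment column is recoded as a binary character —
target residue present (1) or absent (0) — with gaps and ambiguity letters
masked, because only per-branch gains and losses of one residue are
consumed downstream. The binary recoding makes every reconstruction
checkable against exact enumeration oracles.

**Parsimony.** `fitchMPR()` computes the parsimony score and the exact MPR
state sets by a unit-cost dynamic program (conditional subtree costs in
postorder, rest-of-tree costs in preorder); a state is in a node's set iff
it is attained by at least one minimal labeling. Masked leaves are
uninformative. `acctranResolve()` fixes one optimal labeling: nodes are
visited in preorder and, where both states remain optimal given the
parent's resolved state, the state *differing* from the parent is chosen,
placing changes as close to the root as possible (accelerated
transformation); a root tie resolves to absence. This tie rule is
deterministic and documented, but it is one defensible convention, not a
claim about how any particular published reconstruction resolved its
ambiguities.

**Likelihood.** The two-state model has gain rate α and loss rate β per
unit branch length, with closed-form transition probabilities and a root
prior defaulting to the stationary distribution (β, α)/(α+β) (a flat prior
can be supplied). `mlMarginal()` returns marginal posteriors by the
pruning algorithm (below-likelihoods postorder, above-likelihoods
preorder); `mlJoint()` returns the single best joint labeling by
max-product with backtracking. The `bayes` method tag thresholds the
marginal posterior at 0.5 (ties defer to the parent, producing no event);
`ml` uses the joint reconstruction — mirroring the two distinct
reconstruction flavours named in standard phylogenetics toolkits.

**Event counting.** Per branch, gains are columns with parent 0 → child 1
and losses the reverse; `net = gains − losses`. Columns with fewer than
two unmasked leaves are skipped with a warning and contribute no events.
An algebraic identity holds by construction and is asserted in tests: for
any column, the sum of (gain − loss) along a root-to-leaf path equals
leaf state minus root state.

**Limitations.** Branch lengths are required for the probabilistic
methods; rate heterogeneity across sites, 20-state models, and tree
inference are out of scope (trees are consumed as input).

## Uricase kinetics

**Chain model.** Catalysis is modelled as the sequential first-order chain
UA ⇌ UA²⁻ ⇌ PIU ⇌ HIU with forward rates k₁, k₂, k₃ and reverse rates
k₋₁, k₋₂, k₋₃ (all zero in the irreversible variant). The enzyme is not
modelled explicitly: under single-turnover, enzyme-excess conditions the
species kinetics are pseudo-first-order. Binding steps, pH dependence and
inhibitor competition are out of scope.

**Numerics.** The linear system is solved in closed form by
eigendecomposition of the 4 × 4 rate matrix. When eigenvalues nearly
coincide (relative gap below 1e-8) or the eigenvector matrix is
ill-conditioned (reciprocal condition below 1e-10), the solver falls back
to a stiff integrator (`deSolve::lsoda`, tolerances 1e-12). Mass
conservation holds to 1e-9 relative at all times and is asserted in
tests. Cumulative H₂O₂ is the integral of k₃·[PIU]: peroxide is released
at the PIU → HIU step and is *not* consumed by the reverse step, so for a
back-biased final step the H₂O₂ curve keeps rising after HIU plateaus.

**Spectra and SVD.** Absorbance follows Beer–Lambert,
A(t, λ) = Σ ε_s(λ)·c_s(t)·path, with concentrations in µM and molar
absorptivities in M⁻¹cm⁻¹. SVD sign is arbitrary, so a convention is
enforced: each spectral vector's largest-magnitude entry is made positive
(the paired temporal vector flips with it). The matrix can be analysed raw
(default) or after subtracting the final spectrum, which isolates the
time-evolving difference components; both modes are exposed because either
is defensible for stopped-flow data. Components retained default to 3 or
however many explain 99.9% of variance, whichever is smaller. The
"isolated wavelength" is where the chosen component's |loading| most
dominates the summed |loadings| of the other retained components; an
infinite ratio (all other loadings zero) is allowed, with ties broken by
the chosen component's own loading.

**Fitting.** Progress-curve and Michaelis–Menten fits use
Levenberg–Marquardt least squares with non-negativity bounds
(`minpack.lm`). The chain fit is multistarted from 8 log-spaced rate seeds
spanning 0.05–500 s⁻¹ with a fixed per-parameter stagger; the best
residual sum of squares wins. A near-singular curvature matrix (flat RSS
direction, reciprocal condition < 1e-12) sets an `identifiable = FALSE`
flag rather than failing silently — a constant trace, for example, pins
the entry rate at zero but leaves downstream rates unconstrained.
Standard errors come from the Gauss–Newton approximation
(J'J)⁻¹·RSS/(n−p). The Michaelis–Menten fit requires at least four
distinct substrate concentrations; K_M pinned at its lower bound raises a
boundary flag. The FOX standard curve is an ordinary least-squares line;
inverse prediction clips negative concentrations to zero with a flag.

**Time grids.** Acquisition times default to log spacing (dense early
sampling, no oversampling late) starting at 1–2 ms, just past a typical
stopped-flow dead time of 1.5 ms.

## Synthetic data: what it does and does not emulate

The generators provide every input with recorded ground truth, and their
defaults are the study conditions the package is tested against:

* `genOrthogroupDataset()` draws sequences residue-by-residue from
  clade/orthogroup-specific multinomials (three clades of 50 species by
  default, baseline Cys 1%), with planted fold changes, presence dropout
  and duplication. Default sequence length is 2500 residues — longer than
  a typical protein — chosen so the per-sequence sampling coefficient of
  variation of a 1% residue stays below 20%, the within-clade dispersion
  regime the recovery properties address. Real orthologs additionally
  carry phylogenetic autocorrelation, among-site composition structure and
  indels, none of which are simulated; passing tests therefore demonstrate
  the statistics under idealized dispersion, not robustness to correlated
  evolution.
* `genCharacterHistory()` evolves binary characters by exact two-state
  transition sampling per branch. Events are recorded from endpoint pairs,
  a single-change-per-branch reading; when rate × branch length exceeds
  0.5 a warning notes that multiple hits may be undercounted.
* `genStoppedFlowDataset()` composes the chain solver and the spectral
  forward model with additive Gaussian noise (default σ = 0.002 AU, a
  realistic photodiode-array noise floor). The default species spectra are
  Gaussian bands engineered to reproduce the literature landmarks of the
  uricase reaction — urate at 292 nm with ε = 12,650 M⁻¹cm⁻¹, HIU near
  301 nm, and a PIU−HIU difference spectrum with extrema at 294/314 nm —
  not measured curves. The default reversible model has fast early steps
  (complete within the dead time) and a back-biased final step
  (k₋₃ > k₃), which caps HIU at roughly a fifth of the initial urate.
  The irreversible reference model places the rate-limiting final step at
  4.11 s⁻¹ with earlier steps an order of magnitude faster.
* `genMMDataset()` applies 2% multiplicative noise to rates on a 2–140 µM
  substrate grid; `genFoxStandards()` uses the four assay standards
  10, 25, 50, 100 µM.

All generators are deterministic given a seed (byte-identical files).

## Problem sizes and test design

The test suite favours exact oracles at small size over approximate checks
at large size: parsimony against exhaustive enumeration on trees of up to
6 leaves (100 random instances), marginal posteriors against brute-force
summation on up to 4 leaves (tolerance 1e-12), the chain solver against
the Bateman closed form and an independent RK4 integrator (1e-8), the
Welch test against `stats::t.test` on 100 random tables (1e-10), and the
Michaelis–Menten optimum against a dense grid search. Simulation studies
use 10–50 replicate seeds with 15–30 orthogroups, 60–80 alignment columns
or 80–150 time points — sizes chosen so each study still exercises the
full pipeline. The permutation-null and planted-recovery checks run the
complete scan on 150-species datasets at five fixed seeds.

## Known limitations

* The composition scan tests each orthogroup × amino acid independently;
  sequences within a clade are treated as exchangeable replicates, which
  real phylogenetic structure violates.
* ACCTRAN resolution and the 0.5 posterior threshold are conventions;
  branch-event counts for genuinely ambiguous columns depend on them.
* The spectral shapes of the reaction intermediates are engineered
  landmarks; quantitative spectral claims beyond the landmark positions
  should not be read into the defaults.
* The chain fit estimates rates from a single wavelength; global
  multi-wavelength target analysis is out of scope.
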