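# uoxkit

Vertebrate urate oxidase (uricase, Uox) converts uric acid to
5-hydroxyisourate (HIU) and hydrogen peroxide. In uricotelic reptiles and
birds the gene is conserved but no longer acts in the liver: the chicken
ortholog is a cysteine-rich enzyme expressed in the skin, with a ~100-fold
reduced turnover and the unusual ability to reduce HIU back to urate.
`uoxkit` re-implements, as a tested R package, the three bespoke
computations behind that story, for molecular evolutionists and enzymologists
who want to run them on their own data or on synthetic data with known
ground truth:

1. **Orthologous composition scan** — per-sequence amino-acid content of
   orthogroups (single-copy, present in ≥ 90% of species), pairwise clade
   contrasts by Welch *t*-test and log2 fold change of mean content, and
   volcano classification at *p* < 1e-16, |log2FC| > 1. This is the scan in
   which the Uox orthogroup stands out as a unique case of cysteine
   enrichment.
2. **Ancestral cysteine gain/loss** — each alignment column is recoded as
   presence/absence of a target residue (Cys by default) and reconstructed
   on a rooted phylogeny by Fitch/MPR parsimony with a documented ACCTRAN
   tie rule, or by a two-state likelihood model (marginal posteriors via the
   pruning algorithm; joint max-product reconstruction). Per-branch gains,
   losses and net enrichment (gain − loss) are reported.
3. **Uricase kinetics** — the three-step chain
   UA ⇌ UA²⁻ ⇌ PIU ⇌ HIU (rate constants k₁, k₋₁, k₂, k₋₂, k₃, k₋₃;
   irreversible variant with all reverse rates zero), solved in closed form;
   a Beer–Lambert spectral forward model; SVD of time-resolved spectra with
   isolated-wavelength selection; progress-curve fitting with multistart
   bounded least squares; Michaelis–Menten estimation
   (v = V·S/(K_M + S), k_cat = V/[E]); and FOX-assay H₂O₂ quantification by
   linear standard curve.

A fourth module generates every input with recorded truth: clade-structured
orthogroup sequence sets with planted compositional shifts, binary character
histories evolved on trees, noisy stopped-flow spectra from known models,
initial-rate tables, and FOX standards.

## Worked example

Recover Michaelis–Menten parameters from a synthetic triplicate experiment
at the chicken-enzyme design point (K_M = 12.5 µM, k_cat = 0.03 s⁻¹,
4.1 µM enzyme, 2% noise):

```r
library(uoxkit)
d   <- genMMDataset(Km = 12.5, kcat = 0.03, enzymeConc = 4.1, cv = 0.02, seed = 1)
fit <- fitMichaelisMenten(d$data$S, d$data$v, enzymeConc = 4.1)
fit
#> Michaelis-Menten fit: Km = 12.61 uM, kcat = 0.03025 1/s (Vmax = 0.124 uM/s, [E] = 4.1 uM)
```

The fitted K_M (12.61 µM) and k_cat (0.0302 s⁻¹) recover the planted values
within about 1%.

Scan a synthetic orthogroup set in which one orthogroup carries a planted
5-fold cysteine enrichment in sauropsids:

```r
shifts <- data.frame(orthogroup_id = "OG0007", amino_acid = "C",
                     clade = "Sauropsida", fold = 5)
g    <- genOrthogroupDataset(nOrthogroups = 10, shifts = shifts, seed = 1)
comp <- computeComposition(filterOrthogroups(g$table))
diff <- classifyVolcano(differentialComposition(comp, cladeMap(g$table),
                                                c("Sauropsida", "Mammalia")))
subset(diff, volcano_class != "ns")
#>    orthogroup_id amino_acid    clade_a  clade_b   mean_a   mean_b   log2fc
#> 17        OG0007          C Sauropsida Mammalia 0.048592 0.010376 2.227468
#>         p_value n_a n_b volcano_class p_bonferroni
#> 17 1.025616e-61  50  50     increased 2.051232e-59
```

Only the planted orthogroup/residue is called: its mean cysteine content is
4.9% in the shifted clade versus 1.0% in the other (log2FC ≈ 2.2, far past
both cutoffs); all 199 other orthogroup × amino-acid rows are `ns`.

For per-branch cysteine gains and losses on a tree, see
`?binarizeAlignment`, `?ancestralStates` and `?branchEvents`; for the
kinetics pipeline, `?simulateChain`, `?svdComponents`, `?fitChainModel` and
the package vignette.

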