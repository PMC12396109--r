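# carveflux

Transcriptomic analysis ranks genes by how much their expression changes;
it says little about whether those changes matter for the cell's
metabolism. `carveflux` adds that missing dimension for anyone who has a
count table and a genome-scale metabolic model (GEM): it builds a
condition-specific metabolic model from each condition's expressed genes,
explores the achievable flux states of that model, and scores every
reaction — and, through gene–protein–reaction (GPR) rules, every gene —
by its metabolic importance. The result is a set of differential,
enrichment-ready and plot-ready gene tables in which "significant" means
*metabolically* significant.

## The method

1. **Expression filtering.** Per condition, a `filterByExpr`-style rule
   (CPM cutoff derived from `min_count = 10` against the median library
   size, in ≥ 70% of the condition's samples, total ≥ 15) turns the UMI
   count table into an expressed-gene list.

2. **Carving.** The universal model (e.g. Recon3D in SBML or COBRA JSON)
   is cut down to a context-specific submodel by a mixed-integer program
   over inclusion indicators $y_r \in \{0,1\}$:

   $$\max \sum_{s_r > 0} s_r y_r + \sum_{s_r < 0} s_r y_r
     - p_{\mathrm{nogpr}} \sum_{s_r = 0} y_r$$

   subject to steady state $Sv = 0$, $lb_r y_r \le v_r \le ub_r y_r$,
   biomass flux $\ge f_{\min} \cdot v_{\mathrm{bio}}^{\max}$, and every
   included supported reaction carrying at least $\varepsilon$ flux.
   The evidence score $s_r$ is $+1$ when the reaction's GPR evaluates
   TRUE on the expressed set, $-1$ when FALSE, $0$ when it has no GPR.

3. **Flux sampling.** The carved model's flux polytope is explored with
   an artificial-centering hit-and-run chain (global view) and a
   random-objective vertex sampler (corners/extremes). Geweke and
   Raftery–Lewis diagnostics drive the stopping rule, so each model gets
   as many samples as its solution space needs.

4. **Scoring.** For each reaction, the Reaction Cumulative Correlation
   $\mathrm{RCC}_i = \sum_j |\mathrm{corr}(v_i, v_j)|$ (range 0 to the
   reaction count) measures how strongly its flux co-varies with the
   whole network — a centrality-like essentiality score — while the
   sampled mean flux (mol·kgDW⁻¹·h⁻¹) measures its usage. Conditions
   are compared by mean-flux differences with Welch tests on strided
   samples.

5. **Gene projection and selection.** Scores propagate to genes through
   GPR membership (default: a gene inherits its most important
   reaction). Signature genes pass $|\Delta \mathrm{flux}| > 0.5$ and
   $P < 0.05$; hypergeometric over-representation and pre-ranked GSEA
   run on any GMT collection; MA-style and flux-weighted volcano tables
   are written ready to plot.

## Worked example

The package ships a self-contained fixture generator, so the whole
pipeline runs without any download: a toy universal model whose backbone
is always expressed plus one branch whose gene (`g5`) is expressed only
in condition A.

```r
library(carveflux)
fx <- two_condition_fixture(seed = 1)

expressed_A <- filter_expressed(fx$expr, "condA")
carved_A <- carve(fx$model, score_reactions(fx$model, expressed_A))
carved_B <- carve(fx$model, score_reactions(fx$model,
                                            filter_expressed(fx$expr, "condB")))
setdiff(carved_A$reactions$id, carved_B$reactions$id)
#> [1] "branch1"

resA <- sample_until_converged(remove_blocked(carved_A), sampler_config(seed = 1))
resA$report
#> <convergence_report> converged = TRUE; 5000 samples; 100.0% of reactions
#> pass |z| < 1.96; Raftery-Lewis N_min = 3864

resB <- sample_until_converged(remove_blocked(carved_B), sampler_config(seed = 2))
diff_rx <- differential_reactions(
  list(scores = reaction_scores(resA$samples), samples = resA$samples),
  list(scores = reaction_scores(resB$samples), samples = resB$samples))
diff_rx
#>   reaction delta_mean_flux       p_value  delta_rcc in_model_a in_model_b
#> 1      bio        1.659476  8.799845e-40 -1.4917705       TRUE       TRUE
#> 2  branch1        3.303841 5.027544e-245  4.4917386       TRUE      FALSE
#> ...

genes <- project_scores(diff_rx, gene_reaction_map(fx$model))
select_signature_genes(genes)
#> [1] "g5"
```

The carved models differ exactly by the planted branch; the branch
reaction carries ≈ 3.3 more flux in condition A (it splits the uptake
with the backbone, so ≈ 10/3 on average, versus 0 when absent); and the
signature selection recovers exactly the branch gene.

The same run is available end-to-end via `run_pipeline()` (R) or the
CLI (`inst/cli/carveflux run --config config.json`), which writes a
report directory with models (SBML + JSON), sample matrices, score
tables, enrichment results, MA/volcano tables and a checksummed
manifest.

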