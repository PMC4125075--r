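# phenosig

Phenotypic signatures from unbalanced bacterial growth curves.

Bacteria in batch culture grow in a continuously changing environment of
their own making: as the substrate is consumed, the specific growth rate
μ(t) = (1/OD)·dOD/dt fluctuates instead of holding a clean exponential
plateau. Those fluctuations are not noise — they encode the coupling
between the strain's regulatory network and the nutrient it depletes.
`phenosig` turns them into quantitative phenotypes and uses them three
ways:

* **Strain and condition classification.** OD curves from a plate reader
  (10-minute sampling) are denoised (db4 wavelet, universal soft
  threshold), differentiated to specific growth rates, and transformed
  into a time–period map of wavelet coefficient magnitudes (a
  scaleogram). The coefficient row at the most informative period —
  selected by minimizing the Davies–Bouldin cluster-quality index
  DB = (1/K)·Σᵢ maxⱼ (Sᵢ+Sⱼ)/Mᵢⱼ — is the strain's signature vector,
  clustered by average-linkage hierarchical clustering. A leave-one-out
  analysis scores robustness; concatenating ("multiplexing") one
  strain's series across perturbation conditions sharpens hard pairs.
* **Why cell-coupled inputs help: simulation studies.** For random
  three-node linear models, local parameter identifiability is scored
  from the correlation matrix R of transfer-function sensitivities
  H·ⱼ = ∂g(iω)/∂kⱼ (a parameter is identifiable when no |R_ij| ≥ 0.99);
  for random nonlinear models, a deliberately simple regression estimator
  ẏ = Ay with edge rule |A_ij| > 0.005 is scored by the fraction n/m of
  true influences recovered. Both studies contrast a constant input flux
  with a consumable, cell-coupled nutrient on the same networks.
* **Reverse engineering growth dynamics.** A three-variable growth ODE
  (nutrient N, machinery pool P, burden pool Q, growth modulator G with
  μ = G) reproduces sigmoidal batch curves and the qualitative phenotypes
  of plasmid load (k₄ → 1.2: lower peak μ, unchanged stationary entry)
  and low temperature (all kᵢ × 0.7: lower peak μ, delayed entry). A
  particle-swarm algorithm fits its parameters to growth-rate data and
  searches over structures assembled from a 12-component equation
  library (power-law, mass-action and Michaelis–Menten terms).

A seeded synthetic-data module (`make_strain_panel()`,
`make_expression_dataset()`) generates every input class, so all results
are reproducible without laboratory data. The methods vignette
(`vignettes/phenotypic-signatures.Rmd`) documents the models,
conventions and design decisions.

## Worked example

Classify a synthetic panel of 4 strains × 3 replicate wells:

```r
library(phenosig)

panel <- make_strain_panel(strain_panel_spec(conditions = "control"), seed = 1)
panel[[1]]
#> <growth_curve> S1 / control (well W001): 85 points, 0.00-14.00 h, dt = 0.1667 h

res <- classify_panel(panel)
res$period          # most informative wavelet period (h)
#> [1] 13.67
res$n_misclassified # permutation-minimal errors vs true strain labels
#> [1] 0

classify_panel(panel, use_raw = TRUE)$n_misclassified  # raw growth-rate vectors
#> [1] 2

bootstrap_misclassification(res$features, res$true_strains)$histogram
#>  0
#> 12
```

The wavelet signatures classify all 12 wells correctly and stay perfect
in every leave-one-out replicate; clustering the raw growth-rate vectors
of the same panel misplaces 2 wells. The growth model behind the panel:

```r
simulate_growth(growth_model())
#> <growth_sim> 241 points to 40.0 h; max mu 0.608 1/h; stationary entry 9.83 h
```

The simulation studies run through `compare_input_modes()` (parameter
identifiability) and `compare_ensembles()` (network-inference accuracy),
and the swarm machinery through `swarm_fit_params()` /
`swarm_search_structure()`. A thin command-line front end wrapping these
workflows is installed at `inst/cli/phenosig.R`
(subcommands `signatures`, `simstudy`, `swarm`, `synth`, `growthmodel`).

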