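# metawebsim

Spatial eco-evolutionary simulation of trophic meta-communities, for
computational ecologists studying how co-evolved food webs respond to
perturbation: species loss, whole-network invasion, habitat destruction,
and nature-reserve placement.

Communities assemble on a lattice of habitat patches (6×6 by default,
von-Neumann adjacency) from a single founder species and one unique
resource per patch. Species are sets of 10 discrete traits from a pool of
500 plus a continuous bodysize *s*. An antisymmetric trait-pair score
matrix β determines feeding scores

    S_ij = max(0, Σ_mn β_{i_m, j_n}) · b1 · exp(−(ln s_i − ln s_j − 3)² / b2)

(a Gaussian feeding window optimal on prey three log-units smaller), and
similarity controls competition, α_ik ∈ [0.6, 0.866]. Each ecological
time step iterates an adaptive-foraging fixed point with a
ratio-dependent functional response, applies one Euler step of allometric
population dynamics (mortality −2s^−1/4, feeding gain with efficiency
λ = 0.3, predation loss), and disperses declining populations to
neighbouring patches (up to 3% · s/s₀ of a local population per step).
Evolution interleaves ecology with trait-mutation speciation events.
On top of the simulator sits a perturbation laboratory: single-species
deletion with secondary-extinction counts, deletion-then-reintroduction
invasion experiments with random-species baselines, pulse/press patch
disruption with elimination or displacement of residents, and sequential
disruption campaigns under configurable reserve schemes. Community
descriptors (shortest-chain trophic levels, connectance, omnivory,
species ranges, species–area power laws, extinction-event-size fits) are
emitted as tidy tables.

## Worked example

A deterministic three-species chain (resource → herbivore A → predator B)
relaxed to its ecological equilibrium, measured, and perturbed:

```r
library(metawebsim)
st <- run_ecology(make_fixture("single-patch-chain"), 300, log = FALSE)
summary(st)
#> 1 live patches, global diversity 3 (2 consumers + 1 resources)
#> total consumer population 626.7, bodysizes 20.1-403
#> evolutionary step 0, ecological step 300

patch_metrics(st)[, c("local_diversity", "link_density", "connectance",
                      "avg_sctl", "max_sctl")]
#>     local_diversity link_density connectance avg_sctl max_sctl
#> row               3        0.667       0.222      1.5        2

delete_species(st, 2, relax_steps = 150)
#> species-delete perturbation of 2
#>   global diversity 3 -> 1; 1 secondary extinctions (1.0000 relative)
```

The chain realizes 2 links over 3 species (connectance 2/9 ≈ 0.222,
levels 0/1/2); deleting the herbivore starves the predator — one
secondary extinction — while the source state is left bit-identical.

A scaled-down assembly (3×3 lattice, 200 evolutionary × 20 ecological ×
50 foraging steps, ~13 s):

```r
cfg <- assembly_config(evo_steps = 200, eco_steps_per_evo = 20,
                       rows = 3, cols = 3, seed = 1)
st <- assemble(cfg, model_params(foraging_iters_per_eco = 50))
summary(st)
#> 9 live patches, global diversity 12 (3 consumers + 9 resources)
#> total consumer population 5.274e+04, bodysizes 3.85-4.52
sar <- species_area_curve(st)
sprintf("z = %.3f (R2 = %.3f)", sar$z, sar$r_squared)
#> "z = 0.772 (R2 = 0.995)"
```

Three consumer lineages persist; the dominant one spans all nine patches
(range 9, population ≈ 5.3e4) and the species–area exponent is already
steep, as expected when every patch carries a unique resource. See
`vignettes/metacommunity-model.Rmd` for the model's assumptions, the
full parameter table, and what desk-scale runs do and do not reproduce.

A command-line wrapper covering `assemble`, `metrics`, `perturb`,
`sequence`, `plan`, and `fixture` is installed at
`system.file("cli", "metawebsim", package = "metawebsim")`.

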