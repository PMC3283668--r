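# firecoex

Spatio-temporal simulation of fire-driven coexistence among three
competing savanna grasses from different fire functional groups: an
**obligate seeder** (killed by fire, regenerates from post-fire seed
germination, senesces at 4 years), an **obligate resprouter** (survives
fire, spreads clonally, sets virtually no seed) and a **facultative
resprouter** (adults survive fire but population growth requires post-fire
seedling recruitment). Because each group exploits a different slice of
the spatio-temporal opportunity structure that fire creates, only a narrow
band of fire regimes lets all three persist together — and locating that
band identifies the fire regime the community is adapted to.

## The model in one paragraph

A 16 × 16 lattice of 1-ha patches (3906 adults each, 10⁶ total) holds
stage-structured populations projected each generation with Lefkovitch
matrices, `n(t+1) = A n(t)`, then modified by three stochastic spatial
processes: **fire** — aligned `s × s` ignition blocks burn with
probability *f* per generation, thinned per cell by a fuel-memory
(refractory) modifier of 0.3 for cells burnt the previous generation, so a
single cell burns at the stationary rate π = *f* / (1 + 0.7 *f*) and its
time-since-fire follows the refractory-thinned geometric
P(t) = π (1 − 0.3 *f*)(1 − *f*)^(t−1); **dispersal** — seed reproducers
shed 90 % of each crop into a fire-gated local pool and scatter 10 %
uniformly over the landscape (germinating on arrival, no fire needed),
while the clonal resprouter invades only its four orthogonal neighbours at
rate N/K; and **competition** — a survival lottery that resolves any
over-capacity patch by a multinomial draw of size K with probabilities
proportional to expected adult counts. Sweeping *f* ∈ {0, 0.1, …, 1} and
scale ∈ {1, 2, 4, 8, 16} in single-species, pairwise and full-community
configurations yields persistence envelopes per functional group and a
Shannon–Wiener coexistence surface over patches holding all species.

## Worked example

```r
library(firecoex)

reg <- fire_regime(0.2, scale = 1)
stationary_burn_fraction(reg)
#> [1] 0.1754386
round(age_distribution_analytic(reg, max_age = 5), 4)
#>      0      1      2      3      4    >=5
#> 0.1754 0.1649 0.1319 0.1055 0.0844 0.3377

pool <- lapply(c("T_bitextura", "T_epactia", "Triodia_sp"), default_species)
run_sim(sim_config(pool, reg, seed = 7))
#> <fc_run> p = 0.2 scale = 1 | record-window means:
#>   T_bitextura  pop   786844.4  occupancy 1.000
#>   T_epactia    pop        0.0  occupancy 0.000
#>   Triodia_sp   pop    98842.2  occupancy 0.827
```

At fire probability 0.2, one cell in 5.7 burns per generation but some
patches stay unburnt for 20+ years (the `>=5` tail above holds a third of
the mass). In this 200-generation three-species run the resprouter
dominates, the seeder holds ~83 % of patches, and the facultative
resprouter — whose recruitment window needs fires roughly every 2–3
years — has dropped out: its robust persistence starts one grid step
higher, which is also where the model's three-way diversity ridge sits
(see the methods vignette for why that is one step above the published
surface, and what that says about the competition model).

Regime sweeps and the coexistence analysis:

```r
sw <- sweep_sim(pool, fire_probs = round(seq(0, 1, 0.1), 10),
                scales = c(1, 4, 16), configurations = "all",
                replicates = 5, seed = 1)
r <- ridge_location(diversity_surface(sw))
r$pooled_argmax      # fire probability with maximal pooled diversity
```

A command-line front end is installed with the package:

```sh
Rscript exec/firecoex simulate --species T_epactia --fire-prob 0.4 --scale 16 --seed 1 --out run.csv
Rscript exec/firecoex sweep --configurations single --replicates 5 --seed 1 --out sweep_dir
Rscript exec/firecoex age-hist --fire-prob 0.2 --generations 500 --seed 1 --out ages.csv
```

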