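# bioturb

Reaction-transport modelling and community analysis of bioturbated
intertidal sediments.

## The problem

Intertidal sands are reshaped by two competing forces: tidal hydrodynamics,
which flush porewater and stir particles near the sediment–water interface,
and burrowing macrofauna — here the Pacific lugworm *Abarenicola pacifica* —
which irrigate burrows at depth and selectively ingest fine particles.
Separating the two requires a transport model in which each has its own
mathematical signature, plus the statistics to connect the resulting
geochemical zonation to microbial community structure. `bioturb` is aimed at
sediment biogeochemists and microbial ecologists who want that full chain in
one tested package.

## What it computes

**Forward models.** A 1-D finite-volume porewater model

&nbsp;&nbsp;&nbsp;&nbsp;∂(φC)/∂t = ∂ₓ(φ Dₛ ∂ₓC) + φ·[α_P(x) + α_B(x)]·(C_ow − C) + φ(P − kC)

where physical flushing α_P(x) = a_P·e^(−x/L_P) and bioirrigation α_B(x)
(a window over the lugworms' living depth) enter as *nonlocal exchange*
terms that swap porewater directly with overlying water; and a solid-phase
pigment model in which chlorophyll a decays to pheopigment while being mixed
by physical (D_P) and biological (D_B) biodiffusion. Backward-Euler time
stepping with a compiled tridiagonal core; conservative to < 1e-8 over 10⁴
steps; second-order in space.

**Inversion.** `fit_physical_porewater()` calibrates (a_P, L_P) on the
defaunated treatment (physics only), `fit_bioirrigation()` then fixes
α_P and fits the bioirrigation window (a_B, z₁, z₂) on the refaunated
treatment; `fit_particle_mixing()` does the same two-stage attribution for
D_P and D_B from pigment profiles. Weighted least squares under the
multiplicative error model, seeded Latin-hypercube multistart Nelder–Mead.
`feeding_intensity()` computes F_B = f_sand − f′_sand, the grain-size proxy
for selective feeding.

**Indices.** Pigment freshness chl a/(chl a + pheopigments), domain rRNA
gene ratios (BAR/EAR/EBR), functional-gene percentages of the 16S pool,
sediment zonation (PBL 0–12.5 cm / BL 12.5–25 cm / UL > 25 cm in bioturbated
sediment; PL / UL in controls), and Welch's t comparisons.

**Community statistics**, written from first principles and cross-checked
against vegan / ape / phyloseq in the tests: rarefaction and observed ZOTU
richness, weighted and unweighted UniFrac, PCoA, PERMANOVA (999
permutations), and CAP constrained ordination with marginal permutation
pre-filtering of environmental variables.

**Networks.** Class-level Spearman co-occurrence networks (mid-rank Pearson,
p < 0.05 masks, average-linkage cluster extraction) and interdomain
cluster–cluster distance correlations (dcor) with a 999-permutation test.

**Synthetic data.** `scenario_config()`, `generate_geochem()`,
`generate_pigments_grainsize()`, `community_scenario()` and
`generate_community()` emulate the whole study design — two treatments,
0–40 cm depth, four sampling dates, a depleted biologically impacted layer,
surface/subsurface lineage turnover and planted correlation clusters — so
every stage runs end-to-end without any field data, and estimates can be
scored against known truth (`recovery_study()`).

## Worked example

Generate a synthetic manipulation experiment (known truth: a_P = 0.4/day,
L_P = 4 cm, bioirrigation a_B = 0.25/day on 10–20 cm, 5% measurement
noise), then recover the mixing parameters:

```r
library(bioturb)
cfg <- scenario_config(seed = 1)
geo <- generate_geochem(cfg)
inv <- inversion_config_from_scenario(cfg)
obs <- subset(geo$observations, time_point %in% c("T1", "T2"))

fit_p <- fit_physical_porewater(subset(obs, treatment == "defaunated"), inv)
fit_b <- fit_bioirrigation(subset(obs, treatment == "refaunated"), fit_p, inv)
print(fit_p)
#> fit_result: a_P = 0.3943, L_P = 3.943 
#>   loss = 0.189246, converged = TRUE, evaluations = 1023
print(fit_b)
#> fit_result: a_B = 0.2555, z1 = 9.995, z2 = 20.06 
#>   loss = 0.187642, converged = TRUE, evaluations = 3404
```

The defaunated plot pins physical flushing to the top few cm (a_P within a
few percent of truth); the refaunated increment is attributed to a
bioirrigation window whose edges land within a cell width of the planted
10–20 cm living depth.

Community side — rarefy, compute weighted UniFrac, and test the zonation:

```r
com <- generate_community(community_scenario(), cfg)
tab <- rarefy(com$tables$bac16S, depth = 5000, seed = 1)
d <- unifrac(tab, com$trees$bac16S)
permanova(d, tab$metadata$zone, seed = 1)
#> PERMANOVA: pseudo-F = 28.83, R2 = 0.5599, p = 0.001 (999 permutations)
```

Roughly half the community variation is structured by sediment zone, and no
label permutation reaches the observed pseudo-F (p at the 1/1000 floor) —
the planted surface/subsurface turnover and BL depletion are clearly
detected.

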