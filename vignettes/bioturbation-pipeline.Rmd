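---
title: "Modelling lugworm bioturbation: transport, inversion and community structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lugworm bioturbation: transport, inversion and community structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioturb)
```

## The scientific problem

Intertidal sands are disturbed by two competing agents: tidal hydrodynamics,
which flush porewater and mix particles near the sediment–water interface,
and burrowing macrofauna such as the Pacific lugworm *Abarenicola pacifica*,
which irrigate their burrows and selectively ingest fine particles at depth.
`bioturb` implements a desk-scale version of the full analysis chain used to
separate these two agents: forward reaction-transport models, inversion of
mixing parameters from paired manipulation plots, the derived geochemical
indices, and community-structure statistics for the accompanying amplicon
and qPCR data. A seeded synthetic-data generator stands in for field data, so
every stage of the pipeline can be exercised and scored against known truth.

## The porewater model

Porewater solutes (DIC, sulfate, and any analyte with a free-solution
diffusivity) obey a one-dimensional early-diagenesis equation on the depth
coordinate $x$ (cm, positive downward):

$$\frac{\partial (\phi C)}{\partial t} =
  \frac{\partial}{\partial x}\!\left(\phi D_s \frac{\partial C}{\partial x}\right)
  + \phi\,[\alpha_P(x) + \alpha_B(x)]\,(C_{ow} - C) + \phi\,(P - kC),$$

where $\phi$ is porosity, $D_s = D_0/(1 - 2\ln\phi)$ is the
tortuosity-corrected diffusivity (the standard correction for sands),
$C_{ow}$ is the overlying-water concentration, and the bracketed *nonlocal
exchange* term moves porewater directly between depth $x$ and the overlying
water — the canonical representation of both tidal flushing
($\alpha_P$) and burrow irrigation ($\alpha_B$), which bypass the
intervening sediment. $P$ and $k$ are optional constant-production and
first-order-decay hooks, disabled by default; they exist so that reaction
effects can be switched on for sensitivity runs and so that the solver can
be checked against diffusion–decay closed forms.

Functional forms follow the qualitative depth structure of the system:
physical exchange decays exponentially from the interface,
$\alpha_P(x) = a_P e^{-x/L_P}$, while bioirrigation is a constant window
$\alpha_B(x) = a_B$ on $[z_1, z_2]$ with half-cosine edges (default ramp
2 cm) covering the lugworms' living depth. The same two shapes are reused
for the particle-mixing coefficients $D_P(x)$ (exponential) and $D_B(x)$
(window).

Solid-phase pigments obey the coupled pair

$$\frac{\partial \mathrm{Chl}}{\partial t} =
  \frac{\partial}{\partial x}\!\left([D_P + D_B]\frac{\partial \mathrm{Chl}}{\partial x}\right)
  - k_{chl}\,\mathrm{Chl}, \qquad
  \frac{\partial \mathrm{Pheo}}{\partial t} =
  \frac{\partial}{\partial x}\!\left([D_P + D_B]\frac{\partial \mathrm{Pheo}}{\partial x}\right)
  + y\,k_{chl}\,\mathrm{Chl} - k_{pheo}\,\mathrm{Pheo},$$

with a prescribed chlorophyll-a deposition flux at the interface. By default
the degradation chain assumes full conversion ($y = 1$) and slow pheopigment
loss ($k_{pheo} = k_{chl}/10$); both are explicit parameters because the
literature does not pin them down.

### Numerical scheme

The solver is a conservative finite-volume discretization on uniform cells
(default 0.5 cm over 40 cm) with backward-Euler time stepping, implicit in
diffusion, exchange and decay, so it is unconditionally stable; the default
step obeys $\text{rate} \times \Delta t \le 0.1$ for the fastest linear
rate. Chlorophyll is advanced first and its fresh value feeds the
pheopigment source within the same step, which preserves stability without
splitting error in the conservation audits. Dirichlet boundaries use a
second-order one-sided gradient $(9C_1 - C_2 - 8C_{bc})/(3h)$, which keeps
the observed spatial convergence order at ~2 (the tests require $\ge 1.8$);
boundary options cover fixed-concentration, no-flux and prescribed-flux
cases, and a direct tridiagonal solve gives exact steady states. The
tridiagonal marches run in compiled code (Rcpp); with no-flux boundaries and
no reactions, depth-integrated mass drifts by less than $10^{-8}$ relative
over $10^4$ steps.

Burial/advection is neglected: the experiments span weeks, over which
sedimentation in these sands is negligible.

## Inversion: attributing mixing to physics vs fauna

The attribution logic mirrors the paired-plot design: the *defaunated*
treatment experiences only physical mixing, so its DIC and sulfate profiles
constrain $(a_P, L_P)$; the *refaunated* treatment adds lugworms at natural
density, and with $\alpha_P(x)$ frozen at the defaunated estimate its
profiles constrain the bioirrigation window $(a_B, z_1, z_2)$. Particle
mixing is fitted the same way from steady pigment profiles: nonbioturbated
sediment gives $(d_P, L_{DP})$, bioturbated sediment then gives
$(d_B, w_1, w_2)$.

The loss is weighted least squares with inverse-variance weights under
each analyte's multiplicative (log-normal) error model — the error sd of a
concentration measurement scales with its value, so observations are
weighted by $1/\text{value}^2$ (floored at 1% of the analyte mean) — with
model values linearly interpolated from cell centers to observation
depths. This weighting matters: flat per-analyte weights roughly double
the sampling scatter of the physical-exchange amplitude because the
information-rich small concentrations near the flushed interface are then
under-weighted relative to the noisy large ones at depth. Porewater fits are transient from a uniform initial
condition (the plots were sieved and homogenized, erasing any gradient) and
use only the first two sampling dates, matching the design in which later
dates were compromised; pigment fits use the steady model because pigment
profiles integrate over seasons rather than weeks. The optimizer is a
bounded derivative-free search: Nelder–Mead on logit-transformed
coordinates from eight seeded Latin-hypercube starts, best loss winning
with a lexicographic tie-break, plus one polish restart. Identical data and
seed give identical fits.

Choices a user may want to revisit:

* **Bounds** (`inversion_config()`): amplitudes in $[0, 5]$ /day
  (diffusivities $[0, 10]$ cm²/day), length scales $[0.5, 15]$ cm, window
  edges inside the column. The zero lower bound matters: fitting data with
  no biological signal drives $a_B$ (or $d_B$) to it, so the nested-model
  property — adding a biological term never worsens the fit — holds to
  optimizer tolerance.
* **No formal uncertainty quantification**: the package instead ships a
  simulation-study harness (`recovery_study()`) that regenerates noisy
  synthetic data and reports true-vs-estimated tables. Under the default 5%
  multiplicative noise with 2 dates × 15 depths, the bioirrigation amplitude
  $a_B$ and particle-mixing amplitude $d_B$ are recovered within ±20–25% in
  essentially all replicates; the physical amplitude $a_P$ sits on an
  intrinsic trade-off ridge with its length scale $L_P$ and is recovered
  within ±20% in roughly 90% of replicates — the weighted-least-squares
  estimator attains the Cramér–Rao bound for this design (CV ≈ 11%), so
  that scatter reflects the information content of the data, not the
  fitting machinery.

Feeding intensity needs no model at all: $F_B(x)$ is the difference in sand
volume fraction between bioturbated and control profiles (control linearly
interpolated to the bioturbated depths), positive where worm feeding has
enriched coarse grains.

## Indices

* **Freshness index** chl a / (chl a + pheopigments): 1 = fresh algal
  pigment, 0 = fully degraded; undefined (NA) when both are zero.
* **Domain ratios** BAR = bac16S/arc16S, EAR = euk18S/arc16S,
  EBR = euk18S/bac16S, computed on linear copy numbers (log display is a
  plotting choice). The Eukarya-in-the-numerator orientation follows the
  ratio names (EAR/EBR); the source literature is internally inconsistent
  on this point, so the orientation is documented rather than guessed at
  twice.
* **Functional fractions** 100 × gene/(bac16S + arc16S) for dsrB, soxB,
  narG, amoA; values above 100% are flagged as implausible rather than
  clipped.
* **Zonation**: bioturbated columns split at 12.5 and 25 cm into PBL / BL /
  UL; nonbioturbated at 12.5 cm into PL / UL. Boundaries are half-open and
  lower-inclusive (a sample at exactly 12.5 cm is BL), consistent with the
  "> 25 cm" phrasing of the deepest zone.
* **Welch's t** (unequal variances, Satterthwaite df) is the two-group test
  used throughout; no multiple-testing correction is applied, and the
  number of tests is the caller's to report.

## Community statistics

These are written from first principles (the installed vegan, ape and
phyloseq implementations serve as independent cross-checks in the test
suite, never as the implementation):

* **Rarefaction** draws exactly `depth` reads per sample without
  replacement (default depth: 90% of the smallest sample total); richness
  is observed ZOTU count. Mean rarefied richness matches the closed-form
  hypergeometric expectation in the tests. Richness is computed on a single
  seeded draw by default, with replicate averaging available by looping
  seeds — the single-draw default is stated rather than hidden.
* **UniFrac**: weighted-normalized
  $\sum_i b_i |A_i - B_i| / \sum_i b_i (A_i + B_i)$ over tree branches
  (raw variant by flag), unweighted
  $\sum b_i \mathrm{XOR} / \sum b_i \mathrm{OR}$ on presence.
* **PCoA**: eigendecomposition of the double-centered Gower matrix;
  negative eigenvalues are reported, excluded from variance proportions,
  and a Lingoes correction is available by flag (off by default).
* **PERMANOVA**: pseudo-F from the among/within partition of squared
  distances, free label permutation (999 by default, no strata),
  $p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$.
* **CAP**: PCoA axes covering ≥ 95% of positive-eigenvalue variance
  (user-overridable) are regressed on the standardized environment matrix;
  the fitted values are rotated to canonical axes, and the explained
  proportion is fitted variance over total positive-eigenvalue inertia.
  Variables enter only if a marginal permutation test keeps them at
  p < 0.05, mirroring the practice of showing only significant drivers.

## Networks

Class-level co-occurrence uses Spearman correlations (Pearson on mid-ranks)
across all samples and time points, two-sided p-values from the
t-approximation for n ≥ 10 (exact permutation enumeration below that), and
an edge mask at p < 0.05 without correction (the test count is reported).
Clusters come from average-linkage hierarchical clustering on $1 - \rho$;
the automatic cut maximizes mean within-cluster minus mean between-cluster
correlation over k ∈ 2..8, and k can be fixed by hand. Interdomain
cluster–cluster dependence uses the distance correlation (dcor) of the two
member-class abundance blocks. Significance uses 999 permutations of the
sample rows of the second block — the "999 bootstraps" of common usage is
implemented as a permutation null because permutation, not the bootstrap,
gives a valid test of independence; the unsigned dcor is accompanied by the
sign of the Pearson correlation of the cluster aggregates for
"positively/negatively correlated" reporting.

## The synthetic-data generator

`scenario_config()` fixes the study conditions: a 40 cm column at porosity
0.4; DIC (overlying water 2.1 mM, homogenized start 7 mM) and sulfate
(28 / 22 mM) profiles at 2 cm spacing over 0–30 cm; sampling at days 4, 18,
26 and 37 with porewater calibration on the first two; true mixing
$a_P = 0.4$ /day, $L_P = 4$ cm, $a_B = 0.25$ /day on 10–20 cm,
$d_P = 0.8$ cm²/day, $d_B = 0.15$ cm²/day on 12.5–25 cm; chlorophyll decay
0.02 /day with a 0.002 /day pheopigment loss; a +0.2 sand-fraction bump on
15–25 cm; 5% multiplicative log-normal noise on concentrations, additive
Gaussian (sd 0.02, clipped to [0,1]) on sand fractions. These values are
choices of a plausible sandy-intertidal regime — surface-concentrated
physical exchange, decimeter-deep irrigation, order-of-magnitude realistic
diffusivities — not reconstructions of any measured site.

`community_scenario()` plants the community structure the analyses are
meant to detect: per domain (bacteria 16 classes × 6 ZOTUs, archaea 8 × 5,
eukaryotes 10 × 5) classes belong to "surface" clusters (logistic decline
with depth) or "subsurface" clusters (the reverse), classes in a cluster
share a log-normal latent factor calibrated so the within-cluster
correlation is ~0.8, reads are multinomial at 8–12k per sample, and the
bioturbated BL (12.5–25 cm) is depleted ~2 orders of magnitude in
prokaryotic and ~1 order in eukaryotic gene copies with 35% of lineages
suppressed (the richness signal). Trees are random coalescents — UniFrac
needs a valid tree, not a realistic one.

What the generator does *not* emulate — and therefore what green tests do
not certify about field data: compositional sequencing artefacts and PCR
bias, overdispersion beyond the log-normal–multinomial mechanism, real
phylogenetic signal in the tree, spatial autocorrelation between adjacent
depths beyond the smooth response curves, and any reactive-transport
feedback between chemistry and community.

## Problem sizes and runtime

The shipped tests and the acceptance script use the study-default sizes:
80–320 cell grids, 50-replicate recovery studies, 200-replicate null
calibrations at 999 permutations, 2000 Welch replicates, 10⁴ rarefaction
draws, and 72-sample three-domain communities. On a single CPU the full
suite completes in minutes; the forward model's compiled tridiagonal core
is what keeps the 50 × (2 + 3)-parameter inversion study cheap.

## Known limitations

* One spatial dimension: no burrow-resolving geometry, no tidal-cycle
  forcing, no temperature dependence.
* The inversion reports point estimates plus a simulation-study bias/spread
  harness, not posterior uncertainty.
* Networks use plain Spearman on relative abundances; compositionality
  corrections (SparCC-style) are deliberately out of scope.
* The window parameterizations of $\alpha_B$ and $D_B$ are the simplest
  shapes consistent with a confined living depth; real irrigation profiles
  can be multi-modal.

## A worked mini-example

```{r example, eval = FALSE}
cfg <- scenario_config(seed = 1)
geo <- generate_geochem(cfg)
inv <- inversion_config_from_scenario(cfg)
obs <- subset(geo$observations, time_point %in% c("T1", "T2"))
fit_p <- fit_physical_porewater(subset(obs, treatment == "defaunated"), inv)
fit_b <- fit_bioirrigation(subset(obs, treatment == "refaunated"), fit_p, inv)
fit_p$parameters   # a_P, L_P  (truth: 0.4 /day, 4 cm)
fit_b$parameters   # a_B, z1, z2  (truth: 0.25 /day on 10-20 cm)

com <- generate_community(community_scenario(), cfg)
tab <- rarefy(com$tables$bac16S, depth = 5000, seed = 1)
d <- unifrac(tab, com$trees$bac16S)
permanova(d, tab$metadata$zone, seed = 1)
```
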