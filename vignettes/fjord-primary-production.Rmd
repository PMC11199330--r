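---
title: "Methods: carbon-14 primary production in glacier-influenced fjords"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon-14 primary production in glacier-influenced fjords}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fjordpp)
```

## The measurement and its model

Phytoplankton primary production in the water column is measured by the
carbon-14 light/dark bottle method: subsamples from discrete depths are
inoculated with labelled bicarbonate, incubated in situ in transparent and
darkened bottles, and the fixed tracer is counted by liquid scintillation
(activities in dpm). The volumetric carbon fixation rate at depth $z$ is

$$
P_e(z) = \frac{\langle \mathrm{dpm}_a(z)\rangle \cdot \mathrm{totalCO_2}
  \cdot 13.356 \cdot k_1 k_2 k_3}{\mathrm{dpm}_b}
  \quad [\mathrm{mgC\,m^{-3}\,h^{-1}}]
$$

where $\langle \mathrm{dpm}_a(z)\rangle$ is the mean light-minus-dark
activity, $\mathrm{dpm}_b$ the inoculated tracer activity, and
$13.356 = 12 \times 1.05 \times 1.06$ combines the atomic weight of carbon
with the isotope-discrimination (heavy-tracer uptake 5% slower) and
respiration (6% of new organic matter respired) corrections
(`composite_constant()`). $k_1$ corrects for subsampling (default 1 — field
protocols rarely print it, so it is explicit configuration), $k_2$ converts
the per-incubation uptake to an hourly rate ($1/\text{exposure hours}$; 0.5
for a two-hour exposure) and $k_3 = 10^3$ converts
$\mathrm{mgC\,dm^{-3}}$ to $\mathrm{mgC\,m^{-3}}$.

Daily areal production is the trapezoid of $P_e$ over the top 30 m,

$$
P_i = d \int_0^{30} P_e(z)\, dz \quad [\mathrm{mgC\,m^{-2}\,day^{-1}}],
$$

with $d$ the day factor in hours per day.

### Replicate pairing and negative rates

With equal replicate counts the mean of pairwise light-minus-dark
differences is used; with unequal counts, the difference of replicate means.
The two have identical expectation; fixing the convention makes results
deterministic. A dark bottle occasionally out-counts its light partner at
depth — that is measurement noise, so negative rates are clamped to zero
with the raw value and a flag retained (`pe_clamped`).

### The day factor is explicit configuration

Converting hourly profiles to daily integrals requires an hours-per-day
factor that field reports often leave implicit; it is the single largest
unstated scale in the workflow. The default is 24 h/day — the polar day of
high-Arctic midsummer (77–79° N in July–August) — with 12 h/day (a
06:00–18:00 daytime exposure window) the documented alternative
(`integrate_pi(..., day_factor = )`). All integrated values should be read
alongside the factor used; it is recorded in the pipeline provenance.

## Total CO2 from temperature, salinity and pH

The tracer dilution requires the total inorganic carbon of the sample.
Following the classical shipboard approach, carbonate alkalinity is
estimated from salinity, $CA = 0.068\,S$ meq L$^{-1}$ (the specific
alkalinity factor is configurable), and partitioned with apparent
dissociation constants $K_1', K_2'$ evaluated at in-situ $(T, S)$:
with $h = 10^{-\mathrm{pH}}$,

$$
[\mathrm{HCO_3^-}] = \frac{CA}{1 + 2K_2'/h}, \qquad
\mathrm{totalCO_2} = [\mathrm{HCO_3^-}]
 \left(\frac{h}{K_1'} + 1 + \frac{K_2'}{h}\right).
$$

The default constant set is the Mehrbach constants as refit by Dickson and
Millero (1987); the set name is carried in the output because different fits
shift total CO2 by a few percent. The routine is deliberately minimal — no
borate or phosphate alkalinity, no pCO2 or saturation states — matching
what the production equation needs. Guards: salinity must be positive
(alkalinity is salinity-derived) and pH must lie in [6, 9]. The test suite
cross-checks the routine against an independently coded solver (Lueker
et al. 2000 constants, numeric inversion of the alkalinity speciation),
requiring agreement within 5% over $T \in [-1, 10]$ °C, $S \in [28, 35]$,
pH $\in [7.8, 8.3]$. Because the alkalinity factor, constant set and $k_1$
are not printed by typical campaign reports, outputs carry this provenance
rather than claiming bit-compatibility with any particular study.

## Chlorophyll-a from extract absorbances

Chlorophyll-a is determined spectrophotometrically from pigment extracts
using the monochromatic form with a turbidity blank at 750 nm:

$$
C_a = \frac{10^6 (A_{665} - A_{750})\, v}{a \cdot l \cdot V \cdot 10^3}
 \quad [\mathrm{mg\,m^{-3}}]
$$

with extract volume $v$ (mL), filtered volume $V$ (L), cuvette path $l$
(cm) and specific absorption coefficient $a$. Campaigns that extract in 96%
ethanol while citing acetone-based equation families leave the exact
coefficient ambiguous, so the equation family and coefficient are explicit
configuration with documented defaults (ethanol 96%: 83.4 L g$^{-1}$
cm$^{-1}$; acetone 90%: 87.67). No phaeopigment (acidification) correction
is applied. Negative corrected absorbances clamp to zero with a flag.

## Water-mass classification

Observations are classified in temperature–salinity space by rectangular
boxes evaluated in priority order (first match wins; no match is
`Unclassified`). Surface water (SW) — the meltwater-influenced class — is
defined exactly as $S < 34.00$ and $T > 1$ °C with strict inequalities and
top priority, so no other box can shadow it. The remaining boxes (Atlantic
Water, Transformed Atlantic Water, Intermediate Water, Arctic Water, Local
Water) follow the Cottier-type fjord taxonomy; since the literature revises
these boundaries, the ruleset ships as an editable CSV
(`default_watermass_rules()`), data rather than code. Non-SW boxes use
closed lower / closed upper bounds as tabulated; overlaps are resolved by
priority (Local Water is evaluated after Arctic Water).

## Zone comparison: the gated test

Zones are compared by a decision procedure: Shapiro–Wilk normality in every
group and Levene homogeneity of variances (classical Levene, deviations
from group means) are tested first; only if all gate p-values exceed
$\alpha$ does a one-way ANOVA (equal-variance F test) run, otherwise the
Kruskal–Wallis rank test. The gate $\alpha$ equals the test $\alpha$
(default 0.05) — the conjunction logic and gate level are design choices
made explicit here because reports typically state the gates without them.
No post-hoc tests are run. A Monte-Carlo check in the test suite verifies
the composed procedure holds its type-I error within [0.035, 0.065] at
$\alpha = 0.05$ over 2,000 null simulations (three normal groups of 15).

Fold ratios between fjords are reported as conventionally printed: one
decimal for surface-production ratios, nearest 0.5 for
integrated-production ratios. The bundled reference tables
(`zone_surface_reference()`, `zone_pi_reference()`) contain a documented
internal inconsistency of their source campaign: the integrated-production
means give Glacier and Inner between-fjord ratios of about 6.5 and 2.5,
while the accompanying narrative text of that campaign quoted 1.8 and 3.
This package reproduces the mean-consistent values (6.5, 2.5) and leaves
the discrepancy documented rather than resolved.

## The synthetic campaign

The generator (`zone_scenario()`, `generate_campaign()`) emulates the
vertical and statistical structure the analysis assumes, and nothing more:

- **Stratification.** Salinity and temperature follow a logistic
  halocline/thermocline between drawn surface values and fixed deep values,
  normalised so the surface value is met exactly at 0 m. Surface values are
  drawn per cast from the calibrated stratum means and SDs.
- **Light.** $PAR(z) = PAR_0 e^{-k_d z}$ with a turbidity-controlled
  diffuse attenuation coefficient: $k_d = 0.8$ m$^{-1}$ in Glacier zones
  (mineral-laden meltwater squeezes the euphotic zone into the top metres;
  true production at 10 m falls below 1% of the surface value), 0.35 in
  Inner and 0.12 in Outer zones.
- **Biomass.** Chlorophyll is a Gaussian subsurface maximum over a
  background, with the peak deepening seaward (7 m Glacier, 10 m Inner,
  15 m Outer) as the meltwater turbidity relaxes.
- **Production.** A saturating hyperbolic-tangent
  photosynthesis–irradiance response,
  $P_e = \mathrm{Chl} \cdot P^B_{max} \tanh(\alpha\, PAR / P^B_{max})$ —
  the minimal model that yields surface-intensified Glacier profiles and
  deep Outer maxima. Photoinhibition is omitted: nothing in the emulated
  regime requires it.
- **Observables by inversion.** Bottle activities and extract absorbances
  are back-computed by inverting the production and chlorophyll equations
  at each cast's own carbonate state, then perturbed with multiplicative
  mean-one log-normal noise (coefficient `noise_cv`, default 0.1) — so at
  zero noise the pipeline recovers the true profiles to machine precision,
  a round-trip identity the tests assert.
- **Calibration.** The default campaign sets surface temperature, salinity,
  surface production and surface chlorophyll per stratum to the bundled
  published zone summaries; the assimilation number is the target surface
  production divided by the target surface chlorophyll (about 1.5–5.7
  mgC mgChl$^{-1}$ h$^{-1}$, within the usual field range), and the
  chlorophyll background is solved so the profile meets the surface
  target. Deep water masses are chosen so classification recovers Local
  Water under the glaciers, Intermediate Water further out, and Atlantic
  Water in outer Kongsfjorden.
- **Sampling.** Ten fixed depths {0, 2, 3, 5, 7, 10, 15, 20, 30, 50} m —
  a 0–50 m Niskin series consistent with the depths named in fjord
  campaign reports; the exact set is an assumption and is flagged as such.
- **Seeding.** One master seed; an independent substream seed per scenario
  drawn deterministically from it, so campaigns are bit-reproducible and a
  stratum's casts do not depend on other strata being generated.

What the generator does **not** emulate: advection and plume dynamics,
nutrient limitation, sea-ice optics, photoinhibition, inter-annual
variability, or the very large between-cast spread of real multi-decadal
campaigns (the reference SDs for surface production are of the order of the
means; the generator's between-cast spread is measurement-noise scale).
Passing recovery tests therefore demonstrates the correctness of the
pipeline arithmetic and profile-shape extraction under realistic vertical
structure — not that the pipeline has been validated against ocean data.

## Numerical choices

- Trapezoid integration on the sampled depths, no smoothing or splines; a
  missing surface sample is filled by constant extension of the shallowest
  value; below the deepest sample the default is zero production
  (conservative where deep light is extinguished), with constant extension
  and truncation as alternatives; samples straddling the 30 m bound are cut
  by linear interpolation. On profiles whose variation scale is comparable
  to the level spacing the trapezoid tracks fine quadrature within 2%;
  sharply peaked turbid-zone profiles sampled at this resolution can
  deviate a few percent more, which is an irreducible property of discrete
  bottle sampling, not of the integrator.
- Envelopes interpolate each cast linearly in depth with no extrapolation
  beyond its sampled span; casts not spanning a grid depth are excluded
  there and the contributing count is reported.
- Depth-of-maximum ties break to the shallowest tied depth.
- Singleton strata get SD 0 with a flag rather than NA, so downstream
  tables stay numeric.
- Simulation sizes in the test suite (30 casts per stratum for recovery,
  2,000 Monte-Carlo null datasets, 0.1-degree classification grids) were
  chosen as the smallest sizes at which the checked statistics are stable;
  they run in well under a minute each on a laptop core.

## Known limitations

- The carbonate routine is a salinity-alkalinity approximation; in
  meltwater-modified surface layers the true alkalinity–salinity relation
  can deviate from the open-ocean factor, and the 5% solver agreement is
  assessed over oceanic ranges (S ≥ 28).
- The pipeline treats each cast independently; no time-of-day or
  inter-annual structure is modelled.
- Published-ratio recomputation exercises the summary arithmetic, not the
  underlying field dataset, which is not redistributed here.
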