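---
title: "Methods: diet indices, permutation statistics and isotopic-niche geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet indices, permutation statistics and isotopic-niche geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietniche)
```

# The analytical problem

Mid-trophic ("mesopredator") pelagic fishes such as mackerels (*Scomber*
spp.) and horse mackerels (*Trachurus* spp.) sit between planktivores and
apex predators, and whether several co-occurring species can persist on
the same resource base is a question about **resource partitioning**: do
their diets, and the time-integrated trophic position recorded in their
muscle tissue, actually differ? The standard study design combines two
complementary views:

* **Stomach-content analysis (SCA)** — a snapshot of what each fish ate
  last, summarized per prey taxon by occurrence, numeric and gravimetric
  composition, and combined importance;
* **Stable-isotope analysis (SIA)** — a bivariate
  (δ¹³C, δ¹⁵N) signal per fish: carbon tracks the basal
  source (benthic/inshore vs pelagic/offshore), nitrogen tracks trophic
  level (each trophic step enriches δ¹⁵N by roughly 2.5–5‰).

`dietniche` implements the full analysis chain for such a design —
four species sampled across three geographic areas and two depth strata —
together with a seeded synthetic-data generator that emulates the survey
structure, so that every statistical component can be exercised and
validated end-to-end even though real survey data of this kind are
typically confidential.

# Diet indices

For a group of stomachs the package computes, per prey taxon \(i\):

* \( \%F_i = n_i \times 100 / N \) — frequency of occurrence, with
  \(n_i\) the number of stomachs containing the taxon and \(N\) the number
  examined. **Convention:** \(N\) counts *all* examined stomachs of the
  group, including empty ones; a flag restricts it to non-empty stomachs,
  since both conventions are in field use.
* \( \%N_i \) and \( \%W_i \) — numeric and gravimetric composition,
  each taxon's counts (weights) as a percentage of all prey counts
  (weights). Unidentifiable fragments carrying weight but no count are
  entered as one individual and reported via a message.
* \( IRI_i = (\%N_i + \%W_i)\times\%F_i \) and its normalized percentage
  \(\%IRI\) (sums to 100 within a group).
* Shannon–Wiener diet diversity \(H' = -\sum p_i \ln p_i\), computed
  **per stomach** (so it can be compared across groups with univariate
  permutation ANOVA) with \(p_i\) based on counts by default; a biomass
  basis is available because the field literature is split on this point.

A stomach counts as empty when its fullness — content weight as a percent
of body weight — is below 0.5%. Records flagged as "other material"
(scales, parasites, undigested matter) are excluded from all composition
analyses by default and from every resemblance matrix.

# Isotope preprocessing

δ values are per-mil deviations of the heavy/light isotope ratio from the
international standards. Because lipids are depleted in ¹³C, δ¹³C of
lipid-rich tissue is normalized arithmetically using the bulk C/N mass
ratio as a lipid proxy:

\[ \delta^{13}C_{corr} = \delta^{13}C_{raw} - 3.32 + 0.99\times C/N,
   \qquad \text{applied only when } C/N > 3 . \]

The gate makes the rule discontinuous at \(C/N = 3\) (a jump of
\(-3.32 + 2.97 = -0.35\)‰); the package implements the rule exactly as
printed rather than smoothing it, and `process_isotopes()` records a
`corrected_flag` so the correction can never be applied twice. All
downstream analyses consume the corrected value; the raw value is kept
for audit. Length–isotope relations are tested with Pearson correlation
(`stats::cor.test`), reported as \(r\), \(R^2 = r^2\), two-sided \(p\)
and \(n\), pooled per species by default (per species × area available).

# Permutation multivariate statistics

All tests operate on a resemblance matrix: Bray–Curtis on
log(x+1)-transformed prey biomasses for diet composition, plain Euclidean
distances for univariate responses (fullness, \(H'\)) and for the isotope
pair. Sums of squares are partitioned directly from squared inter-point
distances through the Gower-centered matrix \(G = -\tfrac12 C D^{(2)} C\):
the SS explained by a design is \(\mathrm{tr}(HG)\) with \(H\) its hat
matrix, so the one-way pseudo-F on Euclidean distances of univariate data
reproduces the classical ANOVA F exactly (this closed-form limit is a
standing test).

Two designs are provided:

* **One-way** (fixed factor, e.g. area within one species):
  unrestricted permutation of raw data — group labels are freely
  reallocated, 9999 permutations by default.
* **Nested mixed model** (species fixed, area random and nested in
  species): the fixed factor is tested against the nested-factor mean
  square and the nested factor against the residual, following
  mixed-model expected mean squares. Sequential (Type I) SS are used for
  unbalanced designs. For the fixed term the exchangeable units under the
  null are the nested cells, so whole cells are reallocated across
  fixed-factor levels; for the nested term a Freedman–Lane-style
  permutation of the reduced-model (fixed-factor-only) residual Gower
  matrix is used. The exact residualization scheme for a nested random
  term is not uniquely defined in the literature; this choice is
  documented here as the package's own and is validated by simulation
  (type-I rate within Monte-Carlo error of the nominal 5%, power > 0.8
  for a one-pooled-SD centroid shift in the reference design).

P-values always use the \((b+1)/(m+1)\) convention and ties count as
exceedances, so a permutation p-value is never exactly zero and the test
is conservative under discreteness. A caveat worth knowing: with few
nested cells the fixed-term null distribution has limited resolution
(e.g. 2 species × 3 areas gives only 20 distinct reallocations), so
small designs cannot reach small p-values — a property of the design,
not of the implementation.

Supporting analyses:

* **PERMDISP** — distances to group centroids computed directly from
  squared dissimilarities,
  \( z_i^2 = \frac{1}{n_g}\sum_{j\in g} d_{ij}^2 -
     \frac{1}{n_g^2}\sum_{j<k\in g} d_{jk}^2 \),
  which equals the corrected principal-coordinate formula when negative
  eigenvalues are present (values truncated at zero before the square
  root). The ANOVA F on these distances is referred to a permutation of
  the distances across groups; group means are read as diet generalism
  (large) vs specialism (small).
* **SIMPER** — the average between-group Bray–Curtis dissimilarity is
  decomposed into additive per-taxon contributions averaged over all
  cross-group pairs; the listing is truncated at a cumulative 60% by
  default (the full decomposition is retained). It runs on the
  transformed biomasses, consistent with the resemblance matrix that the
  tests use; raw biomass is an option.
* **CAP** — principal-coordinate embedding followed by linear
  discriminant analysis on the first \(m\) axes, with \(m\) chosen to
  maximize leave-one-out allocation success (the first maximum, i.e. the
  most parsimonious \(m\), wins ties); the LOO allocation success per
  group is the headline diagnostic.

Pairwise follow-ups rerun the same one-way scheme on each level pair.
No multiplicity correction is applied by default, matching common
practice for these permutation tests; Holm adjustment is available.

# Isotopic-niche geometry

For each group's corrected (δ¹³C, δ¹⁵N) cloud:

* **TA** — convex-hull area (shoelace formula on the hull vertices);
  collinear sets give area 0 with a warning.
* **SEA / SEAc** — the standard ellipse is the 1-σ Mahalanobis ellipse of
  the sample covariance; \( SEA = \pi\sqrt{\lambda_1\lambda_2} \) and
  \( SEA_c = SEA\,(n-1)/(n-2) \). Under bivariate normality the standard
  ellipse contains \(1 - e^{-1/2} \approx 39.3\%\) of the data — the
  usual "about 40%" statement — and this coverage is verified by
  simulation.
* **SEA_B** — a Bayesian posterior for the ellipse area: covariance drawn
  from its conjugate inverse-Wishart posterior (prior degrees of freedom
  2, prior scale \(0.01\,I\); a vague prior whose influence vanishes
  by \(n \approx 20\)), each draw mapped to \(\pi\sqrt{\det\Sigma}\).
  The posterior median approaches SEAc as \(n\) grows; prior sensitivity
  can be probed by looping `prior_scale` over 0.001/0.01/0.1.
* **Layman metrics** — NR and CR (δ¹⁵N and δ¹³C ranges), CD (mean
  distance to centroid), MNND and SDNND (mean and SD of nearest-neighbor
  distances). SDNND uses the population (divide-by-n) convention so that
  two points give exactly 0; nearest-neighbor ties resolve to the minimal
  distance value, since only the metric matters.
* **Ellipse overlap** — the intersection area of two ellipses, each
  inflated by \((n-1)/(n-2)\) so its area equals SEAc, computed by grid
  integration (400 × 400 over the intersection bounding box; error
  typically below 0.5%, resolution configurable). Overlap is reported in
  ‰² and as a percentage of each group's SEAc.

Groups with \(n < 3\) report only ranges; ellipses from \(n < 5\) are
flagged as small-sample per the usual field guidance.

# The synthetic-data generator

The generator is a first-class module: its defaults *are* the emulated
study conditions, and they are not tuned per run.

* **Design** — 4 species × 3 areas × 2 depth strata with exact per-cell
  specimen counts by sex (totals 62, 16, 93 and 42; juvenile-heavy for
  the chub and Atlantic horse mackerel, adult-heavy for the Mediterranean
  horse mackerel), matching the emulated survey table cell-by-cell.
* **Sizes** — total length is a mixture of uniforms over the size-class
  bands small < 12 cm, medium 12.1–24 cm, large ≥ 24 cm, with per-species
  mixes; TL is rounded to 0.1 cm (ichthyometer precision) and kept inside
  the open band edge so the drawn and derived classes agree. Undetermined
  sex (ND) is assigned to the smallest fish in each cell. Wet weight
  follows \(W = aL^b\) with \(a = 0.008\), \(b = 3.05\) — generic small
  pelagic values; only *relative* fullness matters downstream.
* **Stomachs** — empty with a per-species probability (0/62, 6/16,
  16/93, 8/42); otherwise biomass shares are a Dirichlet draw around the
  species × area expected profile with concentration 5, which produces
  realistic among-individual diet variation; fullness is uniform on
  (0.6%, 5%), empty stomachs uniform on (0, 0.45%) so the 0.5% threshold
  is never straddled by rounding. Prey counts derive from per-taxon mean
  individual weights; digestion grades are uniform on 0–3.
* **Isotopes** — per species × area bivariate normal on the
  *corrected* scale, plus per-species TL slopes applied to
  \(TL - E[TL]\) with homoscedastic Gaussian noise (the error structure
  is an assumption; nothing finer is identifiable from summary
  statistics). The δ¹⁵N slope of *T. mediterraneus* is set in closed form
  so the pooled TL regression has expected \(R^2 = 0.56\); its area
  signal is carried by δ¹³C so the calibration is not diluted by
  between-area variance. The emitted raw δ¹³C is back-transformed through
  the C/N gate so that applying the lipid correction recovers the
  simulated corrected values exactly.
* **Seeding** — one root seed; each stage draws from its own derived
  stream, so stomachs can be regenerated without re-drawing specimens.
  Identical config + seed gives byte-identical CSV output.

What the generator does **not** emulate: haul-level spatial clustering and
any within-haul correlation, seasonal turnover of prey communities,
digestion-state-dependent detectability of prey, measurement error in
prey weights, and isotope baseline gradients within an area. Passing
tests therefore demonstrate that the *statistical machinery* is correct
and calibrated under the declared generating model — not that any
particular field dataset satisfies that model.

# Validation problem sizes

The standing test suite validates each component at sizes chosen to keep
Monte-Carlo error meaningful: the diet-index oracle runs 200 random small
groups; the classical-ANOVA limit 50 datasets at 10⁻⁹; type-I calibration
of the one-way test uses 500 null replicates at 999 permutations
(acceptance band 3–7% at α = 0.05); the nested design runs 200 replicates
at 199 permutations for both the power (≥ 0.8 at a 1-SD shift) and null
branches; geometry oracles run 100 random point sets at 10⁻¹²; ellipse
recovery uses 10⁴ Gaussian draws (2% band); scenario fidelity checks the
exact cell counts, empty-stomach binomial confidence intervals over 200
seeds, and the TL–δ¹⁵N \(R^2\) over 20 seed replicates (± 0.1 band).

# Known limitations

* The nested design supports exactly one fixed and one nested random
  factor — the two designs the analysis needs — not a general linear
  model with covariates.
* Only Bray–Curtis and Euclidean resemblances are provided.
* PERMDISP permutes distances-to-centroid rather than re-deriving
  centroids per permutation; with very unbalanced groups this variant can
  be slightly liberal.
* The ellipse-overlap quantification is a declared extension: "partial
  overlap" statements in the literature are usually verbal, and the
  intersection-of-SEAc-ellipses definition here is one reasonable
  formalization.
* Bayesian SEA assumes bivariate normality; heavy-tailed isotope clouds
  will widen SEAc faster than SEA_B.

# A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(scenario = default_scenario(42),
                       out_dir = "report", n_perm = 999, seed = 42)
rep <- run_pipeline(cfg)
rep$niche_by_species
```
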