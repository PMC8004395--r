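---
title: "Methods and design of the dietmg pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the dietmg pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietmg)
```

`dietmg` couples multi-day diet diaries with shotgun gut metagenomes. This
vignette describes the statistical machinery, the choices made where the
design was genuinely open, what the synthetic-data generators emulate, and
what the passing tests do and do not demonstrate about real data.

## The food tree and UniFrac diet distances

Food items are leaves of a five-level rooted tree: level 1 is the root,
level 2 holds the five broad classes (animal-based, plant-based, alcohol,
fats, others), levels 3–4 come from the food composition database's own
hierarchy, and level 5 subdivides each level-4 category by nutrient
content. The subdivision fits a Dirichlet multinomial mixture (DMM) to the
integerised per-100 g nutrient compositions of the category's items
(values ×10, rounded; energy is excluded from the composition vector since
it is a near-linear combination of the macronutrients) and makes each
selected mixture component a level-5 subcategory. Categories with a single
item become a single level-5 node.

The unweighted UniFrac distance between two diaries is the branch length
occurring in exactly one diary's leaf set divided by the branch length in
either. Presence means any consumption above 0 g across the recorded days;
amounts are deliberately ignored (the weighted variant is out of scope).
All branches have unit length by default — the source hierarchy gives no
meaningful branch lengths, so the distance is purely topological; the
length is a single configurable constant, which cancels in the ratio.
UniFrac values are in [0, 1], and the test suite verifies the metric
axioms exhaustively on 50-subject cohorts and checks exact agreement with
an independent implementation (`picante::unifrac` on a zero-length
dichotomisation of the exported newick tree).

The meat/plant ratio of a diary is
`log2((grams animal-based + c) / (grams plant-based + c))` with a 1 g
pseudocount; alcohol, fats and "others" enter neither sum. Assigning those
classes to either side has no support in the underlying food taxonomy, so
they are excluded rather than guessed.

## DMM fitting and Laplace model selection

The DMM is fitted by EM: the E-step uses the exact Dirichlet-multinomial
marginal likelihood; the M-step updates each component's Dirichlet
parameter vector by a responsibility-weighted fixed-point iteration and
the weights by their posterior means. For each candidate K the fit is
restarted from k-means initialisations and the best likelihood kept.

Model selection minimises a Laplace approximation to the negative log
evidence, evaluated at the posterior mode under a Gamma(0.1, 0.1) prior on
every Dirichlet parameter and a N(0, 2) prior on the softmax-transformed
weight coordinates (the mode is polished by BFGS after EM). The score is

$$-\log L(\hat\theta) - \log \pi(\hat\theta) - \tfrac{d}{2}\log 2\pi +
  \tfrac12\log\lvert H\rvert,$$

with $H$ the observed information of the log posterior (finite differences
of the analytic score function). The prior matters: at a pure maximum
likelihood optimum, redundant components create near-flat directions whose
vanishing curvature would spuriously *reward* larger K; the prior prices
those directions and keeps $H$ positive definite. Component assignment is
the posterior maximum, with ties broken towards the lowest component
index. On data simulated from a well-separated K = 3 mixture (n = 200),
the selection recovers K = 3 in essentially every seed (the acceptance
suite requires ≥ 80% of 20 seeds).

The same machinery drives the "CAZotype" partitioning of samples by CAZy
family profiles, after converting relative abundances to pseudo-counts
(×10⁴, rounded — the same integerisation convention as the food tree).

## FSA-NPS scoring

Points are attributed per component by the highest threshold strictly
exceeded, using the packaged grid file (`inst/extdata/fsanps_grids.csv`,
editable): energy kJ 335…3350, sugars 4.5…45 g, saturated fat 1…10 g and
sodium 90…900 mg give 0–10 unfavourable points each; fibre 0.7…3.5 g and
protein 1.6…8 g give 0–5 favourable points; fruit/veg % maps 40/60/80 to
1/2/5 points. The item score is unfavourable minus favourable, spanning
−15…+40 by construction. The scheme's protein-capping exception (protein
points withheld at high unfavourable totals unless fruit/veg is maximal)
is intentionally not applied: the score here is the plain signed sum, which
is what the downstream diet index consumes and what fixes the theoretical
bounds. Class bounds are strict (`score < bound`), so a drink scoring 2 is
class C while a food scoring 2 is class B; the edge score of exactly 40 is
class E.

The diet index is the energy-weighted mean score over consumed *portions*
(per-100 g energy × grams/100), making it invariant to splitting a portion
in two. Where an item recurs, each portion contributes its own energy
weight. The high/low meal-quality ratio counts items (not grams) in class
A versus class E by default; both the counting unit and the class
groupings are configurable because the underlying convention is not fixed
by any standard.

## MSP subspecies

Per sample and MSP, the median core-gene coverage determines detection
(strictly > 2). In detected samples, each accessory gene is called present
when its coverage lies within the 2.5–97.5% quantile band of that sample's
core-gene coverages, absent below the band. Coverage above the band
indicates a multi-copy or strongly conserved gene; since the gene is
evidently there, the default codes it present, with a switch to code it
absent (both paths are tested). The core genes are the natural coverage
reference for the band: they are by definition present in one copy per
cell. A degenerate band (all core coverages equal) falls back to
presence = coverage > 0 with a warning.

Jaccard distances between the binary accessory rows feed partitioning
around medoids for k = 2…k_max; the mean silhouette width selects k, and a
floor of 0.25 (configurable) leaves the MSP unsplit when even the best
silhouette is weak — mirroring the observation that most MSPs do not
split. Stability is assessed by refitting on 100 random 2/3 subsets
without replacement and recording, per original cluster, the mean best
Jaccard agreement with the refit clusters; clusters below 0.6 are flagged
unstable. Splitting is only attempted with at least 10 detected samples.
Subspecies abundance attributes each sample's whole MSP abundance (median
core coverage) to its assigned subspecies, so abundances are conserved
exactly; unsplit MSPs are carried as single "unassigned" units.

## Ordination and coupling

√JSD between per-sample compositions uses a 10⁻⁹ pseudocount before
normalisation and the natural logarithm; it satisfies the metric axioms on
the tested instances. PCoA is the classical double-centred eigendecomposition;
variance fractions use positive eigenvalues only. New individuals are
projected onto training axes with Gower's out-of-sample formula from their
distances to the training samples; projecting a training sample through
its own distances reproduces its coordinates exactly, which the tests
assert.

Co-inertia takes the two blocks' PCoA coordinates over common subjects
(each block keeps enough axes to reach 50% of its positive-eigenvalue
variance), centres them with uniform row weights, and decomposes the
cross-covariance by SVD; 7 axes are retained by default and regressions
use the first 5 — the reference analysis's reported choices. The RV
coefficient summarises global coupling in [0, 1]. Individuals with only
one block are placed in the common space by centring their (possibly
projected) PCoA coordinates and applying that block's loadings.
PERMANOVA is delegated to `vegan::adonis2`; the per-taxon scan runs a
continuous-covariate PERMANOVA of the diet distances on every node
abundance from MSP down to subspecies and retains lineages with any node
R² > 0.02, with no significance filter — effect size, not p-value, is the
screen. Out-of-sample PCoA projection is also available as a switch, but
the default coupling stage computes PCoAs on all samples jointly, matching
the reference analysis's wording.

The H₂/CH₄ read-out is `log2((H2 + 1)/(CH4 + 1))`; the +1 offsets guard
zero measurements and are configurable. Severity regression codes
healthy/mild/moderate/severe as 1–4.

## Functional profiles

Gene counts are aggregated per annotation universe (CAZy families;
hydrogenase metal-site groups) and renormalised per sample, so each
universe is compositional. The correlation network keeps cross-universe
Spearman correlations with |ρ| > 0.4, signed; within-universe edges are
optional and off by default. The two-class discriminant score standardises
features, solves (S_w + λI)w = m₁ − m₀ on the pooled within-class scatter
(λ ridge applied with a warning when S_w is singular — always the case for
compositions, which carry a sum constraint), and reports each feature's
loading signed towards its enriched class plus a log₁₀-style display
magnitude; features are ranked by loading magnitude.

## What the synthetic generators emulate

The generators define the study conditions under which the pipeline is
validated:

- **Food database** (default 120 items, 8 nutrients): a fixed 4-level
  hierarchy under the five broad classes; within every level-4 category,
  item compositions are drawn from 2–3 distinct Dirichlet components
  (precision 150) so the level-5 split has real structure. FSA-relevant
  columns (sugars, saturated fat, sodium, energy, fruit/veg %, drink flag,
  fructose/monosaccharides) are derived with class-plausible skews.
- **Diaries** (4 days × breakfast/lunch/dinner + 0–2 snacks; log-normal
  grams): item choice is tilted by two subject latents — `meat_plant_score`
  (N(0, 1) by default) multiplies an item direction of +1/−1/0 for
  animal/plant/other, and `quality_score` (higher = poorer diet) tilts
  towards high-FSA-NPS items. Each subject's grams are scaled to a
  plausible daily energy (N(2100, 300) kcal clamped to 1000–4200), so
  generated cohorts pass the 800/4500 filter by construction. A derived
  `gas_score` (0.6·meat_plant + independent noise) is the latent behind
  exhaled-gas coupling.
- **Metagenomes**: each MSP has ≥ 30 core genes and accessory genes in
  disjoint blocks (one per planted subspecies) plus background accessory
  genes present at random. Detected samples draw coverage log-normally
  around an MSP base (clamped ≥ 3.5 so detection is unambiguous); an
  `undetected_frac` of samples (default 10%) gets sub-threshold coverage.
  MSP abundances respond to the meat-plant latent with random
  per-MSP coefficients; one designated MSP is made diet-*neutral* in
  abundance while its subspecies assignment follows the latent — this is
  the configuration in which subspecies-level analysis must out-resolve
  species-level analysis, and the PERMANOVA-scan test asserts exactly that.
- **Clinical table**: severity is a noisy monotone function of
  `quality_score` cut at quartiles into codes 1–4; log H₂ and log CH₄ are
  linear in the gas and meat-plant latents with opposite signs on the gas
  term, so the H₂/CH₄ ratio carries the latent; enterotype is a noisy
  3-level cut of the meat-plant latent.
- **Functional tables**: one hydrogenase group ([FeFe] A3) and eight
  animal-carbohydrate CAZy families share the gas latent (slope 1.0 on the
  log scale, noise 0.45); [FeFe] A3 gains 1.2 log-units in severe
  subjects. The compositions are anchored by a few dominant, stable
  families (log-abundance base 4, noise 0.15) with the coupled families
  rare (base −1). This anchoring is deliberate: in a closed composition, a
  high-variance coupled family drags every other relative abundance with
  it, and spurious closure-driven correlations would otherwise cross the
  |ρ| > 0.4 threshold. Dominant stable families are also the realistic
  regime for gut functional profiles, where housekeeping glycoside
  hydrolases dwarf specialised ones.

What passing tests show: every algorithmic stage recovers the structure it
was designed to find, at realistic sizes, from inputs it has never seen,
deterministically. What they do not show: performance under real-world
nuisances absent from the generators — batch effects, compositional
sequencing depth variation, diary under-reporting, correlated nutrient
measurement error, or MSP catalog errors. The cohort-scale numbers of the
reference analysis (RV = 0.59 at n = 79; 1661 MSPs / 523 subspecies; diet
PCoA fractions 7.9%/6.1%) depend on the deposited data and are quoted as
context only.

## Numerical choices and degenerate inputs

- EM: tolerance 10⁻⁴ on the log-likelihood, ≤ 150 iterations, 2 restarts;
  Dirichlet parameters floored at 10⁻⁸; information-matrix eigenvalues
  floored at 10⁻⁸ before the log-determinant.
- All-zero count rows, empty diaries/profiles, constant covariates,
  zero-variance features and degenerate quantile bands raise errors or
  warnings naming the offending unit; they are tested explicitly.
- Every generator and every stochastic stage draws from a locally seeded
  RNG (`withr`-style save/restore), so package calls never disturb the
  caller's RNG state and the whole pipeline is reproducible from one
  master seed; stage seeds are derived deterministically from it.
- Problem sizes in the validation suite — 50-subject metric checks,
  n = 200 DMM selection over 20 seeds, 500 × 199-permutation PERMANOVA
  calibration, 100-subject coupling runs, 150-sample network recovery —
  were chosen as the smallest sizes at which the planted effects are
  comfortably identifiable, keeping the full suite fast on a single CPU.

## Known limitations

- The FSA-NPS grids are the published per-100 g thresholds, but the
  protein-capping exception is omitted (see above); scores for
  high-protein, high-unfavourable items are therefore slightly more
  favourable than a strict implementation of the original scheme.
- DMM model selection relies on a Laplace approximation, which can be
  optimistic for small n or near-boundary weights; candidate K should stay
  well below n.
- The PERMANOVA scan reuses the same distance matrix across many nodes;
  its R² screen is descriptive and deliberately unadjusted.
- Co-inertia assumes commensurable PCoA blocks; axes are not re-weighted
  by eigenvalue share beyond the 50%-variance truncation.
- The correlation network treats relative abundances directly; no
  compositionally-aware transform (e.g. CLR) is applied, matching the
  reference procedure rather than best current practice.
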