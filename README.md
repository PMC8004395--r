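# dietmg — coupled analysis of diet records and gut metagenomes

`dietmg` is an R toolkit for cohorts in which participants provide both
multi-day diet diaries and shotgun gut metagenomes (typically irritable
bowel syndrome studies with exhaled H₂/CH₄ measurements). It implements, as
one tested pipeline:

- **Nutrient-informed food trees + UniFrac diet distances.** Food items are
  arranged on a 5-level tree (root; animal-based / plant-based / alcohol /
  fats / others; the food-database hierarchy; nutrient-based subcategories
  found by a Dirichlet multinomial mixture per category). The unweighted
  UniFrac distance between two diaries is the branch length unique to
  either diary's consumed leaves over the branch length they jointly touch.
- **FSA-NPS diet quality.** Per-item nutrient-profiling scores
  (unfavourable points for energy kJ, sugars, saturated fat, sodium, 0–10
  each, minus favourable points for fibre, protein and fruit/veg %, 0–5
  each; theoretical range −15 to +40), A–E quality classes (drink bounds
  1/2/5/9/40, food bounds 0/3/10/18/40), and the energy-weighted diet
  index DI = Σ eᵢsᵢ / Σ eᵢ. Per-meal quality profiles, excess fructose,
  the ±4 SD FODMAP outlier rule and the 800–4500 kcal/day plausibility
  filter are included.
- **MSP subspecies.** From a metagenomic species pangenome (MSP) catalog
  and a gene×sample coverage matrix: detection (median core coverage > 2),
  accessory presence calls inside the per-sample 2.5–97.5% core-coverage
  quantile band, Jaccard distances between samples, and partitioning around
  medoids with the mean silhouette width choosing k and a subset-bootstrap
  cluster stability (100 refits on 2/3 subsets).
- **Diet–metagenome coupling.** √Jensen–Shannon distances at subspecies
  level, principal coordinate analysis with Gower out-of-sample projection,
  PERMANOVA (via vegan's adonis2) including a per-taxon-node scan with a 2%
  effect-size lineage filter, co-inertia analysis of the two PCoA blocks
  with the RV coefficient RV = tr(XᵀY YᵀX)/√(tr((XᵀX)²)·tr((YᵀY)²)),
  projection of single-block individuals into the common space, and
  principal-component regression of clinical read-outs (severity coded
  1–4, log₂ H₂/CH₄ ratio, meat/plant ratio) on the leading co-inertia axes.
- **Functional profiles.** Aggregation of gene counts to CAZy families and
  hydrogenase metal-site groups, DMM "CAZotype" partitioning with Laplace
  model selection, CAZotype×enterotype χ² association, the CAZy–hydrogenase
  Spearman network at |ρ| > 0.4, and two-class linear discriminant scores
  for severe-vs-control.
- **A synthetic-data module** that generates every input with planted
  truth — a latent meat↔plant gradient, a diet-quality gradient coupled to
  symptom severity, disjoint accessory-gene subspecies blocks, and
  functional families coupled to a gas-metabolism latent — so that each
  stage's recovery can be verified without any cohort download.

## Worked example

```r
library(dietmg)
res <- demo_pipeline(seed = 42, n_subjects = 60, out_dir = "results")
res$coupling$coinertia
#> co-inertia model: RV = 0.184 ; 5 axes accounting for 100% of covariation
round(sapply(res$coupling$regressions, function(r) r$test_r), 2)
#>         severity     h2_ch4_ratio meat_plant_ratio
#>             0.86             0.62             0.90
res$functions$network
#> correlation network: 8 edges at |rho| > 0.4
head(res$functions$lda, 1)
#>   feature loading enriched_in   score log10_magnitude
#> 1 FeFe_A3 1.95624      severe 1.95624       0.4707396
```

The demo generates a 60-subject synthetic cohort, builds the food tree and
UniFrac matrix, scores diet quality, calls MSP subspecies, couples the two
ordinations and fits the functional stage. The held-out Pearson r values
show that the planted clinical couplings are recovered from the diet block
alone (severity 0.86, log₂ H₂/CH₄ 0.62, meat/plant ratio 0.90 for this
seed); the network edges are exactly the planted hydrogenase–CAZy pairs,
and the LDA ranks the planted severe-enriched [FeFe] A3 group first.
Output tables (UniFrac matrix, diet summary, subspecies partition,
co-inertia scores, regressions, network edges, a manifest with all
parameters and seeds) are written under `results/`.

A thin command-line front-end ships in `inst/scripts/dietmg`:

```sh
Rscript inst/scripts/dietmg demo --seed 42 --n 60 --out results/
Rscript inst/scripts/dietmg validate --food-db food_db.tsv --diaries diaries.tsv
```

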