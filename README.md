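# flyrisk

Invasion-risk mapping for the peach fruit fly *Bactrocera zonata* — and,
with different inputs, any presence-only invasive species. The package is
aimed at quantitative ecologists and plant-health analysts who need a
reproducible, scriptable version of the classic risk-mapping workflow:

1. **Occurrence handling** — load, validate, deduplicate and spatially
   thin presence records (greedy 10 km minimum-distance filter, haversine
   distances on WGS84).
2. **Predictor pruning** — pairwise Pearson correlations between
   bioclimatic layers and iterative elimination of collinear layers at
   |r| > 0.7.
3. **Climatic suitability** — a presence-background maximum-entropy
   (MaxEnt-style) model: a Gibbs density q<sub>λ</sub>(x) =
   e<sup>λ·f(x)</sup>/Z over background + presence points, fitted by
   L1-penalised coordinate descent over linear, quadratic and hinge
   features (regularisation multiplier 2 by default), with logistic
   output p = e<sup>H</sup>q/(1 + e<sup>H</sup>q), rank-sum AUC on a
   75/25 split, jackknife variable importance, percent contribution and
   the 10% training-presence threshold.
4. **Habitat overlay** — overall suitability S = (n(cs) + n(h))/2, the
   equally weighted mean of min–max-normalised climatic suitability and
   host availability, reclassified into four classes at breaks
   0.15 / 0.30 / 0.60.
5. **Natural spread** — a Gaussian dispersal kernel c₁e^(−c₂x²) with
   parameters derived from the literature maximum dispersal capacity
   D_max = 40.2 km (25 miles) read as 3σ: σ = 13.4 km, c₁ = 0.03,
   c₂ = 0.003; the dispersal likelihood at a cell at distance x from its
   nearest source is l = [(k₁·n(cs) + k₂·n(h))/(k₁+k₂)]·c₁e^(−c₂x²).

Because no public bundle of occurrences + rasters exists for this
workflow, the package ships a first-class synthetic-data generator
(spatially autocorrelated predictor stacks with exactly controlled
collinear pairs, a known logistic true-suitability surface, presences
sampled proportionally to it, host rasters, climate-scenario
perturbations), so the entire pipeline runs and is tested end to end
without downloading anything. Rasters are exchanged as plain-text ESRI
ASCII grids; occurrences as CSV.

## Worked example

```r
library(flyrisk)

# 1. Synthetic study region: predictors, true suitability, presences, hosts
scenario <- synthetic_scenario(seed = 4242)
fixtures <- write_scenario(scenario, file.path(tempdir(), "study"))

# 2. Clean and thin the occurrence records
occ <- thin_spatial(deduplicate(fixtures$occurrences), min_km = 10)
#> occurrence_set: 81 records
#>   sample_presences 150 -> 150 (0 removed)
#>   deduplicate  150 -> 150 (0 removed)
#>   thin_10km    150 -> 81 (69 removed)

# 3. Prune collinear predictors at |r| > 0.7
report <- eliminate_correlated(pearson_matrix(fixtures$stack), cutoff = 0.7)
#> correlation_report: 12 layers; 3 dropped at |r| > 0.7: bio7, bio1, bio10
stack <- subset_stack(fixtures$stack, retained_layers(report))

# 4. Fit the maximum-entropy model on a 75/25 split
split <- split_presences(occ, 0.75, seed = 1)
bg    <- sample_background(stack, 10000, seed = 2)
train <- extract_values(stack, split$train$records$lon, split$train$records$lat)
test  <- extract_values(stack, split$test$records$lon,  split$test$records$lat)
model <- fit_maxent(train, bg, feature_spec(), reg_multiplier = 2)
#> maxent_model: 9 variables, 378 features (17 nonzero), reg x2
#>   presences 61, background 10000; entropy H = 7.5021 nats

auc(predict(model, test, "logistic"), predict(model, bg, "logistic"))
#> held-out AUC: 0.951
round(sort(percent_contribution(model), decreasing = TRUE), 1)
#>  bio3  bio6  bio4  bio9  bio5 bio12  bio8 bio11  bio2
#>  37.7  26.2  14.2  10.6   6.1   1.7   1.2   1.2   1.1
threshold_10pct(model, train)
#> 10% training-presence threshold: 0.448

# 5. Merge with host availability and classify
suit <- predict_logistic(model, stack)
S    <- overall_suitability(suit, normalize(fixtures$host))
table(classify(S)$values)
#>    1    2    3
#> 7929 1167  904

# 6. One generation of natural spread from the thinned records
params <- derive_params(D_max = 40.2)
#> dispersal_params: D_max = 40.2 km, sigma = 13.4 km, c1 = 0.03, c2 = 0.003,
#>                   k1 = 0.5, k2 = 0.5
spread <- dispersal_likelihood(suit, normalize(fixtures$host), occ, params)
#> dispersal likelihood: max 0.0169 at sources, 1.5% of cells above 0.01
```

Reading the output: thinning keeps 81 of 150 presences; three of the
twelve candidate predictors are eliminated as collinear; the fitted model
separates held-out presences from the landscape with AUC 0.951 and
credits most of its gain to a few dominant predictors, as real
contribution tables typically do. The overlay classifies most of the
landscape as not suitable (class 1) because host crops cover a minority
of cells, and the spread surface is bounded by c₁ = 0.03, peaking at the
source records and decaying with squared distance.

`run_pipeline(run_config(...))` performs the same chain from file inputs
and writes every intermediate (rasters, tables, a JSON manifest with
settings, seeds and per-stage counts) to an output directory;
`run_synthetic_benchmark(seed)` wraps the whole synthetic experiment and
returns the held-out AUC and the Spearman correlation against the known
true surface.

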