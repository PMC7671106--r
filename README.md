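# dietmorph

Trait-based dietary niche categorization and feeding ecomorphology for
phylogenetic comparative studies.

Conventional diet guilds (insectivore, piscivore, ...) group prey by
taxonomy. For many predators — the package ships a worked dataset of 54
sculpin species (Cottoidea) — taxonomy is a poor proxy for what a jaw
actually has to do: an octopus and a fish are distant relatives but pose the
same functional problem to a predator (acute vision, rapid escape), while a
sessile barnacle poses an entirely different one. `dietmorph` implements a
*synthetic* alternative: prey items are scored for binary functional traits
(exoskeleton, swimming ability, defensive spines, ...), clustered into
emergent prey categories, and each predator's primary diet is the category
carrying the greatest summed stomach-content importance. The package then
relates these diet categories to jaw functional morphology on a phylogeny.

## What it computes

**Prey categories.** From an item × trait binary matrix: Euclidean
distances (for binary traits, the distance between two items is the square
root of the number of traits on which they differ), Ward minimum-variance
clustering (both the squared-distance and as-is dialects of the
Lance–Williams recurrence), and selection of the number of categories from
the within-groups sum of squares,
WGSS(k) = Σ_clusters Σ_members ‖x − x̄_cluster‖², by a reproducible
maximum-distance-to-chord elbow rule.

**Primary diet.** Per-item importances (e.g. percent volume) are averaged
across studies (absent items count 0; descriptive accounts get equal
importance 1/n per listed item), summed within categories, and each species
is assigned argmax_c importance(c), with exact ties resolved toward the
rarer category by default. A conventional coarse label is also assigned by
the strict >50 % majority-type rule.

**Jaw functional characters.** Seven dimensionless ratios from linear
cranial measurements: anterior and posterior closing mechanical advantage
(in-lever/out-lever), occlusal offset, tooth aspect ratio, symphyseal
height, relative head length, and ascending-process/premaxilla length (jaw
protrusion).

**Comparative analyses.** z-transformation, PCA with broken-stick axis
retention (b_j = (1/p) Σ_{i=j..p} 1/i), phylomorphospace node placement by
maximum-likelihood Brownian ancestral states, phylogenetic MANOVA (observed
Wilks Λ = det(W)/det(W+B) against a null simulated by multivariate Brownian
motion on the tree with a GLS-estimated rate matrix), single-rate Mk
ancestral state reconstruction (pruning likelihood, ML rate, re-rooting
marginals, uniform root prior), and linear discriminant re-classification
of diet from morphology.

**Synthetic data.** Seeded generators for birth–death trees conditioned on
tip count, multivariate Brownian traits with group mean shifts, Dirichlet
diet profiles concentrated on a planted focal category, and block-structured
binary prey-trait matrices with flip noise — so the whole pipeline is
testable end to end without any external data.

## Worked example

```r
library(dietmorph)

traits <- read_prey_traits(dietmorph_example("prey_traits.csv"))
pc  <- prey_cluster(traits)              # Ward, sqrt-input dialect
sel <- select_k(wgss_curve(traits, pc))
sel
#> Selected 5 prey categories
cats <- cut_categories(pc, 6)            # cut at the published k

fix <- read_category_importances(dietmorph_example("diet_category_importances.csv"))
a <- assign_diet(fix$importances)        # argmax, rarer-category tie rule
head(a, 3)
#>                   species           category importance   tie
#> 1 Abyssocottus korotneffi benthic_arthropods       0.96 FALSE
#> 2    Artedius fenestralis benthic_arthropods       0.64 FALSE
#> 3      Blepsias cirrhosus benthic_arthropods       0.59 FALSE

s <- concentration_summary(fix$importances, a)
s$category_counts
#> benthic_arthropods pelagic_arthropods stationary_benthic_items
#>                 41                  4                        3
#>   squishy_swimmers tentacles_and_appendages              vermes
#>                  3                        2                   1
c(s$n_concentrated, s$n_unconcentrated)
#> [1] 48  6
```

41 of the 54 species feed primarily on benthic arthropods; 48 species take
more than half their diet from a single category and 6 do not; among the
benthic-arthropod feeders, 28 exceed 0.70 importance and 17 reach 0.90 at
the table's printed precision. The elbow rule selects 5 categories on this
trait matrix while the published analysis used 6 — the WGSS curve has no
sharp kink, and `select_k()` returns the full curve precisely so that this
judgement can be reviewed; `cut_categories(pc, 6)` reproduces the published
grouping for five of the six categories (see the methods vignette for the
one divergent prey item).

The full pipeline, including the phylogenetic stages, runs from one config:

```r
run <- run_pipeline(list(prey_traits = "prey.csv", diet_records = "records.csv",
                         measurements = "meas.csv", tree = "tree.nwk",
                         nsim = 1000, seed = 1, out = "out/"))
```

or from the shell via `Rscript inst/cli/dietmorph.R run --config config.yml`.

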