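# actland

Quantitative comparison of three-dimensional activity landscapes (ALs)
of compound datasets.

## The problem

A 3D activity landscape places an interpolated potency surface over a
2D projection of chemical space: smooth terrain reflects continuous
structure-activity relationships (SARs), rugged terrain reflects SAR
discontinuity and activity cliffs. Landscapes are usually compared by
eye. `actland` makes the comparison quantitative: it renders each
landscape as a color-coded heatmap, reduces the heatmap to a small
distributional feature vector, and measures pairwise (dis)similarity
between datasets with information-theoretic and geometric distances.
It is aimed at medicinal chemists and cheminformaticians who need to
rank compound datasets by similarity of their SAR information content
— for example to pick a dataset rich in SAR discontinuity as a source
for compound optimization.

## Method

For a dataset of compounds with pKi potencies:

1. **Chemical space** — ECFP4 (2048-bit) fingerprints give pairwise
   Tanimoto distances `d = 1 − |a∩b|/|a∪b|`; metric MDS (SMACOF)
   embeds the compounds in 2D by minimizing
   `Σ_{i<j} (d_ij − ‖x_i − x_j‖)²`.
2. **Potency surface** — Gaussian-process regression with a
   `Matern(ν = 3/2) + White` kernel on standardized potencies;
   the ridge parameter `α` is selected from 10 log-spaced candidates in
   `[1e-7, 1e-1]` by maximum log marginal likelihood, with the kernel
   hyperparameters optimized at each candidate.
3. **Heatmap** — the posterior-mean surface is rasterized at 280 × 300
   pixels and colored along a green→yellow→red gradient with pKi
   anchors 3.72 / 5.75 / 8.75 (clamped outside); per pixel the combined
   RG intensity `(R − G)/255 ∈ [−1, 1]` encodes potency.
4. **Grid features** — a 56 × 60 grid yields 3360 cells of 25 pixels;
   mean cell intensities are binned into eight intervals from deepest
   valley `[−1, −0.75)` to highest peak `[0.75, 1]`. The eight counts
   are the landscape's feature vector (orientation-invariant).
5. **Similarity** — symmetric relative entropy
   `RE(p,q) = (KLD(p‖q) + KLD(q‖p))/2` on smoothed probabilities, and
   cosine distance `CD(x,y) = 1 − x·y/(‖x‖‖y‖)` on raw counts. Larger
   values = more dissimilar landscape topology.

## Worked example

```r
library(actland)
rugged <- generate_dataset(n_compounds = 150, n_series = 8,
                           ruggedness = 0.8, seed = 3)
smooth <- generate_dataset(n_compounds = 150, n_series = 8,
                           ruggedness = 0, seed = 4)
al_r <- activity_landscape(rugged$compounds, seed = 1, id = "rugged")
al_s <- activity_landscape(smooth$compounds, seed = 1, id = "smooth")
al_r
#> 3D activity landscape 'rugged'
#>   compounds: 150  pKi range: [ 3.68 , 10.5 ]
#>   MDS stress ratio: 0.0451  GPR alpha: 0.001  length scale: 0.0585
#>   cell counts (valleys -> peaks): 128 174 144 197 489 1048 603 577
al_compare(al_r, al_s)
#>     id_a   id_b        re         cd
#> 1 rugged smooth 0.1063864 0.05725588
```

The print method summarizes the fit: the MDS stress ratio (0.045 —
the 2D embedding reproduces the Tanimoto distances well), the selected
GPR ridge `alpha` and the short length scale the activity cliffs force
on the fit, and the eight cell counts from valleys to peaks.
`al_compare` reports the relative entropy (nats) and cosine distance
for the pair: the rugged and smooth landscapes differ visibly
(RE ≈ 0.11) compared with RE = 0 for identical landscapes.
The fitted object supports `summary()`, `coef()`, `predict()` (posterior
mean ± sd at new 2D coordinates), `plot()` (the heatmap), `residuals()`
and `simulate()` (posterior surface draws).

A command-line interface wraps the same pipeline:

```sh
AL=$(Rscript -e 'cat(system.file("cli", "al.R", package = "actland"))')
Rscript $AL simulate --out syn --n 700 --series 20 --ruggedness 0.8 --seed 1
Rscript $AL build --dataset syn_dataset.csv --fingerprints syn_fingerprints.tsv \
        --out run --seed 1 --id SYN
Rscript $AL compare run_features.json other_features.json --out pairs.csv
```

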