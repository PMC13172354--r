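# trajdyn

Quantifying gene-expression dynamics along single-cell differentiation
trajectories, plus two companion measurements used in engineered-skin
biology: FFT-based fiber/vessel alignment in micrographs and
Cutometer-style suction viscoelasticity ratios.

## Who this is for

Analysts who have already run trajectory inference (a 2-D embedding, a
principal graph, per-cell pseudotime) on single-cell RNA-seq data — for
example of fibroblast-to-pericyte differentiation in a human skin
equivalent — and want a tested, reusable implementation of the downstream
question: *which genes change systematically along the path, and which of
them mark the fate decision?*

## The method

Given a log-normalized expression matrix, an embedding, a principal graph
and pseudotime, the pipeline:

1. extracts the minimum-Euclidean-length node path between two chosen graph
   nodes;
2. selects the cells whose distance to the path polyline falls at or below
   the 20th percentile of all cell-to-path distances;
3. keeps genes detected (expression > 0) in ≥ 10% of selected cells;
4. fits LOESS (span 0.3, degree 2) of each gene's expression on pseudotime
   and scores it with the **dynamics range**

   Dynamics Range = (max ŷ − min ŷ) / (max y − min y),

   where y is observed expression and ŷ the LOESS fit;
5. classifies genes with score < 0.05 as *static* (0.1 for the
   fibroblast-branch preset) and drops them;
6. computes Spearman's ρ of each dynamic gene with pseudotime
   (Bonferroni-corrected over the dynamic family), reports the strict
   |ρ| > 0.7 set and the top 20 genes per direction as candidate
   fate-determining genes.

Cell-level QC (inclusive 1000–8000 detected features, mitochondrial
fraction strictly < 7%, with an in vivo preset of < 7500 features and
< 5%) and total-count log-normalization are included, as are a 2-D-FFT
radial-summation module (angular profile, fiber-axis peak angle after the
90° spectrum/fiber correction, and a (max − median)/median alignment
index) and suction-curve analysis (Uf, Ur, Ua, R2 = Ua/Uf, R7 = Ur/Uf).
A synthetic-data module generates all inputs with known ground truth.

## Worked example

```r
library(trajdyn)
library(dplyr)

ds  <- generate_trajectory_dataset(trajectory_sim_config(seed = 1))
path <- extract_path(ds$graph, "Y_1", "Y_20")
sel  <- select_cells_near_path(ds$embedding, path, percentile = 0.20)
res  <- run_dynamics_pipeline(ds$expression, sel, ds$pseudotime,
                              dynamics_config("pericyte"))
res
#> <gene_dynamics> 500 genes over 100 cells: 500 dynamic, 0 static, 0 degenerate; 2 with |rho| > 0.7

head(res$fate_up[, c("gene_id", "dynamics_range", "rho", "p_adjusted")], 3)
#> # A tibble: 3 × 4
#>   gene_id   dynamics_range   rho p_adjusted
#>   <chr>              <dbl> <dbl>      <dbl>
#> 1 gene_0037          0.771 0.753   8.13e-17
#> 2 gene_0001          0.673 0.678   4.54e-12
#> 3 gene_0040          0.651 0.667   1.76e-11
```

All 500 genes pass the 0.05 static cutoff here: with 20% dropout even
noise-only genes carry enough LOESS-trackable structure to clear it. What
separates truth from noise is the ranking — the |ρ| > 0.7 set and the top
of each direction list are simulated dynamic genes.

The top-ranked genes are simulated `dynamic_up` genes (`ds$truth`): their
logistic mean curves rise along pseudotime, so their Spearman ρ with
pseudotime is large and positive, their LOESS trend spans most of the
observed range (dynamics range ≈ 0.8), and the Bonferroni-adjusted p
values are tiny over the 100 selected cells. `autoplot(res)` draws the
leading gene's expression against pseudotime with its LOESS trend;
`tidy(res)` and `glance(res)` return the per-gene table and a one-row
summary.

Fiber alignment and viscoelasticity work the same way:

```r
fiber_alignment(generate_fiber_image(256, 256, angle = 30, coherence = 1, seed = 1))
#> <radial_profile> 180 bins, annulus [3, 115] px: peak at 29.5 deg, alignment index 20.3

compute_r_parameters(generate_suction_curve(uf = 0.3, elastic_fraction = 0.5,
                                            recovery_fraction = 0.8))
#> <r_parameters> Uf 0.3 mm, Ur 0.15 mm, Ua 0.24 mm, R2 0.8, R7 0.5
```

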