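# bandpop

Population-genetic analysis of dominant molecular markers (ISSR, RAPD,
AFLP) scored as binary band-presence matrices.

Dominant markers show a band whether an individual carries one or two
copies of the presence allele; only the double-null genotype shows
nothing. `bandpop` takes the resulting 0/1 band matrix (individuals ×
loci, grouped by primer, with population labels) and runs the standard
analysis chain for such panels, for breeders and population geneticists
characterizing germplasm collections:

* **Marker efficiency per primer** — TSB/PB/PPB bookkeeping, expected
  heterozygosity `H = 2p̄(1−p̄)`, `PIC = H − H²/2`, effective multiplex
  ratio `EMR = n·β`, marker index `MI = PIC·EMR`, resolving power
  `RP = Σ(1 − 2|0.5 − p|)`, Tessier's discriminating power `D`.
* **Diversity statistics** (POPGENE conventions) — allele frequencies
  via the HWE estimator `q̂ = √(1 − band frequency)` (Lynch–Milligan
  correction optional), per-locus Na, Ne, Nei's `h`, Shannon's `I`,
  and the partition statistics `Ht`, `Hs`,
  `Gst = (Ht − Hs)/Ht`, `Nm = 0.5(1 − Gst)/Gst`.
* **Distances and clustering** — Nei identity `I = Jxy/√(JxJy)` and
  distance `GD = −ln I` at individual or population level, UPGMA with
  deterministic tie-breaking and Newick export, Ward/Euclidean
  ordering for heatmaps.
* **Ordination** — covariance PCA of the band profiles (eigenvalues,
  % and cumulative % of variation, case scores) and the per-accession
  Shannon index (log₁₀ of the band count).
* **Bayesian admixture for dominant data** — a Gibbs sampler (Rcpp)
  for the STRUCTURE-style admixture model with Balding–Nichols
  correlated allele frequencies and the dominant-diploid observation
  model `P(band absent) = (Σₖ Q_ik(1 − P_kl))²`; per-cluster fixation
  indices `F_k`, `ln P(D) = mean(lnL) − var(lnL)/2`, Evanno
  `ΔK = |L″(K)|/sd(L(K))` model selection, Q-threshold purity
  classification (Q > 0.60), net nucleotide distances between
  clusters.
* **Synthetic data with ground truth** — `simulate_band_matrix()`
  generates band matrices from known admixture proportions and
  Balding–Nichols cluster frequencies, so every estimator above can be
  validated against truth.

## Worked example

```r
library(bandpop)

# a 44-accession, 11-population, 32-primer panel with K = 3 clusters
sim <- simulate_band_matrix(sim_config(seed = 42))
sim$bands
#> band_matrix: 44 individuals x 508 loci (32 primers, 11 populations)

pm <- primer_metrics(sim$bands)
head(pm[, c("primer","tsb","pb","ppb","h","pic","emr","mi","d","rp")], 3)
#>  primer tsb pb     ppb     h   pic   emr    mi     d    rp
#>     P01  11 10  90.909 0.424 0.334 7.231 2.414 0.897 2.455
#>     P02  15 12  80.000 0.500 0.375 7.345 2.753 0.992 5.909
#>     P03  11 11 100.000 0.487 0.368 6.386 2.353 0.965 4.682

pd <- partition_diversity(sim$bands)   # by population label
sprintf("Ht = %.3f  Hs = %.3f  Gst = %.3f  Nm = %.2f",
        pd$Ht, pd$Hs, pd$Gst, pd$Nm)
#> "Ht = 0.335  Hs = 0.181  Gst = 0.460  Nm = 0.59"

p <- pca(sim$bands)
sprintf("PC1 %.2f%%, PC2 %.2f%%", p$pct_variation[1], p$pct_variation[2])
#> "PC1 14.33%, PC2 12.80%"

fit <- admixture_fit(sim$bands, K = 3,
                     admixture_config(burnin = 1000, sweeps = 3000),
                     seed = 42)
fit
#> admixture fit: K = 3, lnPD = -8418.6
#>   F_k: 0.399, 0.234, 0.386
```

Here `Gst = 0.46` says 46% of the total gene diversity lies between
population samples, the implied gene flow is below one migrant per
generation, and the fitted per-cluster fixation indices (0.23–0.40,
"great" to "very great" differentiation on the conventional scale)
recover the simulated `F = (0.19, 0.37, 0.40)` up to posterior spread.
A full run — all reports, Newick tree, Evanno scan, membership tables,
plus a reproducibility manifest — is one call:

```r
res <- run_pipeline(pipeline_config(out_dir = "run1", seed = 42))
```

`issr_reference_panel()` returns bundled published per-primer summary
tables (32 ISSR primers scored on 44 Bambara groundnut accessions) used
as worked-example inputs by the test suite.

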