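---
title: "Models and methods behind bandpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bandpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandpop)
```

## The data and the problem

Dominant molecular markers — ISSR, RAPD, AFLP — are scored as the
presence (1) or absence (0) of an amplified band. A band is the dominant
phenotype of a diploid genotype: the individual shows the band whether it
carries one or two copies of the presence allele, and shows nothing only
when both copies are null. The whole analysis therefore starts from a
binary *band matrix* (individuals × loci, grouped by amplifying primer,
with a population label per individual) and everything downstream must
respect the information loss of dominance: genotypes are not observed,
only phenotypes.

`bandpop` implements the standard analysis chain for such panels —
marker-efficiency indices per primer, POPGENE-style diversity and
differentiation statistics, Nei distance with UPGMA and Ward clustering,
covariance PCA, and a Bayesian admixture model for dominant diploid data
with Evanno ΔK model selection — plus a generative simulator so that
every stage can be validated against known ground truth.

## Allele frequencies from dominant phenotypes

Under Hardy–Weinberg equilibrium the band-absent phenotype frequency is
$q^2$, so the null-allele frequency is estimated as
$\hat q = \sqrt{1 - \bar x}$ with $\bar x$ the observed band frequency
(`estimate_allele_freq()`). The Lynch–Milligan small-sample adjustment is
available behind a flag but off by default: for panels of this kind the
uncorrected square-root estimator is the convention of the programs
practitioners use, and which correction (if any) a given published table
used is generally unknowable. Per-locus diversity follows directly:
$N_e = 1/(p^2+q^2)$, Nei's $h = 1-p^2-q^2$, Shannon's
$I = -p\ln p - q\ln q$ (natural log, so $I \le \ln 2 \approx 0.693$).

For population partitions, $H_S$ is the unweighted mean over groups of
$2 p_g q_g$ and $H_T = 2\bar p\bar q$ with $\bar p$ the unweighted mean
of group frequencies — the equal-weight convention matches equal-sized
sampling designs (4 individuals per population in the reference panel);
a size-weighted variant is a flag. The headline
$G_{ST} = (\bar H_T - \bar H_S)/\bar H_T$ is the ratio of means (Nei's
definition, more stable than averaging per-locus ratios; both are
reported), loci monomorphic overall are skipped, and gene flow is
$N_m = 0.5\,(1-G_{ST})/G_{ST}$.

## Marker-efficiency indices

Per primer: TSB (loci scored), PB (loci with both states among
non-missing scores; a minor-frequency threshold is available but off by
default so that a single discordant individual makes a locus
polymorphic), PPB = 100·PB/TSB. H and PIC use a *single pooled band
frequency* over the primer's polymorphic loci,
$H = 2\bar p(1-\bar p)$ and $\mathrm{PIC} = H - H^2/2$ (the bi-allelic
Botstein form). The pooled-frequency choice is deliberate: published
per-primer tables of this kind satisfy $\mathrm{PIC} = H - H^2/2$
exactly row by row, which only a single pooled bi-allelic frequency
produces; a per-locus average would break the identity. EMR is
$n\beta$ (mean bands per individual times the polymorphic fraction),
MI = PIC·EMR, resolving power $R_P = \sum_b (1 - 2|0.5 - p_b|)$, and
discriminating power is Tessier's
$D = 1 - \sum_i p_i (N p_i - 1)/(N-1)$ over full multi-locus banding
patterns. Havp is the mean per-locus $2p(1-p)$ over polymorphic loci —
note that published Havp columns for such panels are often on an
inconsistent scale (~10⁻⁴) that no variant of the printed formula
reproduces, so Havp is computed per its formula and not used in any
numerical cross-check.

## Distances and trees

Nei's normalized identity is $I = J_{xy}/\sqrt{J_x J_y}$ with
$J_{xy}$ the mean over loci of $p_x p_y + q_x q_y$, and distance
$GD = -\ln I$. At the individual level the 0/1 band states are used
directly as frequencies (the GenAlEx convention for dominant data; the
Nei 1978 "unbiased" correction is undefined for single individuals, so
the original 1972 measure is used there and the correction is an option
at the population level only). Two fully mismatched profiles give
$I = 0$, $GD = \infty$; infinite distances are reported as such and
capped (default 10) only when a tree must be built.

UPGMA is implemented in the package rather than delegated: node height
is half the merged distance, the new cluster's distances are
size-weighted arithmetic means, and ties are broken by the
lexicographically smallest pair of cluster labels so the tree (and its
Newick serialization) is identical across platforms. An independent
implementation (`hclust(..., "average")`) serves as a cross-check in the
test suite, which would be meaningless if it were also the
implementation. Ward linkage for heatmap ordering, by contrast, is the
standard Lance–Williams `ward.D` update on unsquared Euclidean
distances and is delegated to `stats::hclust`.

PCA is covariance PCA on mean-centred 0/1 columns (divisor $n-1$),
with missing scores imputed by the locus mean beforehand; eigenvalues on
this scale are far below the locus count, matching the conventions of
the ordination programs used for such panels. Axis signs are fixed by
making the largest-magnitude loading positive. The per-accession
Shannon index is the equal-weight entropy of the presence profile in log
base 10, which for binary data is exactly $\log_{10}$(bands present) —
published tables never define this index, and this reduction reproduces
the 1.86–2.01 range seen for ~500-locus profiles, so it is documented
prominently as a reconstruction.

## The admixture model

The sampler targets the STRUCTURE-style admixture model with correlated
allele frequencies, specialized to dominant diploid data. Each
individual $i$ carries admixture proportions $Q_i$ (Dirichlet(α) prior,
α fixed at 1 by default); each cluster $k$ has band-allele frequencies
$P_{kl}$ drawn around ancestral frequencies $p_l$ by the
Balding–Nichols prior
$\mathrm{Beta}\!\big(p_l\tfrac{1-F_k}{F_k},\,(1-p_l)\tfrac{1-F_k}{F_k}\big)$,
so $F_k$ is a per-cluster fixation index. The observation model is
dominance itself: a band is absent iff both latent allele copies are
null, $P(x=0\mid Q_i,P) = \big(\sum_k Q_{ik}(1-P_{kl})\big)^2$.

One Gibbs sweep: (a) sample each copy's cluster of origin and allelic
state from its full conditional given the band (for a present band the
pair is drawn conditioned on "not both null"); (b) update every
$P_{kl}$ from its Beta full conditional; (c) update the ancestral
frequencies $p_l$ by per-locus random-walk Metropolis on the logit
scale; (d) update every $Q_i$ from its Dirichlet full conditional; (e)
update every $F_k$ by logit-scale random-walk Metropolis under a
Uniform(0.001, 0.999) prior; (f) accumulate the log-likelihood.
Posterior means over post-burn-in sweeps are returned. Step (c) is
essential, not cosmetic: fixing $p_l$ at the pooled sample estimate
anchors the prior to a size-weighted average of the cluster
frequencies, which systematically understates the divergence of the
largest cluster — in calibration runs the true $F = 0.19$ of a
24-individual cluster was estimated near 0.09 with fixed ancestral
frequencies and within the expected posterior spread once they are
sampled. The narrow-support alternative prior for $F$ (mean ~0.01, as
some programs default to) is rejected for the same reason: simulated
panels in the 0.2–0.4 range must be reachable within desk-scale chains.

Model selection uses $\ln P(D) = \overline{\ln L} -
\mathrm{var}(\ln L)/2$ per run and the Evanno statistic
$\Delta K = |L''(K)|/\mathrm{sd}(L(K))$ across replicate runs, with the
best $K$ the argmax over the interior of the scanned range. Membership
is classified pure in cluster $k$ iff $Q_{ik} > 0.60$ (strictly, so a
value of exactly 0.60 is admixed). Label switching across runs is
undone by exact permutation matching of Q columns (enumeration for
$K \le 7$, greedy beyond). Cluster divergence is summarized by
within-cluster expected heterozygosity and the net nucleotide distance
$d_{AB} = \pi_{AB} - (h_A + h_B)/2$ from the point estimates of $P$.
Fixation indices are labelled with the conventional bands
(little/moderate/great/very great at 0.05/0.15/0.25).

Defaults are desk-scale — burn-in 2,000, 10,000 sweeps, 5 runs per K —
chosen so that a full K = 1..6 scan of a 44 × 500 panel completes in
minutes on one CPU while posterior means are stable to the second
decimal; production-scale settings (10⁵ burn-in, 10⁶ sweeps, 10 runs)
are plain configuration values.

## The synthetic generator and what passing tests mean

`simulate_band_matrix()` realizes exactly the model above: ancestral
frequencies Uniform(0.1, 0.9) (avoiding near-fixed loci, where
square-root frequency estimation is unstable), Balding–Nichols cluster
frequencies, admixture rows either one-hot (population-to-cluster map)
or Dirichlet(α), diploid dominant phenotype sampling under HWE, and
uniform random masking for missingness. Its defaults mirror the
reference study design this package ships worked examples for: 11
populations × 4 individuals, 32 primers of 11–22 loci (~510 loci),
K = 3 with F = (0.19, 0.37, 0.40), populations mapped 6/2/3 to the
three clusters. One seeded RNG stream drives panel layout, frequencies,
admixture and band sampling in that documented order, so identical
configurations are bit-identical.

The generator deliberately omits features of real ISSR panels: linkage
between loci of one primer, scoring error and band co-migration,
selfing (the reference accessions are S4 inbred lines, so HWE sampling
is an idealization), and any mutation process. Recovery tests on this
generator therefore validate the estimators under their own model
assumptions — they show internal correctness, not robustness to
violations of HWE or locus independence.

Validation problem sizes are the package's own choices: Gst recovery
uses 2 × 100 individuals × 500 loci (20 replicates; the dominant-data
Gst tracks the truth-implied differentiation within ±0.06), fixation
recovery uses 60 individuals × 300 loci with F ∈ {0.2, 0.4} (±0.08
over 5 seeds), Evanno uses 44 × 150 loci with 4 runs × K = 1..5
(argmax ΔK = 3 in at least 4 of 5 experiments — with populations mapped
6/2/3 the 8-individual cluster is occasionally absorbed at ΔK = 2,
which is faithful to how the statistic behaves on unbalanced designs),
and the UPGMA 3-cluster cut matches the simulated clusters for ≥90% of
individuals in ≥90% of replicates.

## Numerical choices and edge cases

* Non-binary cells, duplicate ids and unassigned loci are rejected at
  construction with the offending coordinates; missing scores are `NA`
  in files and −9 in STRUCTURE export.
* `count_bands()` treats a locus as polymorphic when both states occur
  among non-missing scores; a frequency threshold is available.
* A primer with no polymorphic locus has EMR = 0, Havp = 0 (with a
  warning) and no pooled frequency (error) — degenerate by design.
* Gst skips loci with $H_T = 0$; $G_{ST} = 0$ reports $N_m = \infty$
  with a warning; a single group is an error.
* Sampled frequencies in the Gibbs sampler are clamped to
  $[10^{-9}, 1-10^{-9}]$ to keep Beta densities finite.
* Evanno requires a contiguous K range of length ≥ 3 and ≥ 2 runs per
  K; zero run-variance makes ΔK undefined at that K (warned, `NA`).
* UPGMA merge ties are resolved by smallest label pair; Newick output
  uses 10 significant digits by default.

## Known limitations

Individual-level "Nei" distances on 0/1 profiles are a field convention
rather than a statistically motivated estimator (the unbiased correction
does not exist for n = 1). The admixture sampler is a single-chain
Gibbs scheme without tempering; at very small K ranges or very weak
structure, ΔK inherits the known instabilities of the Evanno method
(undefined at the range ends, sensitive to run variance). Havp is
computed per its formula but has no reliable published comparator. The
per-accession Shannon index is a documented reconstruction of an
undefined published quantity.
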