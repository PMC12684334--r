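# CloneScape

Population-genomic analysis of partially clonal organisms — brown
seaweeds and other taxa in which a sampled individual (a *ramet*) may be
a physical copy of a genetic individual (a *genet*). The package takes
biallelic SNP dosage matrices with site labels and provides, end to end:

- **Clone detection.** Pairwise genetic distance as the proportion of
  allelic differences, `d(a,b) = Σ_l |g_a,l − g_b,l| / (2 L_ab)` over
  pairwise-complete loci; an automatic distance-cutoff predictor based
  on the gap structure of single-linkage merge heights; and contraction
  of individuals into multilocus genotypes (MLGs ≈ genets) as connected
  components at the chosen threshold.
- **Per-site evolvability.** Clonal richness `R = (G − 1)/(N − 1)`, the
  multilocus inbreeding coefficient `F_IS = 1 − ΣH_o / ΣH_e` (with
  `H_e = 2p(1−p)`; strongly negative values flag fixed-heterozygote
  clones), and the standardised index of association `r̄_d` with a
  locus-permutation null — near 0 under free recombination, inflated
  under clonality.
- **Individual structure.** Dosage PCA, ancestry coefficients by
  simplex-constrained non-negative matrix factorisation with
  masked-cell cross-entropy for choosing K, and neighbour-joining trees
  with locus-bootstrap support.
- **Demographic inference.** Two-population divergence histories on the
  (folded) joint site frequency spectrum: a registry of the 22
  SI/IM/AM/SC scenarios with growth (G), linked-selection (2N) and
  barrier-locus (2m) variants; expected spectra from a compiled
  structured-coalescent engine; composite Poisson likelihood with
  analytic spectrum scaling; three-step optimisation; AIC ranking with
  the conservative ΔAIC < −10 rule; conversion to years and effective
  sizes (generation time 4 y, μ = 1×10⁻⁸ by default).
- **Seascape connectivity.** Multi-generation stepping-stone
  connectivity `P̃^g` (or its cumulative mean) from a row-stochastic
  per-generation dispersal matrix, with basin-asymmetry summaries.
- **Morphometrics.** Undulation index (margin arc length over chord),
  trait PCA, and congruence between morphological and genetic site
  dendrograms (cophenetic correlation, Robinson–Foulds distance).

A synthetic-data module (`simClonalSite`, `simMetapopulation`,
`simDivergence`, `simDispersal`, `simMorpho`) generates inputs with
known truth — clone partitions, target F_ST, divergence parameters,
advective asymmetry, trait lineages — so every stage is testable.

## Worked example

```r
library(CloneScape)

# a partially clonal site: 8 genets sampled as 5 ramets each, with a
# 0.5% per-allele genotyping error rate
cs  <- simClonalSite(n_genets = 8, ramets_per_genet = 5, n_loci = 600,
                     error_rate = 0.005, seed = 29)
d   <- pairwiseDistance(cs$snp)
thr <- predictCutoff(d)
mlg <- contractMLGs(d, thr, m = cs$snp)
mlg
#> MLGAssignment: 8 genets among 40 individuals (threshold 0.1442)
clonalRichness(mlg)
#> [1] 0.1794872
fis(cs$snp)$fis
#> [1] -0.02913467
indexAssociation(cs$snp, n_perm = 99, seed = 1)[c("rbarD", "p")]
#> $rbarD
#> [1] 0.09559972
#> $p
#> [1] 0.01
```

The predictor lands the threshold (0.144) in the gap between the
ramet-pair distances (at most 0.018 here, about twice the per-allele
error rate) and the genet-pair distances (0.28 and up), so all 8 genets
are recovered; R = 7/39 reflects the heavy cloning; F_IS is pulled
slightly negative and `r̄_d` is elevated with a significant permutation
p — the multilocus signature of clonal reproduction.

A demographic comparison on synthetic spectra:

```r
sim <- simDivergence("SC", c(N1 = 1, N2 = 1, Ts = 4, m12 = 2, m21 = 2,
                             Tfrac = 0.1), n1 = 6, n2 = 6,
                     n_loci = 50000, seed = 77, theta_locus = 0.2,
                     fold = TRUE)
fits <- lapply(c("SI", "SC"), function(mod)
  fitDemography(sim$sfs, mod, n_fits = 2, seed = 5, n_loci_mc = 12000,
                n_random = 40, maxit = c(250, 100)))
compareModels(fits)
#>   model k    loglik      AIC  deltaAIC stronger
#> 1    SC 7 -2136.505 4287.010 -1444.169     TRUE
#> 2    SI 4 -2861.589 5731.179  1444.169    FALSE
```

Secondary contact is flagged as the stronger history by a wide margin
under the ΔAIC < −10 rule.

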