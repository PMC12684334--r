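---
title: "CloneScape: models, defaults and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CloneScape: models, defaults and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CloneScape)
```

CloneScape analyses partially clonal populations: organisms in which a
sampled thallus (a *ramet*) may be a physical copy of a genetic
individual (a *genet*), so that the sample mixes sexually recruited
genotypes with repeated ones. This vignette is the package's own
account of the models behind each module, the defaults and their
rationale, and the numerical choices that were genuinely open.

## Data model

Genotypes are biallelic SNP dosages (0/1/2 ALT copies, `NA` missing)
in a `SNPMatrix`, a `SummarizedExperiment` with loci as rows,
individuals as columns, and the sampling site in `colData`. Ploidy is
fixed at 2. All downstream denominators use pairwise- or
locus-complete counts; no statistic silently imputes except where
stated below.

Filtering (`filterSNPMatrix`) applies three rules to a fixed point:
drop loci with missingness strictly above 5%, then individuals
strictly above 5%, then loci that are no longer polymorphic. The order
locus → individual → monomorphic, iterated until stable, makes the
operation deterministic and idempotent; the thresholds are arguments.
A companion diagnostic (`hetMissingDiag`) regresses individual
heterozygosity on missingness and flags outliers beyond k MAD
(default 3), the standard screen for individuals whose heterozygosity
is an artefact of missing data.

## Clone detection

The distance between two individuals is the proportion of allelic
differences over loci typed in both: a heterozygote differs from
either homozygote by one allele and opposite homozygotes by two, so
`d = Σ|g_a − g_b| / (2 L_ab)`. Distances in partially clonal samples
are bimodal: a low mode of ramet pairs (technical and somatic noise
only) and a high mode of genet pairs. `predictCutoff` works on the
single-linkage merge heights, restricts attention to heights at most
`fraction` (default 0.5) of the maximum, and returns the midpoint of
the largest gap from such a height to the next, ties broken towards
the lowest height. Searching merge heights rather than raw pair
distances makes the statistic insensitive to the quadratic
over-counting of large-cluster pairs. `contractMLGs` then takes
connected components of the at-most-threshold graph (single linkage)
— the transitive closure mirrors how merge heights were computed, and
the representative of each genet is its lowest-missingness member.

Clone statistics are intended per site: repeated genotypes between
sites are biologically distinct genets, so `siteStats` contracts and
summarises within each locality.

## Per-site evolvability

`fis` excludes within-site monomorphic loci and reports per-locus
`f_l = 1 − H_o/H_e` with `H_e = 2p(1−p)` and the multilocus
`F_IS = 1 − ΣH_o/ΣH_e`. The small-sample `2n/(2n−1)` correction is
available behind `unbiased = TRUE` but off by default: without it a
site consisting of one heterozygous clone gives exactly −1, the
canonical fixed-heterozygosity signature, rather than a
sample-size-dependent value.

`indexAssociation` computes `I_A = V_O/V_E − 1` and the standardised
`r̄_d = (V_O − V_E) / (2 Σ_{l<m} √(v_l v_m))` from per-pair per-locus
dosage differences, using the population-variance convention (divide
by the number of pairs) consistently in `V_O`, `V_E` and the
denominator; an enumeration oracle in the test suite pins this
convention down. Missing dosages are mean-imputed per locus first —
after the 5% filters this touches few cells and keeps every pair
comparable. The permutation null shuffles each locus column
independently across individuals, destroying inter-locus association
while preserving locus-wise genotype frequencies; the p-value uses the
add-one rule. Defaults of 999 permutations are a convention choice,
not an estimate.

One degenerate case is worth knowing: a site that is literally a
single genet varies only by independent genotyping errors, which carry
no inter-locus association, so its `r̄_d` is near zero even though the
site is maximally clonal. The clonal LD signal requires at least two
repeated genotypes; the package's monotone-clonality checks therefore
use a two-genet fixture as their high-clonality endpoint.

## Individual structure

`snpPCA` mean-imputes per locus, centres, optionally scales by the
binomial standard deviation `√(p(1−p))`, and orients every component
so its largest-magnitude loading is positive (a deterministic sign
convention). When an `MLGAssignment` is supplied, only one individual
per genet enters — repeated genotypes otherwise dominate the leading
components.

`ancestryNMF` one-hot encodes genotypes (three classes per locus) and
factorises X ≈ QG with Q rows on the probability simplex (ancestry
proportions) and each cluster's per-locus genotype triple in G on the
simplex too. The fit alternates projected-gradient steps (Duchi
simplex projection) with backtracking line search, which guarantees a
monotone objective while keeping both constraint sets satisfied after
every iteration — a property the tests assert on the recorded trace.
Initialisation is Dirichlet(1) rows for Q and perturbed empirical
genotype profiles for G; convergence at relative objective change
below 1e−6 or 200 iterations; the best of `reps` restarts by objective
is kept. K is chosen by the cross-entropy of a 5% held-out cell mask
(`selectK`); with the same seed the mask is identical across K, making
the profile comparable.

`njTree` wraps the standard neighbour-joining agglomeration with
lowest-index tie-breaking, clamps negative branch lengths to zero
(flagged in an attribute), and obtains support by resampling loci with
replacement, rebuilding distance and tree per replicate, and counting
split recovery. Ramets appear as leaves on near-zero terminal
branches, the visual signature of clonal clusters.

## Demographic inference

The model space is the classical two-population family: strict
isolation (SI), isolation with continuous migration (IM), ancestral
migration (AM: gene flow only between the split and a later
cessation), and secondary contact (SC: gene flow only in a recent
window), each with variants for asymmetric exponential growth since
the split (G), a two-class effective-size mixture capturing linked
selection (2N: proportion Q of loci at a reduced size factor), and —
for the migration histories — a two-class migration mixture capturing
barrier loci (2m: proportion P at a reduced migration factor). That
yields 4 SI + 6 IM + 6 AM + 6 SC = 22 scenarios in `modelRegistry`.

Expected spectra come from a compiled structured-coalescent engine
rather than a diffusion solver: `n_loci` independent genealogies are
simulated backward in time (per-pair coalescence rate `1/N_i(t)`,
per-lineage migration `m_ij`, time in units of 2 N_ref generations)
and the branch-length-weighted spectrum is accumulated — cell (i, j)
collects the total length of branches subtending i samples from
population 1 and j from population 2, proportional to the expected
site count under infinite-sites mutation. The epoch boundary times for
AM/SC are parameterised as a fraction `Tfrac` of the split time, which
keeps the constraint `0 < Tm < Ts` built into the box.

Three numerical choices matter here:

- **Scale anchoring.** The spectrum scaling θ is profiled out
  analytically (`θ̂ = Σobs/Σmodel`), so a free ancestral size would sit
  on an exact ridge — multiplying all sizes and times by c and
  dividing migration by c leaves the spectrum shape unchanged. Sizes
  and times are therefore expressed relative to the ancestral
  population (the usual θ-scaled convention); the registry does not
  free `Na`. The engine still supports an ancestral size epoch
  (spanning one split-time before the split) for custom models.
- **Common random numbers.** Each locus draws from its own
  deterministic substream keyed on (seed, locus). A parameter change
  then perturbs each locus's genealogy locally instead of
  desynchronising every other locus, making the Monte Carlo objective
  piecewise smooth — without this the optimiser stalls in simulation
  noise.
- **Masking.** The composite Poisson likelihood excludes the
  fixed-in-both corners and, for folded spectra, the structurally
  empty half; Monte Carlo zeros are floored at 1e−10 of the spectrum
  total.

`fitDemography` runs, per replicate fit: a broad log-uniform scan of
the parameter box, Nelder-Mead refinement from the top three scan
points on a logit-of-box scale, and perturbation restarts around the
refined optimum; 20 replicate fits by default, best kept. AIC counts
the free parameters plus one for the scaling, and `compareModels`
flags a model as stronger only when it beats its best competitor by
more than 10 AIC units. `toBiologicalUnits` anchors
`N_ref = θ̂/(4μL)` and converts with a 4-year generation time and
μ = 1×10⁻⁸ per base per generation by default.

Folding is keyed on the pooled minor allele (cells at exactly half the
pooled total are averaged once), which is idempotent and
total-preserving. Folding discards the ancestral-state information
that anchors the absolute scale, so parameter-recovery validation in
the test suite fits unfolded spectra (legitimate for simulated data,
where derived states are known); model discrimination (for example SC
against SI) is robust on folded spectra and is validated that way.

## Connectivity

`multigenConnectivity` masks non-habitat sites, renormalises rows, and
iterates the per-generation kernel. Because the accumulation rule
behind "multi-generation connectivity" admits two readings, both are
implemented and labelled: `power` (the g-step transition matrix, the
default) and `cumulative` (the mean of the first g powers, a
path-visiting interpretation). Rows are renormalised after every
multiplication so stochasticity holds to within accumulated round-off.
The asymmetry summary totals probability mass leaving a supplied
region against mass entering it — the advective-basin signature.
Heatmap export transposes to the columns-as-source convention common
in seascape figures.

The synthetic kernel (`simDispersal`) is a discretised Gaussian on a
1-D coastline with its mean shifted downstream by the advection
parameter; kernel mass falling off the coastline stays at the source,
so the zero-advection kernel is exactly symmetric and the direction of
asymmetry is known by construction.

## Morphometrics

The undulation index is the arc length of a traced branch margin over
its endpoint chord — 1 for a flat margin, π/2 for a semicircular one —
and is invariant to rigid motions and scaling. Individuals carry the
mean of three branch measurements, which is how the synthetic
generator structures its draws (UX draws are floored at 1, the
geometric minimum). Site dendrograms use average linkage on Euclidean
distances of z-scored site trait means; neither the linkage nor the
distance is canonical, so both are arguments. Congruence with the
genetic site tree is reported as cophenetic correlation plus
Robinson–Foulds distance — a quantitative stand-in for the visual
comparison of paired dendrograms.

## Synthetic data: what it does and does not emulate

The generators define the package's study conditions. `simClonalSite`
draws genet base frequencies Uniform(0.05, 0.95) so within-site
polymorphism is near-certain (F_IS and r̄_d need polymorphic loci),
models genotyping error as independent per-allele flips — giving
replicate discordance a closed form the tests verify — and masks cells
completely at random. `simMetapopulation` uses the Balding–Nichols
Beta construction, whose realised Hudson F_ST lands within a few
hundredths of the target at a few thousand loci. `simDivergence`
shares the coalescent engine with inference, so the returned spectrum
equals the spectrum rebuilt from the returned genotypes exactly; the
independent check against a second coalescent implementation (msprime)
lives in the test suite.

Real 2b-RAD data differ in ways these fixtures do not capture: linked
loci on a physical genome, coverage-dependent and genotype-dependent
missingness, allele-balance genotyping bias, and somatic mutation
within clones. Passing tests therefore demonstrate correctness of the
statistics under their stated models, not robustness to every
real-data pathology.

Problem sizes in the test suite (tens of individuals, hundreds of loci
for clone statistics; 5×10⁴ loci and 6+6 diploids for demographic
validation; 12 000 Monte Carlo genealogies per likelihood evaluation
with 2 replicate fits) were chosen as the smallest designs at which
the validated effects are decisively resolved, and are stated here as
the package's reference experimental design.

## Known limitations

- The coalescent engine supports at most 64 haploid samples per
  spectrum (bitmask representation); joint spectra beyond 33×33 cells
  need projection upstream.
- Migration parameters of the 2m variants share one reduction factor
  across both directions; fully direction-specific barrier effects
  would double the class parameters.
- The cutoff predictor needs a visible gap: samples with continuous
  somatic divergence (no bimodality) should be thresholded manually.
- `F_IS` and `r̄_d` are multilocus summaries; no per-locus-pair LD map
  is provided by design.
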