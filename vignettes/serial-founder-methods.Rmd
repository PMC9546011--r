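---
title: "Methods: reconstructing serial founder expansions from SNP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing serial founder expansions from SNP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacifex)
```

# The problem

Island range expansions — a large continental source population founding a
colony, which may itself found further colonies — leave a characteristic
footprint in genome-wide SNP data: diversity (π, H~O~) decreases along the
colonization chain, Tajima's *D* flips from negative (a large, recently
grown source) to positive (bottlenecked colonies), shared derived alleles
drift to higher frequencies in the colonies (the directionality index ψ),
and differentiation accumulates where migration has ceased (F~ST~,
isolation by distance). `pacifex` implements this full analysis stack for
diploid biallelic SNP panels — the kind produced by RAD sequencing — plus a
demographic-inference layer that fits founder-event models to the joint
site frequency spectrum (SFS), and a structured-coalescent simulator that
generates complete synthetic data sets with exactly this structure.

All coalescent-scaled quantities follow one convention: time runs backward
from the present in units of $2N_{\mathrm{ref}}$ generations, deme sizes
$\nu$ are relative to $N_{\mathrm{ref}}$, migration rates are
$M = 2N_{\mathrm{ref}}m$ with $m$ the fraction of the receiving deme
replaced per generation, and $\theta = 4N_{\mathrm{ref}}\mu L$.

# Data model and filtering

A `genotype_matrix` stores samples × loci alternative-allele counts
(0/1/2/`NA`) with per-locus chromosome, position and alleles. Three filters
mirror standard RAD practice:

* **Call rate** — samples genotyped at <75% of loci are removed (the
  default threshold applied before diversity and F~ST~ work).
* **Minor allele frequency** — loci with MAF < 0.05, computed over
  *observed* gene copies, are removed. The threshold is inclusive (a locus
  at exactly 0.05 is retained); allele frequencies always skip missing
  calls.
* **Linkage thinning** — loci are visited in a seeded random order and
  accepted only if no previously accepted locus on the same chromosome
  lies within 10 kb. This is a random maximal conflict-free subset, not a
  maximum one: we prioritise an unbiased draw over squeezing out a few
  extra loci.

The Hardy–Weinberg exact test (`hwe_exact_test`) evaluates Levene's
conditional distribution of heterozygote counts with the stable ratio
recurrence and sums the probabilities of all configurations no more
probable than the observed one. Being an exact test on discrete data it is
conservative: rejection rates sit at or below the nominal level.

# Spectra

`build_joint_sfs` polarizes each locus against an outgroup base: if the
outgroup matches exactly one of the two alleles, that allele is ancestral;
loci with missing focal calls or an uninformative outgroup are dropped and
tallied. Projection to smaller sample sizes uses the exact hypergeometric
redistribution
$\xi'_j = \sum_i \xi_i \binom{i}{j}\binom{n-i}{m-j}/\binom{n}{m}$,
which preserves expectations, is linear, and composes
($n \to m \to k$ equals $n \to k$). The all-ancestral and all-derived
corners are always masked — they are unobservable in SNP data and the
Poisson likelihood must not see them. Spectra read and write the standard
dadi text format (shape header with a folded/unfolded flag, C-order data
line, mask line).

# Summary statistics

* **π and H~O~** are averages over SNP loci (per-SNP scale). Per-locus
  $\hat\pi = \frac{2n}{2n-1} 2\hat p(1-\hat p)$ with $n$ the diploids
  genotyped there. Per-base π would require invariant-site counts that a
  SNP panel does not carry.
* **Tajima's D** is computed from a one-population spectrum,
  $D = (\hat\pi - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ with the 1989
  constants; the pairwise-difference weights $i(n-i)$ are symmetric, so
  folded spectra give identical values. $S = 0$ is reported as undefined,
  never as a number.
* **F~ST~** is the Weir–Cockerham (1984) estimator: per-locus variance
  components $a$ (among populations), $b$, $c$, combined across loci as
  $\hat\theta = \sum a / \sum (a+b+c)$. Significance comes from permuting
  individuals between the two populations with group sizes preserved
  (without replacement — the standard exchangeability null), with
  $p = (1 + \#\{\theta^* \ge \theta\})/(1 + n_{\mathrm{perm}})$ so p is
  never exactly zero. Note that the estimator's finite-sample correction
  makes $\hat\theta$ *negative* when the two samples are identical: its
  null distribution is centred near zero, not floored at it.
* **ψ** (directionality index) is the mean derived-frequency difference at
  shared polymorphisms between two equally sized populations:
  cells with the derived allele present in both (i, j ≥ 1), excluding
  fixed-in-both, contribute $(j - i)/n$ weighted by their site counts.
  Positive ψ~A→B~ means B carries shared derived alleles at higher
  frequency — the signature of B being the colony. Equal sample sizes are
  required; project the spectrum first (the standard choice here is 10
  gene copies per population).
* **Evanno's ΔK** is
  $|\bar L(K+1) - 2\bar L(K) + \bar L(K-1)| / \mathrm{sd}(L(K))$ over
  clustering replicates; zero replicate variance yields an explicitly
  *undefined* ΔK (a real situation when replicate likelihoods are
  identical), flagged rather than propagated as NaN.

# Distances, trees and isolation by distance

Edwards' angular distance treats each individual as a two-allele
"population" with frequencies 0, ½, 1:
$D = \sqrt{1 - \frac{1}{L}\sum_l \sum_u \sqrt{p_{xu} p_{yu}}}$ over loci
genotyped in both samples. Identity-by-state distance is the mean of
$|g_x - g_y|/2$. Geographic distances are haversine great circles with
Earth radius fixed at 6371.0 km. The Mantel test correlates off-diagonal
entries and permutes rows+columns of one matrix jointly; we use the
one-sided (greater) alternative because isolation by distance predicts a
*positive* association. Neighbour-joining trees come from the Saitou–Nei
agglomeration (via ape), with negative branch lengths clamped to zero and
flagged.

# The coalescent engine

Both the synthetic-data generator and the expected-SFS engine are one
structured-coalescent simulator (C++): lineages carry their deme and
descendant set; coalescence in deme $d$ occurs at rate
$\binom{k_d}{2}/\nu_d(t)$, backward migration at the scaled rates, and
discrete events (founding joins, admixture pulses) fire at their scheduled
times. Time-varying sizes (exponential or logistic epochs) are handled by
*thinning*: candidate events are proposed at the maximal rate over a
window within which no coalescing deme's size can fall below half its
current value, and accepted with probability actual/bound. This is exact
(no per-generation discretisation, no integral inversion) and its
acceptance rate is at least one half by construction. The logistic curve
is parameterised by the epoch's final size as carrying capacity, with the
recent end anchored at 99% of capacity and the rate implied by the epoch
duration.

For the expected SFS, the branch length subtending exactly $(i, j)$
sampled copies accumulates into cell $(i, j)$; averaged over genealogies
and divided by two this is the expected spectrum per unit θ (a branch of
length $t$ in $2N$-generation units carries $t\theta/2$ expected
mutations). The engine was cross-validated cell-by-cell against msprime on
a two-deme split scenario (see the test suite). For data sets, mutations
fall on completed branches as a Poisson process (infinite sites); by
default one SNP per locus is retained, mimicking RAD loci and making loci
approximately independent, as the thinning step downstream assumes.
Genotypes pair consecutive gene copies; missingness is uniform at random;
the reference allele is deliberately *not* always the ancestral one
(a fair coin decides), so polarization is genuinely exercised.

The serial-founder preset chains demes each founded from its predecessor
(default founding fraction 0.02, founding interval 0.1, adjacent-deme
scaled migration 0.05, post-founding exponential growth back to size 1),
with coordinates on a line for IBD work. These defaults are the package's
standard study conditions: a strong but partial bottleneck with rapid
recovery and weak ongoing gene flow — the regime in which stepwise island
colonizations leave detectable ψ, diversity and D gradients.

# Demographic inference

Four two-population founder models are implemented (`dem_model`):
`found_and_grow` (constant source, founding with fraction *s*, post-split
growth in both demes, constant symmetric migration), `three_epoch` (two
additional pre-split source size changes and a brief migration lag after
founding, fixed at 10% of the founding age — the lag is deliberately not a
free parameter, keeping the model identifiable at desk scale),
`two_epoch_admixture` (a single source→colony pulse replaces continuous
migration; the pulse time is parameterised as a fraction of the founding
age so the ordering constraint is built in), and `zhan` (a single
persistent source size change, colony-only growth, constant migration).
The founding fraction *s* takes $s \cdot \nu_{\mathrm{source}}(T_F)$ as
the colony's initial size and leaves the source unchanged. Default bounds
are deliberately those a practitioner would use for an island-colonization
panel: sizes in $[10^{-3}, 50]$, times in $[10^{-3}, 3]$, scaled migration
in $[10^{-6}, 5]$, $s \in [10^{-4}, 0.95]$ — wide enough to span the
plausible histories, narrow enough that the optimizer is not asked to
explore absurd corners.

The observed spectrum is compared to the model expectation by Poisson
composite likelihood with the scaling θ̂ profiled analytically
(θ̂ = Σobs/Σmodel). Model cells of zero where observations are positive
are floored; inside the optimizer the floor is 0.25/replicates — a quarter
of the smallest mass the Monte-Carlo engine can resolve — because flooring
at machine epsilon turns unresolved cells into likelihood cliffs that
wreck direct search.

The optimizer is a sequential AIC-weighted restart scheme: pass 1 draws
starts log-uniform within bounds; each later pass perturbs the
Akaike-weighted average of the previous pass's completed runs
($w_i \propto e^{-\Delta_i/2}$; log-scale parameters averaged
geometrically) by the pass's fold factor, and additionally seeds one run
from the best parameters found so far, which guarantees the best AIC never
worsens across passes. Runs are bounded Nelder–Mead searches in a
logit-of-log transformed space, under a wall-clock timeout (default 60 s
per run at desk scale); timed-out runs are recorded but excluded from the
weighting. Common random numbers (one genealogy seed per fit) make the
likelihood surface deterministic; a `search_reps` option lets the search
run on a cheaper Monte-Carlo surface while every run's optimum is
re-scored at full engine resolution, which is what all reported
likelihoods and AICs use. AIC counts all optimized parameters plus the
profiled θ̂, so comparisons across models are internally consistent.

Unit conversion follows the standard scaling laws:
$N_{\mathrm{ref}} = \hat\theta/(4\mu L)$, sizes $\nu N_{\mathrm{ref}}$,
times $2TN_{\mathrm{ref}}$ generations (years via the generation time),
migration both as the scaled rate and as $m/(2N_{\mathrm{ref}})$ per
generation. Defaults are a butterfly-like 0.3 years per generation and
$\mu = 8.4\times10^{-9}$; the effective length $L$ should be total
post-filter bases times the fraction of called SNPs that entered the
fitted spectrum.

# What the tests do and do not show

The test-suite calibrations run at deliberately small problem sizes — the
expected-SFS engine at (20, 10) gene copies and 5,000 genealogies per
evaluation, synthetic panels of a few hundred RAD-like loci, permutation
tests at 99–199 permutations, 300–500 replicate calibrations — chosen so
the whole suite completes on a laptop-class single core. The generator
emulates the statistical structure the analysis assumes (independent
non-recombining loci, known ancestral states, clean biallelic calls,
uniform missingness); it does not emulate alignment or genotyping error,
linked selection, paralogy, or ascertainment from read depth, so passing
tests validate the statistical machinery, not robustness to upstream
artefacts.

Two empirical lessons from the inference experiments are worth recording
as design decisions. First, parameter recovery is only meaningful where
the model is identifiable: a founding bottleneck so strong that all colony
lineages coalesce at the founding saturates — any smaller *s* fits
equally well — so the recovery experiment generates data at a moderate
bottleneck (*s* = 0.05, founding age 0.3) where the likelihood
discriminates sharply. Second, AIC model selection among structurally
overlapping candidates is limited by optimization quality, not by the
criterion: `three_epoch` nests `found_and_grow` up to the migration lag,
so their converged AICs differ by little more than the parsimony penalty,
and with a Monte-Carlo likelihood and a fixed restart budget the practical
discriminator is that richer models optimize worse at equal budget. The
model-ranking experiment therefore generates data with genuine continuous
migration and source growth — features the one-pulse and no-source-growth
candidates cannot express — so that the alternatives misfit structurally
and the comparison does not hinge on resolving a two-unit AIC gap.

# Known limitations

* Numerical parity with diffusion-based SFS solvers is a non-goal; the
  Monte-Carlo expectation carries $O(1/\sqrt{\mathrm{reps}})$ noise that
  sets a floor on resolvable log-likelihood differences.
* Spectra support one or two populations only; ψ beyond pairs is taken
  pairwise.
* The pipeline treats loci as unlinked; within-locus recombination is not
  simulated.
* Admixture-proportion estimation and PCA are out of scope; `evanno_delta_k`
  consumes an externally produced likelihood table.
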