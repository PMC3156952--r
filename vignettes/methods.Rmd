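---
title: "Models and methods in coalsfs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in coalsfs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coalsfs` analyses a single deeply resequenced genomic region (order 100 kb)
across many populations: dataset-construction QC, classical diversity and
differentiation statistics, and demographic inference from the joint
derived-allele frequency spectrum under multi-population out-of-Africa
divergence models.  This vignette documents the models, the numerical
choices, and the limits of what a green test establishes.

## The data model

A `genotype_matrix` holds biallelic SNP genotypes (0/1/2 copies of the
alternate allele, `NA` missing) at 1-based positions within a region of
length $L$ bp, with an ancestral-allele annotation per site.  Coordinates
are region-internal; any genomic offset is metadata and never enters
arithmetic.  A `sample_manifest` maps samples to populations, populations to
continental groups, and populations to an origin coordinate used for
great-circle distances.  Missing genotypes are retained and every statistic
is computed with per-site effective sample sizes (documented per function).

## Dataset-construction filters

The filter order is fixed: individual call rate (fraction of non-missing
sites, threshold 0.80, computed before any site filter), then monomorphic
sites, then multi-allelic sites, then the Hardy-Weinberg screen.  The
counts in the `filter_log` are additive to the site-count difference by
construction.

**Hardy-Weinberg screening.**  Each population contributes an exact
conditional test P-value per site (plain exact P, no mid-P correction).
P-values are mapped to Z-scores by $Z = \Phi^{-1}(1 - P)$ (clamped to
$[10^{-15}, 1 - 10^{-15}]$ so Z stays finite), combined over the $k$
populations with a defined test as $Z_c = \sum Z_i / \sqrt{k}$ (equal
weights), and converted to a two-sided P.  Removal uses the Bonferroni
threshold $\alpha / M$ with $M$ the number of sites tested.

One choice here was genuinely open and we deviated from the most literal
two-sided reading: removal is restricted to the violation direction
($Z_c > 0$).  The exact-test P-value is discrete with a large atom at
$P = 1$; mapping that atom through the clamp gives $Z \approx -7.9$, so a
site in perfect Hardy-Weinberg proportions in every population would
receive an enormous negative combined Z and be removed by a two-sided
rule — a clamping artifact, not evidence.  One-sided removal preserves the
Stouffer arithmetic (per-population $P = 0.5 \Rightarrow Z = 0$, combined
$P = 1$, retained) and restores the intended type-I guarantee (the removal
fraction under a simulated null is at most $\alpha$ after Bonferroni, which
the test suite checks at 2,000 sites).

**Polarization.**  Sites are relabelled so the reference column carries the
ancestral allele: where an outgroup allele matches one of the two alleles
the other is derived; otherwise the global minor allele is taken as derived
(fallback, flagged per site).  The operation is idempotent.

**Reference fill-in.**  Reference-based SNP callers emit no call where a
population is invariant; those population-by-site cells can be filled as
homozygous reference, with a provenance flag kept per cell so a sensitivity
re-analysis can exclude them.  Filled cells count as called genotypes in
diversity statistics, matching how such datasets are constructed.

## Diversity statistics

For a unit (population or continental group) with $n$ chromosomes over a
region of $L$ bp:

* $S$, $S_p$: segregating sites in the unit, and those also monomorphic in
  the complement of the unit (private sites).
* Watterson $\hat\theta_W = S / (a_n L)$, $a_n = \sum_{i<n} 1/i$.
* $\hat\pi = L^{-1} \sum_s \frac{n_s}{n_s - 1} 2 \hat p_s (1 - \hat p_s)$
  with per-site called chromosomes $n_s$; with complete data this equals
  the mean pairwise difference exactly (the suite checks the identity
  against an exhaustive pairwise oracle).
* $H$: mean per-site heterozygote fraction, per bp.
* Haplotype heterozygosity: the region is cut into
  $\lceil L / w \rceil$ windows ($w$ = 10 kb default) anchored at
  position 1; per window the unbiased $\frac{n}{n-1}(1 - \sum_h f_h^2)$
  over distinct phased haplotype strings; windows without a segregating
  site contribute 0; the unweighted window mean is reported.  Phase must be
  supplied (simulated truth or external phasing); the function refuses
  unphased input rather than guessing.
* Tajima's $D$ with the 1989 constants; its two-sided significance is the
  fraction of standard-neutral coalescent replicates — conditioned on $n$
  and $S$, with $S$ mutations dropped on branches proportionally to
  length — whose $|D|$ reaches the observed value.  We chose conditional
  simulation over the beta approximation because the simulation engine is
  already in the package and exact conditioning costs little.

Confidence intervals for $\theta$ and $\pi$ use the normal approximation
with the neutral-coalescent variances ($\mathrm{var}(S) = a_n\theta_L +
b_n\theta_L^2$; Tajima's $b_1, b_2$ form for $\pi$).  These are
intentionally *wider* than intervals produced by some legacy toolboxes:
they include evolutionary (coalescent) variance, not just sampling noise.
Per-bp statistics are reported on the conventional $\times 10^{-5}$ scale.

Tajima's $D$ uses the unit's full $2 \cdot n_{\mathrm{Ind}}$ chromosomes
with the region-wide $S$ and $\pi$ sums; per-site missingness adjusts
$\pi$ and $H$ but not the $D$ constants (sensitivity to this choice is
negligible at the missingness levels the generator produces, and the
statistic is only used as a region-level neutrality screen).

## Differentiation

**Weir–Cockerham FST.**  Per-locus variance components $a$ (among
populations), $b$ (among individuals within populations), $c$ (within
individuals) from sample sizes, allele frequencies and heterozygote
frequencies; multi-locus estimate $\sum a / \sum (a+b+c)$ (ratio of sums).
Negative estimates are reported as computed.  Tables are in percent.  The
group-level matrix has within-group among-population estimates on its
diagonal — the only self-consistent reading of a group-by-group table with
a filled diagonal.  The suite checks the components against an independent
three-level ANOVA (mean-squares) derivation on gamete indicators at
tolerance 1e-10, and checks the island-model calibration
$E[F_{ST}] \approx 1/(1+4M)$ for two demes with scaled per-lineage
migration rate $M$ (first-step analysis gives within/between coalescence
times $2$ and $2 + 1/(2M)$).

**Nei's distance** $D = -\ln I$ with $I = J_{ab}/\sqrt{J_a J_b}$ over
per-locus allele-frequency vectors; non-overlapping alleles at every locus
give an `Inf` sentinel.

**PCA on genetic distances** is implemented as principal-coordinates
analysis (classical scaling via `cmdscale`) of the Nei distance matrix —
the only well-defined "PCA of a distance matrix".  Variance fractions are
eigenvalues over the positive-eigenvalue total; the sign convention makes
the largest-magnitude loading positive on each axis.

**Geography.**  Great-circle (haversine) distances on a 6,371-km sphere
from a reference origin (default Addis Ababa, 9.03N 38.74E) against
per-unit heterozygosity, with a two-sided t-test for the Pearson
correlation.  The package ships an editable origin table
(`inst/extdata/population_origins.tsv`); for panels collected away from
their origin an approximate origin is used (e.g. Beijing for the Denver
Chinese panel, Gujarat for the Houston Gujarati panel, Paris as a
central-western European stand-in).  Because the true coordinates used in
any given study are rarely printed, correlation checks carry a tolerance
(the worked example accepts ±0.10).

## The coalescent engine

A structured-coalescent simulator in compiled code.  Time is in units of
$2 N_{\mathrm{ref}}$ generations and sizes are relative to
$N_{\mathrm{ref}}$ (diffusion scaling; $\theta = 4 N_{\mathrm{ref}} \mu
L$).  A model is the present-day populations plus a time-ordered backward
event list: size/growth changes, joins (splits, viewed backward), and
migration-rate changes; migration is symmetric island-style (per-lineage
scaled rate to each other active population), off by default.  Exponential
growth uses closed-form intensity inversion (time rescaling), not Euler
stepping, so epoch waiting times are exact.  Mutations are infinite-sites:
Poisson with mean $\theta/2$ per unit branch length, positions uniform on
the region with collisions redrawn.

There is no intra-locus recombination: a region is either one genealogy or
(default for the 100-kb emulation) 100 independent 1-kb sub-loci, which
approximates recombination's variance reduction and provides the blocks
for the block bootstrap.  This matches how a single resequenced region is
honestly describable — co-segregating markers — while keeping the
simulator exact.

The expected joint SFS is Monte-Carlo: the mean total branch length
subtending each leaf configuration, times $\theta/2$.  It is exactly
linear in $\theta$, deterministic under a seed, and returns a
standard-error tensor.  The engine is validated against closed forms
($E[\xi_i] = \theta/i$, pair TMRCA, growth vs singleton excess) and was
cross-checked during development against an independent simulator
(msprime) at the calibrated three-population parameters; the frozen oracle
values live in the test suite.

## The study mimic

`make_study_mimic()` emulates the study design the package addresses: 12
populations in 4 continental groups (five Indian including a northern
panel, two African, two European, three East Asian), a 100-kb region as
100 sub-loci, ancestral alleles known, truth record written beside the
data.  Its defaults are the stated world: per-population analysis sizes of
the normalized panel (22–24 diploids each), the calibrated four-population
history as generating model, mutation rate $1.48 \times 10^{-8}$, and
generation time 25 y.  Within-group substructure is a knob
(`within_split_years`, default 10,000 y, chosen to land within-group FST
around the low single-digit percent range that resequencing panels of
closely related populations show); it was set once, a priori, and is not a
fitted quantity.  The "full" 722-individual panel splits the non-printed
per-panel sizes evenly and is documented as synthetic.  What the mimic
does *not* emulate: sequencing error, phasing error, call-rate structure,
recombination within 1-kb blocks, and real within-India history — so a
green pipeline run establishes software correctness on a known truth, not
historical conclusions.

## Demographic inference

**Models.**  The three-population out-of-Africa family: ancestral size
$N_A$ changes to $N_{Af}$ at $T_{Af}$; the Eurasian ancestor ($N_B$)
splits at $T_B$; the two Eurasian groups split at $T_{1\text{-}2}$ with
initial sizes $N_{1,0}, N_{2,0}$ growing exponentially to $N_1, N_2$; no
migration (the selected models exclude it; the grammar supports it).  The
four-population family adds an intermediate Eurasian ancestor $N_C$ and a
second Eurasian split, with $N_{Af}, N_B, T_{Af}, T_B$ fixed from the best
three-population fit; $N_A$ remains free (the distinct $N_A$ values in the
four-population estimates support this reading).

**Likelihood.**  Poisson composite likelihood over joint-SFS entries with
the monomorphic corners masked:
$\ell = \sum_c o_c \ln e_c - e_c - \ln o_c!$.  In the three-population
family $\theta$ is profiled analytically (the expected tensor is rescaled
to the observed masked total — the exact Poisson MLE of a common scale),
removing one optimizer dimension; $N_A$ then follows from
$\hat\theta = 4 N_A \mu L$.  In the four-population family the fixed
physical parameters couple the scaling to $N_A$, so $N_A$ is an explicit
free parameter and $\theta$ is tied to it rather than profiled.  Expected
entries are floored at a small fraction of the mean cell so that rare
configurations cannot produce an infinite objective; an expected entry of
exactly zero with a positive observation is a `-Inf` sentinel, not an
error.

**Optimization.**  Multi-start (default 10 restarts, log-uniform within
bounds) Nelder–Mead on log-parameters, with ordering constraints
eliminated by reparameterizing times as increments
($\tau_{12}, \tau_B - \tau_{12}, \tau_{Af} - \tau_B$, all positive).  The
Monte-Carlo objective uses common random numbers within a restart (the
expected-SFS seed is fixed), making each restart's objective
deterministic.  Because a fixed noise realization of amplitude several
log-likelihood units can still displace an optimum, fitting is two-stage:
a coarse stage with cheap replicates explores, then the best candidates
are refined with an order of magnitude more replicates, and all restart
optima are ranked on a common high-replicate evaluation.  Replicate counts
and iteration caps are runtime-calibrated for a single CPU and are
settings, not constants.

**Bootstrap.**  500 block-bootstrap replicates by default (1-kb sub-locus
blocks), refit with reduced restarts started from the point estimate, with
a fixed optimizer seed so degenerate data give degenerate (zero-width)
intervals; 2.5–97.5 percentile intervals, clipped to contain the point
estimate (the container type's invariant).  Whether a study's bootstrap
resampled sites, windows or individuals is often unstated; blocks are the
defensible choice for a contiguous region and are what the sub-locus
structure provides.

**Units.**  $N_A = \hat\theta/(4\mu L)$; sizes $N = \nu N_A$; times
$T = \tau \cdot 2 N_A g$ years, reported in kya.  The physical-to-scaled
map and its inverse are exact (round-trip identity checked at 1e-10).

**Mutation-rate calibration.**  From outgroup divergence $d$ per bp:
$\mu = d / (2 t_{\mathrm{split}}/g + 4 N_{\mathrm{anc}})$ — divergence
accumulates along two lineages for $t_{\mathrm{split}}/g$ generations plus
the expected $4 N_{\mathrm{anc}}$ generations of coalescence in the
ancestor.  The worked defaults ($d = 1.2\%$, $g = 25$,
$t_{\mathrm{split}} = 6$ My, $N_{\mathrm{anc}} = 84{,}000$) give
$\mu = 1.47 \times 10^{-8}$ per bp per generation.

## Known limitations

* The expected SFS is Monte-Carlo, not a diffusion solution: objective
  values carry noise that shrinks as $1/\sqrt{\text{replicates}}$; the
  two-stage refinement controls, but does not eliminate, noise-induced
  displacement of optima.  The contract allows swapping in a diffusion
  solver without touching inference code.
* A single 100-kb region is weakly informative: single-replicate estimates
  of the Eurasian split times scatter widely (the bootstrap intervals are
  honest about this); only medians over many replicates are calibrated
  quantities.
* No selection, no recombination maps, no sequencing-error model, no
  relatedness inference ("unrelated" is taken from the manifest).
* Individual-level ordination and admixture analysis are out of scope.
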