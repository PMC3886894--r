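---
title: "Models and methods: sex-biased demography and background selection on the Y"
author: "Ypopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(Ypopgen)
```

## The scientific question

The human Y chromosome is startlingly undiverse: divergence-normalized
nucleotide diversity on the Y is roughly an order of magnitude below the
one-quarter of autosomal diversity expected for a uniparental, haploid
marker at mutation-drift equilibrium. Two very different explanations are
on the table:

1. **Sex-biased demography.** If far fewer males than females contribute
   offspring (high variance in male reproductive success), the effective
   number of Y chromosomes shrinks relative to the autosomes, and low Y
   diversity is purely neutral.
2. **Purifying selection.** With essentially no crossing over outside the
   pseudoautosomal regions, a deleterious mutation anywhere on the Y drags
   the whole chromosome down with it when selection removes it. This
   *background selection* shortens the genealogy of the entire chromosome
   and depresses diversity at all linked neutral sites.

The decisive observation is that the four chromosome classes — autosomes,
X, Y and mitochondrial DNA — respond *differently* to a skewed sex ratio,
so they jointly constrain it. The package implements both arms of the
argument: the neutral machinery to show that no sex ratio fits all four
classes at once, and a forward simulator plus an approximate likelihood to
quantify how many Y-linked sites under purifying selection (*L*) would
reconcile the data.

## Effective sizes and the sex ratio

With `Nm` effective breeding males and `Nf` females (Poisson offspring
variance, non-overlapping generations), the diploid-equivalent effective
sizes are

$$N_{auto} = \frac{4 N_m N_f}{N_m+N_f},\qquad
  N_{X} = \frac{9 N_m N_f}{2(2N_m+N_f)},\qquad
  N_{Y} = \frac{N_m}{2},\qquad
  N_{mt} = \frac{N_f}{2}.$$

`effectiveSizes()` implements these; `expectedRatioCurves()` gives the
equilibrium diversity ratios as closed forms in $R = N_m/N_f$, and
`invertXARatio()` solves the X/autosome curve for $R$:
$R = (9-8Q)/(16Q-9)$, defined for $Q \in (9/16,\, 9/8)$. Estimation from
data holds $N_{auto}$ fixed (demography is calibrated on autosomal
markers) and redistributes it between the sexes, via
`sizesFromAutosomal()`.

```{r}
estimateNmNf(0.0723, 0.0804)  # African far-from-genes diversities
estimateNmNf(0.0459, 0.0615)  # European
```

## Neutral coalescent under piecewise demography

Two demographic models are built in: an African expansion (10,000 to
20,000 diploids 4,000 generations ago) and a European bottleneck (10,000
down to 1,000 at 1,500 generations, recovering to 10,000 at 1,100
generations). `demographyForChromosome()` rescales every epoch to a
chromosome class under a chosen $R$.

`sampleGenealogy()` draws a Kingman coalescent with pairwise rate
$1/(2N(t))$ by running the exponential clock across epochs;
`dropMutations()` overlays infinite-sites mutations as
Poisson($\mu\,T_{total}$). The analytic oracle is `expectedPairwiseTime()`:

$$E[T_2] = \sum_j S_j\, 2N_j\!\left(1-e^{-\Delta_j/(2N_j)}\right),
\qquad S_j=\prod_{i<j}e^{-\Delta_i/(2N_i)}.$$

An important subtlety: the familiar 0.75/0.25/0.25 ratio references hold
at *equilibrium*. Under the non-equilibrium study demographies the exact
expectations differ, because the smaller-$N$ classes sit deeper inside
the size changes. Under the African model at $R=1$, for instance,
$E[T_2]$ is 21,903 generations for the autosomes but 6,649 for the Y,
giving an expected Y/A ratio of 0.304 rather than 0.25 — and the
simulated means reproduce exactly these demography-specific values (the
test suite asserts this within Monte-Carlo error). The equilibrium
references are therefore verified under a constant-size demography, where
they are exact.

```{r}
expectedPairwiseTime(africanDemography())
expectedPairwiseTime(demographyForChromosome(africanDemography(), "Y", 1))
```

## Forward simulation of background selection

`runReplicate()` simulates a haploid, non-recombining chromosome forward
in time: `Lsel` selected sites and a linked neutral region, fitness
$w=\prod_j(1-s_j)$ multiplicative over carried mutations, offspring drawn
by fitness-weighted multinomial resampling (per-capita offspring numbers
are asymptotically Poisson). New selected mutations arrive at
Poisson($\mu L_{sel}$) per chromosome per generation with population-scaled
effects $\gamma \sim \Gamma(0.184,\ 1600)$ and per-copy deficit
$s=\gamma/N_{hap}$, clamped below 1 (a clamped draw is effectively
lethal). The scale 1600 comes from rescaling an autosomal calibration
(scale 8200 estimated on 51,272 chromosomes, heterozygous exposure) to
the 5,000-chromosome haploid Y: `rescaleDFE(8200, 51272, 5000)` —
division by the chromosome ratio, doubled because Y mutations are fully
exposed.

Two design choices matter for correctness and speed:

* **Neutral overlay on the traced pedigree.** Neutral mutations are not
  carried individual-by-individual. The engine records the full pedigree,
  traces the sampled chromosomes' genealogy back through it after the
  run, and overlays neutral variation as Poisson($\mu T$) on the realized
  branches. Because the chromosome does not recombine, every site shares
  one genealogy, and conditional on it the number of neutral segregating
  sites is Poisson regardless of selection — so this is distributionally
  *exact*, not an approximation. Selected mutations are still carried
  explicitly (they drive fitness); for large batch runs the bookkeeping
  can be switched off (`trackSelected = FALSE`), which provably leaves
  the dynamics unchanged since fitness is the only channel through which
  selection acts.
* **Burn-in.** Runs start from a clonal founder population and burn in
  for 10 ancestral population sizes of generations before the epochs play
  out. Mean fitness on a non-recombining chromosome declines indefinitely
  (Muller's ratchet), so "stationary mean fitness" is not a usable
  criterion; what equilibrates is segregating variation, and the
  neutral-limit tests (forward vs coalescent, mean and variance of *S*)
  validate the choice.

**Desk rescaling.** `deskRescale(cfg, lambda)` shrinks populations by
$\lambda$, multiplies mutation rates and divides times by $\lambda$, and
keeps population-scaled selection $\gamma$ fixed, so $N\mu$ and $Ns$ are
invariant. The one distortion is that the $s<1$ clamp bites at
$\gamma > N_{hap}/\lambda$: rescaling truncates the strong tail of the
DFE earlier. Such mutations are eliminated essentially instantly at
either scale, so their effect on linked diversity is nearly invariant;
and the recovery experiment uses the same DFE for simulation and
inference, so its coverage statement is internally consistent either way.

## The approximate likelihood for L

Under infinite sites, $S_{obs}\mid T \sim \text{Poisson}(\mu T)$ — even
when selection has distorted the genealogy, as long as the counted
mutations are neutral. The likelihood of $L$ is the integral of that
Poisson kernel over the distribution of $T$ under $L$ selected sites,
which is approximated by simulation: each forward replicate's simulated
count $S^*_i$ estimates its genealogy length via $T^* \approx
S^*/\mu_{sim}$, giving the mixture

$$\hat{\mathcal L}(L) = \frac{1}{k}\sum_{i=1}^k
  \Pr\!\left(S_{obs};\ \text{Poisson}\!\left(
  \tfrac{\mu}{\mu_{sim}}S^*_i\right)\right),$$

computed in log space (`loglikForL()`). The ratio $\mu/\mu_{sim}$
accounts for simulating 500 kb ($\mu_{sim}=0.0171$) in place of the ~7.8
Mb of observed neutral Y sequence ($\mu = 0.265$ African, 0.273
European). `fitL()` maximizes over a grid of $L$ (spanning 50 kb, below
the ~100 kb of coding sites, to 6 Mb, above the ampliconic content) and
reports a 95% confidence interval as all points within 1.92
log-likelihood units of the maximum, interpolating linearly between grid
points and flagging intervals censored at a grid edge. `profileFitL()`
profiles out the DFE scale on a two-dimensional grid.

Numerical choices: zero-probability mixtures return $-\infty$ rather than
erroring so grid scans continue; $S_{obs}=0$ against an invariant pool is
handled exactly; non-finite curve points are clamped 700 log-units below
the cutoff during interpolation (beyond double-precision relevance); ties
at the maximum take the smallest $L$.

A property worth knowing: with *small* reference pools the interval is
anti-conservative — a small $k$ under-samples the tails of the $T$
distribution and the CI comes out too narrow, converging from below as
$k$ grows (the suite demonstrates this on a controlled toy). Pool sizes
should therefore not be skimped.

## Parameter recovery at desk scale

`recoveryExperiment()` rehearses the full inference loop: simulate
datasets at a known true $L$ (7.5 Mb of neutral sequence linked to
$L = 2$ Mb of selected sites), build one shared pool set over the grid,
fit every dataset, and score the CIs against truth. The packaged
experiment runs the African Y model rescaled by $\lambda = 10$
(ancestral 500 haploids), 200 datasets, a seven-point grid
{0.05, 0.5, 1, 2, 3, 4, 6} Mb and $k = 150$ replicates per grid point —
sizes chosen to keep the full experiment in the minutes range on one
core while leaving the coverage estimate's binomial error near 1.5%. At
these sizes the median MLE sits on the true grid point and coverage is
near-nominal (the suite asserts $\geq 90\%$, consistent with slightly
conservative intervals at large $k$).

## Observed-data statistics

`pairwisePi()`, `segregatingSites()` and `foldedSFS()` operate on a
`HaplotypeMatrix` — a binary samples-by-sites matrix plus the callable
intervals that give $\pi$ its denominator. Masks are `GRanges`;
`applyMasks()` removes masked variants and recomputes callable length by
interval arithmetic, and the far-from-genes filter expands gene masks by
a flank (100 kb in the estimation path) before exclusion. Coordinates
are 0-based half-open at the interfaces (BED convention; VCF positions
converted on read); multiallelic sites are excluded with a message; any
missing genotype is an error, mirroring the "called in all individuals"
rule. `muFromDivergence()` converts per-site divergence to a mutation
rate under a molecular clock (6 Myr split, 20-year generations), which
is exactly the calibration behind the built-in class rates
(`chromosomeClass()`).

## What the synthetic generator does and does not emulate

`generateNeutralStudy()` draws study-shaped data: two populations of 8
males, four chromosome classes with class-correct effective sizes under
each population's $R$, written as VCF (phased diploid autosomes, haploid
otherwise) plus BED masks and a YAML manifest recording the generating
truth. Defaults follow the study conditions where stated (demographies,
8 males, Y mutation rate 3.42e-8, Y divergence 0.02051) and otherwise
use field-realistic choices made once: autosomal and X sequence as many
independent 50 kb loci (free recombination between, none within — the
far-from-genes data of a real genome is effectively many weakly linked
windows), single non-recombining Y (500 kb analyzed sequence) and mtDNA
(16,569 bp) loci, divergence for non-Y classes set to $\mu \times 2
\times$ (6 Myr / 20 yr) for exact consistency with the rate calibration,
and sparse gene/repeat masks (1 gene of 10 kb and 100 repeats of 300 bp
per Mb) so that a 100 kb far-from-genes flank still leaves sequence.
`generateYWithSelection()` swaps in forward-simulated Y haplotypes with
known $L$.

What it does *not* emulate: haplogroup structure and geographic
substructure, ampliconic palindromes and gene conversion between their
arms, sequencing error and missingness, CpG hypermutability, or
intra-locus recombination on A/X. Passing tests on synthetic data
therefore validate the estimators' internal consistency under the
model's assumptions — not robustness to those real-data complications.

## Known limitations

* The coalescent replaces intra-locus recombination with independent
  loci; expectations of $\pi$ and $S$ are unaffected, but site-to-site
  correlation within A/X loci is not reproduced.
* Discrete Wright-Fisher pedigrees allow multiple mergers in one
  generation; at the sample sizes used ($n = 8$) the Kingman
  approximation error is $O(1/N)$ and invisible next to Monte-Carlo
  noise, as the neutral-limit tests confirm.
* Full-scale (unrescaled) forward runs of the Y model are memory- and
  time-hungry (the pedigree of a 5,000-chromosome population over 50,000
  burn-in generations is about 1 GB); the package is routinely exercised
  at $\lambda = 10$.
* The likelihood treats the demography and DFE shape as known inputs, as
  the study design does; only $L$ (optionally with the DFE scale) is
  estimated.
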