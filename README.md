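# Ypopgen

Population-genetic machinery for a sharp question: diversity on the human
Y chromosome is roughly ten-fold below the neutral expectation of
one-quarter the autosomal level — is that explained by **sex-biased
demography** (fewer effective breeding males than females), or does it
require **purifying selection** acting on linked sites, i.e. background
selection sweeping a non-recombining chromosome? And if selection is
required, at how many sites *L* must new mutations be deleterious?

The package is aimed at population geneticists who want to run this style
of analysis end to end — on their own haplotype data (VCF + BED masks) or
on fully synthetic, study-shaped datasets with known truth.

## What is inside

* **Sex-ratio algebra.** Effective sizes per chromosome class for
  effective numbers of breeding males and females $(N_m, N_f)$:
  $N_{auto} = 4N_mN_f/(N_m{+}N_f)$, $N_X = 9N_mN_f/(2(2N_m{+}N_f))$,
  $N_Y = N_m/2$, $N_{mt} = N_f/2$; equilibrium diversity-ratio curves in
  $R = N_m/N_f$; and the closed-form inversion $R = (9-8Q)/(16Q-9)$ of an
  observed X/autosome ratio $Q$ (`effectiveSizes`, `expectedRatioCurves`,
  `invertXARatio`, `estimateNmNf`).
* **Neutral coalescent** under piecewise-constant demography, with exact
  analytic oracles for pairwise coalescence times (`sampleGenealogy`,
  `simulateDiversity`, `neutralRatioTable`, `expectedPairwiseTime`).
* **Forward Wright–Fisher simulator** (C++ core) of a haploid
  non-recombining chromosome carrying `Lsel` selected sites with a gamma
  distribution of fitness effects (shape 0.184, scale 1600 for the Y),
  linked to a neutral region; includes standard population rescaling for
  desk-scale work (`runReplicate`, `batchReplicates`, `deskRescale`,
  `rescaleDFE`, `codingSitesTest`).
* **Approximate likelihood for L**: the Poisson-mixture likelihood of an
  observed segregating-site count over simulated reference pools, grid
  MLE with 1.92-log-likelihood-unit confidence intervals, profile
  likelihood over the DFE scale, and a parameter-recovery experiment
  (`loglikForL`, `fitL`, `profileFitL`, `recoveryExperiment`).
* **Diversity statistics** on haplotype matrices: pairwise π, segregating
  sites, folded SFS, GRanges-based interval masking including a
  far-from-genes flank, divergence normalization
  (`pairwisePi`, `foldedSFS`, `applyMasks`, `normalizeByDivergence`).
* **Synthetic data generator** writing VCF/BED/TSV/YAML bundles with the
  study's structure (two populations of 8 males; autosome/X/Y/mtDNA
  classes) and manifest-recorded truth, optionally with a Y that evolved
  under background selection (`generateNeutralStudy`,
  `generateYWithSelection`, `writeBundle`, `readBundle`).

## Worked example

Estimate the sex ratio from observed far-from-genes diversity, then from
a synthetic study where the truth is known:

```r
library(Ypopgen)

## Observed normalized diversities (X, autosomes) far from genes:
estimateNmNf(0.0723, 0.0804)   # African sample
#> $Q
#> [1] 0.8992537
#> $R
#> [1] 0.3351895
estimateNmNf(0.0459, 0.0615)   # European sample
#> $Q
#> [1] 0.7463415
#> $R
#> [1] 1.029851
```

An X/autosome ratio of 0.90 implies roughly one effective breeding male
per three females ($R = 0.335$); the European ratio of 0.75 is what an
equal sex ratio predicts. Now the synthetic route — generate a neutral
African-model study at equal sex ratio and re-estimate:

```r
cfg <- studyConfig(loci = list(A = list(n = 60L, bp = 20000L),
                               X = list(n = 60L, bp = 20000L),
                               Y = list(n = 1L, bp = 100000L),
                               MT = list(n = 1L, bp = 16569L)))
cfg$populations <- cfg$populations["Africa"]
b <- generateNeutralStudy(cfg, seed = 11)
sexRatioFromBundle(b, farFromGenesBp = 1e5)
#>   population    piXStar    piAStar         Q         R
#> 1     Africa 0.05949509 0.07640657 0.7786646 0.8010918
```

The generating truth is $R = 1$; the estimate 0.80 reflects coalescent
noise at 1.2 Mb per class (note $Q = 0.779$, not 0.75: under the
non-equilibrium expansion model the expected X/A ratio at $R=1$ is 0.770,
a point the methods vignette develops). Diversity on a single chromosome
class:

```r
effectiveSizes(SexRatio(5000, 5000))
#> EffectiveSizes (diploid-equivalent):
#>   N_auto = 10000  N_chrX = 7500  N_chrY = 2500  N_mt = 2500
```

For the selection arm — forward-simulate a Y with 2 Mb of selected sites
(rescaled by 10 for desk use), and ask how many selected sites the
approximate likelihood infers from the neutral segregating-site count —
see `?recoveryExperiment` and the methods vignette
(`vignettes/y-chromosome-diversity-methods.Rmd`).

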