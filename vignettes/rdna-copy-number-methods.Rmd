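---
title: "Measuring rDNA copy number by droplet digital PCR: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring rDNA copy number by droplet digital PCR: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnacn)
```

## The measurement problem

The yeast rDNA locus is a tandem array of 9.1 kb repeats whose copy number
per haploid genome (roughly 100–250 in laboratory strains) is the quantity
of interest. Droplet digital PCR measures it without a standard curve: a
reaction is partitioned into ~20,000 nanolitre droplets, amplified to
endpoint, and each droplet scored positive or negative per fluorescence
channel. A duplexed assay carries two targets in the same droplets — the
25S region of the rDNA repeat and a single-copy reference gene (*TUB1*) —
and the ratio of their absolute concentrations is the copies-per-genome
estimate.

## Partition statistics

With occupancy $\lambda$ (mean target molecules per droplet), the number of
negative droplets among $n$ is binomial with success probability
$e^{-\lambda}$, so from $k$ positives the maximum-likelihood estimate and
its delta-method variance are

$$\hat\lambda = -\ln\frac{n-k}{n}, \qquad
  \operatorname{Var}(\hat\lambda) \approx \frac{e^{\hat\lambda}-1}{n}.$$

`estimate_lambda()` implements the closed form (the test suite checks it
against direct numerical maximisation of the binomial likelihood), and
`lambda_ci()` builds a normal interval on $\hat\lambda$, truncated below at
zero. A log-scale variant (`log_scale = TRUE`) is available for very low
occupancies where the symmetric interval would truncate; it is not the
default because at screen occupancies ($\lambda$ between ~0.02 and ~3) the
two agree closely and the symmetric form matches how instrument software
reports intervals. Wells with *no* positive droplets yield a degenerate
interval with a warning; wells with *all* droplets positive are an error
rather than an imputed value, because occupancy is then unbounded and the
assay's answer is to dilute input, not to extrapolate.

The copy-number ratio is formed from the two channels' occupancies
directly, so the droplet-volume factor cancels exactly; droplet volume only
scales absolute concentrations. The ratio CI uses the delta method on the
log-ratio with independent channel variances — in a duplexed partition the
two channels are conditionally independent given the droplets — and is
back-transformed, which keeps it positive and mildly right-skewed, matching
the skew of a ratio estimator. A Fieller-type interval would be an
alternative; at the droplet counts involved the difference is negligible.
The per-reaction technical error is reported as
$\mathrm{SD} = (\mathrm{CI_{max}} - \mathrm{CI_{min}})/(2 \times 1.96)$
(`sd_from_ci()`), the convention that lets a single well's droplet data
stand in for technical replicates.

## The synthetic-well generator

`simulate_well()` reproduces the two error sources that dominate a
well-behaved assay:

1. **Sub-sampling.** With input mass $m$ (default 0.005 ng), genome size
   $L$ (12.1 Mb) and mass per base pair $w$ (1.079e−21 g), the expected
   genome equivalents per well are $\mu = m/(Lw) \approx 383$. The
   reference channel receives $G \sim \mathrm{Poisson}(\mu)$ molecules and
   the rDNA channel an independent $\mathrm{Poisson}(\mu \cdot CN)$ draw.
   The draws are independent per target — not a single genome count scaled
   by $CN$ — because extraction fragments genomic DNA and the pre-droplet
   restriction digestion separates the tandem repeats, so the dilute
   aliquot samples individual target fragments, not intact genomes. This
   matters: with perfectly coupled channels the sub-sampling error would
   cancel in the ratio and the per-well CI would overstate the replicate
   spread several-fold, contradicting the assay's observed property that
   CI-derived error matches true technical replicates. Independent
   Poisson sub-sampling makes the partition-statistics variance formula
   exact, and the suite's coverage and replicate-error checks confirm both.
2. **Partitioning.** Each molecule lands in one of $n$ droplets uniformly
   and independently (digestion is assumed complete, so no linkage between
   repeat copies); a droplet is positive if it holds at least one molecule
   of the channel's target.

Optional per-channel false-positive / false-negative flip rates (default 0)
stand in for droplet misclassification ("rain"). The generator does *not*
model fluorescence amplitudes, droplet-volume variability, partial
digestion (which would cluster rDNA repeats into shared droplets and
inflate variance), PCR inhibition, or instrument droplet-QC; passing tests
therefore demonstrate correctness of the estimators under the idealised
partition model, not robustness to those instrument artifacts.

Determinism: a well's counts are a pure function of its spec and seed (the
caller's RNG stream is left untouched), and plate simulation derives
per-well seeds from the plate seed plus a stable hash of the well id, so
extending a plate never perturbs existing wells.

## Screen calling

`compute_thresholds()` takes the wild-type control measurements and sets
bands at the sample mean ± 1 SD and ± 2 SD (sample SD, $n-1$ denominator —
the controls are a sample of the control population). Calls
(`call_hit()`): within 1 SD is `no_change`, strictly between the 1 SD and
2 SD bounds is `moderate_low`/`moderate_high`, strictly beyond 2 SD is
`significant_low`/`significant_high`. Boundary values take the less extreme
category, because the defining inequalities of the extreme classes are
strict. The 2 SD rule is the two-sided $p<0.05$ criterion under a normal
error model; integer display cutoffs are reported as
$\lfloor \text{mean} - 2\,\mathrm{SD} \rfloor$ and
$\lfloor \text{mean} + 2\,\mathrm{SD} \rfloor$, matching how histogram
cutoffs are quoted (e.g. controls with mean 95 and SD 12.175 give 70
and 119).

```{r thresholds}
compute_thresholds(c(95 - 12.175, 95, 95 + 12.175))
```

Replicate wells of one mutant are pooled by summing droplet tallies before
estimation (`merge_wells()`), the sufficient-statistic treatment, rather
than averaging per-well ratios. Karyotype filtering (`karyotype()`)
computes the chromosome XII / XIII concentration ratio from a second
duplexed assay; strains outside the closed euploid band — default
[0.8, 1.25], asymmetric because a one-chromosome gain in a diploid moves
the ratio to 1.5 but partial effects and measurement spread argue for a
margin below the midpoints — are flagged and excluded from category
tallies, never silently dropped. The band is configurable
(`aneuploidy_band` in the run configuration). Two-condition comparisons
(`compare_conditions()`) use the standard two-sample two-tailed t test
(pooled variance by default, Welch optional) with `*`/`**` stars at
0.05/0.01; two degenerate groups with equal means return $p = 1$ by
convention.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_droplets` | 20,000 | — | QX200-class droplet count; treated as the accepted-droplet count per well |
| `droplet_volume` | 0.85 | nL | QX200 convention; cancels from the ratio |
| `input_mass` | 0.005 | ng | keeps rDNA occupancy below saturation at 100–250 copies |
| `genome_size` | 12.1e6 | bp | haploid yeast genome |
| `mass_per_bp` | 1.079e−21 | g | average base-pair mass |
| `ci_level` | 0.95 | — | reporting convention for all intervals |
| `aneuploidy_band` | [0.8, 1.25] | — | euploid chrXII/XIII ratio band |

At these defaults the reference channel carries ~383 molecules, so the
single-well relative error of the ratio is about $1/\sqrt{383} \approx 5\%$
— dominated by reference-channel sub-sampling, which is why raising input
mass (more genome equivalents) is the lever that tightens the assay.

## Problem sizes and numerical checks

The test suite's simulation checks use sizes chosen to make their binomial
tolerances meaningful while keeping the suite quick to run: 2,000 wells for
ratio-CI coverage (93–97% band), 20 seeds × 8 wells for the
replicate-error summary, 100 rounds of 4 copy-number levels × 3 pooled
wells for distinguishability, and 10 pooled 96-well plates (160 controls,
800 true-wild-type mutants) for null calibration of the significant-call
rate against the ~4.6% two-sided 2 SD expectation. Null calibration pools
controls across plates, as a screen does when it sets thresholds from all
its wild-type measurements; with few controls per plate the estimated-SD
(Student-t) inflation of the false-positive rate becomes visible.

## Known limitations

* The simulator's idealised partition model understates variance whenever
  digestion is incomplete (linked repeats co-occupy droplets) or droplet
  volumes vary.
* The delta-method intervals assume enough positives in both channels;
  boundary wells are flagged or rejected rather than estimated.
* Hit categories inherit the controls' measurement spread: few controls
  give noisy thresholds, and the pipeline refuses to run with fewer than
  two.
* Biological replication is out of scope: the technical-error model says
  nothing about strain-to-strain biological variability in array size.
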