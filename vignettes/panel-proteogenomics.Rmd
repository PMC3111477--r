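---
title: "Methods: comparative transcriptome-proteome genetics on an inbred panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative transcriptome-proteome genetics on an inbred panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`xqtl` implements the statistical machinery for comparing the genetics of
transcript and protein abundance across a panel of inbred strains: quality
filters for both molecular layers, robust concordance statistics, linear
mixed-model genome-wide association, and QTL classification and overlap
analysis. Because inbred strains are genetically reproducible, each strain's
molecular phenotype can be measured in replicate and its heritable component
estimated directly; because the panel segregates natural variation, loci
controlling each transcript (eQTL) and each protein (pQTL) can be mapped and
compared.

The association model for a phenotype vector $y$ over strains is

$$ y = \mu + x\beta + u + e, \qquad
   \mathrm{Var}(u) = \sigma^2_g K, \quad \mathrm{Var}(e) = \sigma^2_e I, $$

where $x$ is the SNP genotype, $K$ the identity-by-state kinship matrix
(fraction of shared alleles per strain pair), and $u$ a polygenic random
effect that absorbs population structure. Variance components are estimated
by restricted maximum likelihood (REML) profiled over
$\delta = \sigma^2_e/\sigma^2_g$: after projecting out the fixed effects,
the kinship is diagonalized once, so the restricted likelihood is a cheap
one-dimensional function of $\delta$. We search a grid of 100 intervals in
$\ln\delta \in [-10, 10]$, refine every sign change of the derivative by
root finding, and keep the global optimum. By default the variance
components are estimated once per phenotype under the null model and reused
for every SNP (the classic approximate strategy; `per_snp_reml = TRUE`
re-estimates them under each alternative, exactly but much more slowly).
Each SNP is then tested by rotating phenotype and design into the
eigenbasis of $K$, whitening with $1/\sqrt{d_i + \delta}$, and applying an
F test of $\beta = 0$ with $n - 2$ denominator degrees of freedom.

## Robust correlation

All correlation-based analyses use the biweight midcorrelation: deviations
from the median are weighted by $w_i = (1-u_i^2)^2\,\mathbf 1[|u_i|<1]$ with
$u_i = (x_i - \mathrm{med})/(9\,\mathrm{MAD})$. We use the raw median
absolute deviation (consistency constant 1) and tuning constant 9, the
standard form of the estimator; a variable with zero MAD falls back to
Pearson-style mean deviations. Two-sided p-values come from the Student-t
transform $t = r\sqrt{(n-2)/(1-r^2)}$. Missing data are removed pairwise
and the number of complete pairs is recorded with every correlation.

## Quality filters

* **Peptides.** Retained when missing in fewer than half the strains
  (strict `< 0.5`, denominator = number of strains), carrying no internal
  lysine/arginine (the tryptic C-terminus is exempt; the proline exception
  is deliberately *not* applied — only the literal rule is), and mapping
  uniquely to one gene. The signal-to-noise ratio $S$ is the panel variance
  over the technical-replicate variance of a designated reference strain,
  with pass defined strictly as $S > 2$; zero technical variance is treated
  as a best-case pass with an infinite sentinel rather than an error, since
  noiseless measurement is not a defect of the peptide. Variances are
  unbiased sample variances ($n-1$).
* **Transcripts.** Broad-sense heritability per probeset is
  $H^2 = SS_\mathrm{strain}/SS_\mathrm{total}$ from a fixed-effect one-way
  ANOVA with strain as the grouping factor (unbalanced designs supported),
  with the strain-term F-test p-value; probesets pass at $p < 0.05$ with a
  unique gene annotation, and probesets sharing a gene with a retained
  peptide are force-included so every protein has its transcript partner.
  Probes containing a SNP (1-based inclusive interval containment) are
  masked, and probesets with eight or more masked probes are excluded.
* **Trend removal.** `eigen_normalize()` removes the leading right singular
  vectors ("eigenpeptides") of the centered matrix, the SVD step of
  LC-MS bias-trend normalization, with missing cells mean-imputed for the
  decomposition only. Because all rows are centered first, the singular
  vectors are orthogonal to the constant vector and the residual rows stay
  centered.

## FDR, pruning, and QTL geometry

Storey q-values estimate $\pi_0$ by the smoother over
$\lambda = 0, 0.05, \dots, 0.90$ (cubic smoothing spline, df = 3, read off
at the largest $\lambda$); with $\pi_0 = 1$ they reduce exactly to
Benjamini–Hochberg, which is the oracle used in the tests. A subsampling
mode computes q-values on random subsets and averages them through
step-function interpolation, the standard approximation when the p-value
list is too large to sort at once.

Significant associations are pruned per phenotype by a greedy rule: the
most significant SNP becomes a peak and removes every significant SNP with
genotype $r^2 \ge 0.5$ against it (ties in p broken toward the smaller
genomic coordinate, making the output order-independent). Peaks are
classified *local* when they fall on the gene's chromosome within 2 Mb of
the transcribed region's boundaries (inclusive; the "4 Mb window"), else
*distant*. Hotspot profiles count peak positions in 2 Mb windows slid every
50 kb; windows are half-open `[start, end)` so adjacent non-overlapping
windows never double-count (the inclusive/exclusive convention is a package
choice — either is defensible and it is documented here and in the help
page). Haplotype blocks are maximal runs of consecutive SNPs whose adjacent
$r^2$ exceeds 0.5 (strictly, "above"), while pruning uses $\ge$ 0.5 ("0.5
or larger") — the two thresholds are quoted differently in their
respective rules and both are kept strict to their wording. eQTL–pQTL
overlap matches peaks within 2 Mb, one-to-one nearest-first (the
multiplicity rule is not dictated by the source analyses; nearest-first is
deterministic and conservative), with local matches restricted to the same
gene.

## Group concordance tests

For gene sets (GO slim terms, pathways), the observed statistic is the mean
correlation p-value of the group's members; the null distribution is built
from 100,000 equal-size subsets drawn randomly *without replacement* from
the whole pool of correlation p-values, and the empirical two-tailed
p-value is $(2\min(\#\{\le\},\#\{\ge\})+1)/(n_\mathrm{boot}+1)$, capped at
1. The +1 correction avoids empirical zeros. The pool can be per-pair or
per-gene; both make sense and the function simply takes whatever pool the
caller supplies. Pathway concordance uses mean pairwise Spearman
correlations within peptides, within probesets, and across the two sets,
for every pathway with at least two members of each kind.

# The synthetic panel generator

Every stage is validated against `simulate_panel()`, whose defaults mirror
the design of a hybrid mouse diversity panel liver study: 97 strains, 19
chromosomes, ~96k SNPs with minor allele frequency at least 10%, mean
haplotype block ~0.75 Mb, transcripts in 3 biological replicates, peptides
as one log2 sample/reference ratio per strain plus 10 technical replicates
of the first (reference) strain, 42 clinical traits, and per-feature
heritability targets spanning 0.07–0.95.

Genotypes are built from contiguous blocks (exponential bp lengths): each
block has a founder column copied to every SNP of the block with a 3%
per-strain flip probability, which produces within-block $r^2$ around
0.7–0.8 against near-zero across blocks. Founder frequencies differ across
four subpopulations (Balding–Nichols, $F_{ST} = 0.2$), giving the panel the
family structure that makes kinship correction matter: on null phenotypes
with a 50/50 polygenic/noise split, naive regression shows ~9–13% type-I
error at $\alpha = 0.05$ where the mixed model stays at ~5%. SNPs below the
MAF floor are redrawn and, if necessary, repaired by flipping the minimal
number of majority-allele strains.

QTL architecture is assigned per *gene* — a local QTL (SNP within the
gene ± 2 Mb) and/or a distant QTL with configured probabilities and effect
sizes — and all features of a gene inherit its QTLs. This shared genetic
driver is what couples a gene's transcript to its peptides, so concordance
analyses have true signal to find, and peptides with higher signal-to-noise
show higher transcript correlation, reproducing the stratified-concordance
pattern qualitatively.

**Heritability semantics.** The generator's per-feature heritability target
is calibrated to the *estimator* used downstream: the strain/replicate
variance ratio is chosen so that $E[SS_\mathrm{strain}/SS_\mathrm{total}]$
equals the target under the replicate design (for single-measurement
peptides, the target is the strain-level fraction of total variance).
This estimator has a structural floor: with $s$ strains and $r$ replicates
its expectation cannot drop below $(s-1)/(sr-1)$ (~0.33 at 100 strains and
3 replicates) because strain means always contain replicate noise, so
targets below the floor are clamped to zero strain variance and realize
near the floor. This is a property of the ratio-of-sums-of-squares
definition itself, not of the generator; it also explains why the estimator
is biased upward for weakly heritable features on real data. QTL effect
sizes are expressed as fractions of the strain-level variance (summing to
at most 1 per feature), which keeps the variance bookkeeping exact whatever
the replicate design; genotypes are standardized (centered by allele
frequency, unit variance) before effects are injected, and the residual
polygenic component is orthogonalized against the QTL projection so the
realized genetic fraction hits its target up to sampling noise.

What the generator does *not* emulate: raw spectra or probe-level
intensities, missingness that depends on abundance (peptide missingness is
MCAR), dominance or epistasis, outbred pedigrees, and correlated
measurement error between the two platforms. Tests passing on this
generator therefore demonstrate the correctness and calibration of the
statistics, not robustness to every failure mode of real LC-MS or
microarray data.

# Numerical and design choices

* Inbred genotypes are coded {0, 1}; heterozygotes do not occur.
* Kinship uses all genotyped SNPs; a $10^{-6}$ diagonal ridge is added only
  if the matrix is numerically non-PSD.
* Missing genotypes are mean-imputed per SNP for testing; kinship uses
  observed pairs only. Phenotypes with fewer than 10 strains are skipped
  and logged, not errored.
* Variance explained is $1 - \mathrm{var}(y - \hat\mu - x\hat\beta)/
  \mathrm{var}(y)$ on the original phenotype scale, clamped to [0, 1].
* The REML search bounds ($\ln\delta \in [-10, 10]$) put the identity-K
  case at the upper bound, where the fit provably matches ordinary least
  squares (verified to $10^{-6}$ relative in the tests).
* All coordinates are 1-based inclusive except hotspot windows (half-open,
  see above). Degenerate inputs (constant phenotypes, all-identical
  features, empty strata or pathways) are defined outcomes, not errors,
  wherever a defined outcome exists; they error loudly otherwise.
* The problem sizes used by the validation suite and `scripts/acceptance.R`
  (100 strains, 1–2k SNPs, 60–300 features, 200 phenotypes for calibration,
  2,000 bootstrap draws for the uniformity check) were chosen as the
  smallest panels at which the calibration and recovery properties are
  stable across seeds.

# Known limitations

* The per-SNP exact REML path is a plain loop and is only practical for
  candidate regions.
* The bootstrap group test recomputes its null per term; for thousands of
  terms at 100,000 draws, precompute and share draws per group size.
* Heritability targets below the design floor of the SS-ratio estimator
  cannot be realized (see above); if an unbiased low-heritability target is
  needed, use the intraclass-correlation parametrization instead — not
  implemented because the downstream filters use the SS-ratio definition.
* `run_pipeline()` resumes only the simulation stage; analysis stages are
  cheap relative to it and are always recomputed.

# A worked mini-panel

```{r}
library(xqtl)
cfg <- sim_config(n_strains = 60, n_chromosomes = 3, chrom_length_bp = 50e6,
                  n_snps = 900, n_transcripts = 120, n_peptides = 150,
                  n_traits = 6, heritability_range = c(0.2, 0.9),
                  frac_local_qtl = 0.6, seed = 7)
out <- run_pipeline(run_config(sim = cfg), out_dir = "mini_run")
summarize_counts(out$calls)
```

The run directory contains every intermediate table as TSV (genotypes,
phenotypes, filter logs, SNR and heritability tables, association records,
QTL calls, hotspot profile) plus `manifest.json` recording the config hash
and per-stage row counts; rerunning with the same config reproduces the
manifest bit for bit.
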