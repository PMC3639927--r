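---
title: "Methods: surveying a biallelic copy-number deletion across populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying a biallelic copy-number deletion across populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcepop)
```

This vignette documents the statistical models, the tunable
parameters, the numerical choices, and what the synthetic-data tests
do and do not establish.  It states no empirical result beyond what
the test suite and `scripts/acceptance.R` themselves compute.

## The measurement model

The variant of interest is a biallelic deletion: each chromosome
carries the intact allele `+` or the deleted allele `-`, so diploid
copy number is 2, 1 or 0 for genotypes `+/+`, `+/-`, `-/-`.  Two data
modalities see it:

* **Pooled aCGH.**  Equimolar pools of population DNA are hybridised
  against a reference pool in a two-channel array.  The pool's mean
  copy number at the deletion is `2 p`, with `p` the pool's
  non-deleted allele frequency, so the ideal probe-level signal is
  `log2(p_test / p_ref)`.  Observed pooled intensities are compressed
  relative to this ideal (the strongest published pooled value is
  about -0.67 where the frequencies alone predict -1.4), so the
  simulator multiplies by an `attenuation` factor in (0, 1].  The
  mechanism of the compression (probe saturation, cross-hybridising
  paralogues, pool construction) is not identifiable from the data;
  attenuation is a phenomenological stand-in, default 0.5, which
  places simulated pooled values in the published range (-0.03 to
  -0.67).  A fitted value of ~0.48 reproduces the -0.67 endpoint
  exactly; we do not tune it per population.
* **Individual genotyping.**  PCR for the deletion, TaqMan for the
  tag SNP rs4112788 (`A`/`G`).  Either locus may fail per sample;
  all statistics are complete-case *per locus* (a sample missing only
  the SNP still counts for the CNV columns) and complete-case
  *pairwise* for LD.

## CNV detection

`call_rule_based()` implements a stringent multi-criterion rule:
`|log2| >= 0.25` on the direct label AND on the dye-swap label with
opposite sign (colour reversal flips a true signal), for at least 3
consecutive probes, constant direction, spanning at least 30 kb.  A
probe failing any criterion terminates the run; runs separated by a
single failing probe are not merged (strict reading of
"consecutive").  Span is measured from the first probe's start to the
last probe's end — probe extents are the only observable boundaries.
The threshold is applied to each label separately; a config switch is
not provided because the dye-swap-combined alternative is exactly
what the second caller uses, keeping the two callers methodologically
distinct.

`call_window()` is the second, independent caller standing in for a
segmentation algorithm: the dye-swap-combined signal
`s = (direct - swap)/2` (per-probe `|s|` clipped at 2.0 to bound
outlier influence; a probe missing one label contributes the other)
is smoothed by a `window_size`-probe running mean **assigned to the
centre probe**, and maximal runs of centre probes with smoothed
`|s| >= 0.25` become regions under the same span filter.  Centre
assignment, rather than flagging every probe of a qualifying window,
is the choice that makes the two callers agree to within one probe
spacing on clean data and lets a clipped isolated outlier die on the
span filter; edge probes without a full window never qualify
(conservative).  Note the window caller is insensitive to signals
only marginally above threshold: with window 5, a 4-probe event at
mean `mu` needs `4|mu|/5 >= 0.25` at its best centre.

`cnv_consensus()` keeps regions of caller A with reciprocal overlap
`>= 0.5` (of both widths) against a same-direction region of caller
B, reporting A's interval.  Overlap arithmetic is delegated to
IRanges; the test suite checks it against a naive pairwise oracle so
the two routes stay independent.

**Monotonicity caveat.**  Raising `min_consecutive_probes` or
`min_span` filters a fixed run set, so neither the region count nor
the total span can grow.  Raising `log2_threshold` shrinks the
qualifying probe set — total span cannot grow — but a long run can
*split* into two shorter runs that both survive the filters, so the
region *count* is not strictly monotone in the threshold.  The
property tests assert exactly the defensible set.

## Genotype statistics

Allele frequency is gene counting, `p_alt = (het + 2 hom_alt)/(2n)`.
The Hardy-Weinberg test is the plain Pearson chi-square of the three
genotype classes against `n(p^2, 2pq, q^2)`, 1 df, **no continuity
correction** — recomputing the published 13-population table (chi2
values 0.04 to 2.66) reproduces every printed value only under the
uncorrected statistic, which fixes the convention.  HWE is computed
on the CNV locus: the published table prints HWE beside the CNV
allele frequencies, and the uncorrected CNV-count recomputation
matches all 13 printed chi2 and p values to +/-0.01 (the acceptance
suite asserts this).  Monomorphic loci return `chi2 = 0, p = 1`,
flagged rather than erroring.

`counts_from_percentages()` exists because published tables are
inputs here: it inverts printed percentages to the unique integer
triple summing to `n` that minimises the maximum deviation from
`n * pct/100`, refusing (rather than guessing) when no triple comes
within 0.75 counts or when two triples tie.  At the survey's printed
precision (1-2 decimals, n <= 44) the reconstruction is exact for
every row it is asked to invert.  Two rows of the 31-population
fixture are shipped verbatim with known internal inconsistencies
(allele percentages not summing to 100; SNP percentages summing to
125.86); they are never reconstructed.

`spearman_correlation()` uses midranks, rho as the Pearson
correlation of rank vectors, and the two-sided t approximation
`t = rho sqrt((n-2)/(1-rho^2))` on `n-2` df — the approximation, not
the exact distribution, reproduces the published p = 0.0002 at
n = 13.  An exact permutation p-value is available behind
`exact = TRUE` for `n <= 8` (full enumeration; beyond 8 the 9!+
permutation space is not worth the runtime for a diagnostic option).
`|rho| = 1` reports the smallest positive double rather than 0.  The
published correlation is quoted as a positive 0.857 although
intensity and deletion frequency are anti-monotone; the package
reports signed rho (negative here) and surfaces the magnitude in the
correlation JSON.

## Linkage disequilibrium

For two biallelic loci genotyped without phase, all 3x3 joint
genotype cells except the double heterozygote `(+/-, AG)` decompose
uniquely into haplotypes.  `em_haplotypes()` is the standard EM:
E-step splits the double-het count between the coupling (`+A/-G`)
and repulsion (`+G/-A`) phases in proportion to the current products
`f(+A)f(-G)` vs `f(+G)f(-A)` (a 0/0 split degenerates to 1/2);
M-step renormalises; start at linkage equilibrium of the observed
allele frequencies; stop when `max|df| < 1e-10` or after 1000
iterations (non-convergence is flagged, not fatal).  The multinomial
log-likelihood is asserted non-decreasing at every step — a decrease
beyond 1e-8 aborts as an internal error.  A single start suffices:
the two-locus likelihood has a unique interior optimum for
non-degenerate tables, and the marginal allele frequencies of the
MLE equal the observed ones because allele counts are
phase-invariant.  That last fact also shapes the brute-force oracle
in the tests: a fine 0.001-step 1-D grid over `D` at observed
marginals plus a coarse 0.02-step grid over the whole 3-simplex
(which does *not* assume fixed marginals), since a full 0.001-step
simplex grid (~1.7e8 points) is not computable in the test budget.

`ld_from_haplotypes()` computes `D = f(-G) - p_- p_G` (deletion and
tag-G alleles, matching how the association is described in the
field; r2 is symmetric under this choice), `D'` with the usual
positive/negative bounds, and `r2 = D^2/(p_+ p_- p_A p_G)`, returning
`NA` for monomorphic loci.  Printed r2 values >= 0.9995 format as
`"1"` by default, matching how published tables print perfect LD.

## The synthetic world

`simulate_genotypes()` draws `2n` gametes i.i.d. from the four
haplotype frequencies and pairs them, so each locus is in
Hardy-Weinberg proportions in expectation and the joint distribution
carries exactly the configured LD.  `simulate_pool_acgh()` models
pools as exact allele-frequency mixtures (no pool-construction noise
is modelled because no error model for it is published); probes tile
the 32,199-bp deletion interval (chr1:150822166-150854365, 0-based
half-open — the published span equals `end - start`, so the printed
coordinates are taken as already half-open) at 10-kb spacing with 5
flanking probes per side, inside-probes get mean
`attenuation * log2(p_test/p_ref)` at the *realised* pool
frequencies, the dye-swap label is the negated signal, and both
labels receive independent Gaussian noise (default sd 0.1, placing
simulated data in the published intensity range).  Everything is
deterministic given the seed; RNG state is saved and restored around
every generator.

What a green synthetic test establishes: the estimators recover the
parameters of this stated world (HWE sampling, binomial allele-freq
error, EM r2 recovery, noise-free and low-noise region recovery).
What it does not: robustness to cross-hybridising probes, segmental
duplications, population substructure, related individuals
(the published Karitiana sample is known to contain relatives and is
taken at face value), pool pipetting error, or breakpoint
heterogeneity — none of which the generator emulates.

## Pipeline and reproducibility

`run_pipeline()` chains simulate, two-caller consensus detection,
population summaries, LD, correlation and report into one bundle
with a manifest (package version, seed, md5 parameter fingerprint,
per-file md5s).  The manifest deliberately contains **no
timestamps**: identical config + seed must give a byte-identical
bundle, and the acceptance suite enforces that at the byte level.
Stage failures abort the run, remove partial outputs, and name the
stage.  Numbers in the summary TSV print at the published tables'
precision (percentages and chi2 to 2 decimals, r2 to 3); all internal
computation is at full double precision.

## Known limitations

* The rule caller's 0.25/3-probe/30-kb defaults are tuned to 10-kb
  pooled arrays; denser platforms would want rescaled defaults.
* The window caller misses events whose attenuated signal sits just
  above threshold (see above); the consensus inherits that
  insensitivity, which is the price of requiring two concordant
  callers.
* LD r2 for small samples (n ~ 11-17) is noisy and the EM can sit on
  a boundary (r2 exactly 1) — published small-population values of 1
  should be read with that in mind.
* The published 31-population r2 column cannot be recomputed from
  printed data (joint genotypes are not published); it is carried as
  fixture metadata only, and the LD machinery is validated against
  oracles and parameter recovery instead.
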