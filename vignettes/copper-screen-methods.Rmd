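---
title: "Methods: scoring copper-dependent fitness in pooled deletion screens"
author: "cuscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring copper-dependent fitness in pooled deletion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuscreen)
```

## The experiment this package models

Budding yeast grows respiratorily on non-fermentable carbon sources
(ethanol, glycerol, lactate), and respiratory growth rate depends on the
availability of copper ions in the medium: copper is required by cytochrome
c oxidase and, through the ferroxidase Fet3, for high-affinity iron uptake.
A chemogenomic screen exploits this by growing a pool of barcoded
homozygous deletion strains competitively — with and without copper
supplementation — and asking which deletions change the size of the copper
growth boost.

Each strain carries up to two unique 20-bp barcodes (an *uptag* and a
*downtag*). After a fixed number of pool doublings, barcodes are amplified
and hybridized to a tag array; fluorescence intensity is the proxy for
strain abundance. `cuscreen` implements the analysis from these
tag-by-sample intensity tables onward, plus the plate-reader growth-curve
statistics used for follow-up experiments on individual strains. Array
image processing (CEL files) is out of scope; the entry point is the
extracted intensity table.

## The abundance model behind the simulator

The synthetic-data generator exists so that every downstream stage can be
tested against known ground truth. It encodes the screen's generative
assumptions directly:

* **Competitive exponential growth.** Strain $i$ has a relative fitness
  $f_i$ per doubling (0 = pool-typical) and a treatment effect $\delta_i$
  added under copper. After $G$ doublings its relative abundance is
  $a_i \propto 2^{(f_i + \delta_i \cdot \text{treated})\,G}$, renormalized
  to a constant per-sample total: the pools are serially diluted every
  three doublings, so the readout is compositional. Growth is
  deterministic — pools of thousands of strains kept in logarithmic phase
  show negligible drift, and a deterministic update makes closed-form test
  oracles exact. A multinomial bottleneck is available behind the
  `bottleneck_n` flag for users who want sampling noise.
* **Tag affinities.** Each tag's intensity is abundance times a
  multiplicative hybridization affinity, drawn log-normal (sdlog 0.5 on the
  natural-log scale by default). Affinity spread is what makes the uptag
  and downtag of one strain report different intensities, which is the
  reason the scoring stage selects the tag with the larger absolute
  response.
* **Noise on the log2 scale.** Additive Gaussian noise with standard
  deviation `sigma_log` (default 0.3 log2 units) is applied to log2
  intensities, i.e. linear intensities receive log-normal noise. This
  matches the scale on which the analysis operates. Array noise magnitudes
  are not identifiable from published summary tables, so the default is a
  plausible value for two-color tag arrays and is a tunable parameter — it
  must not be read as an estimate of any particular data set.
* **Defaults are the screen's study conditions**: 9 generations, four
  carbon sources (YPD, YPE, YPG, YPL), untreated vs copper, triplicates,
  ~2% single-tag strains, and a pool-typical tag intensity of 1000
  fluorescence units (about $2^{10}$, placing typical log2 values near 10
  as on a 16-bit scanner well below saturation).

Planted *responders* receive $\delta \ne 0$ on the non-fermentable carbon
sources; planted *respiration-deficient* (RD) strains receive a strongly
negative $f$ (default $-0.5$/doubling) there and normal fitness on
dextrose, so after 9 generations they fall about $4.5$ log2 units — from
$\approx 10$ to $\approx 5.6$, straddling the RD filter's thresholds the
way real RD mutants do.

What the generator does **not** emulate: probe-level array artifacts
(spatial effects, cross-hybridization, background gradients), strain
dropout by contamination, chemostat dynamics, and mutation during
competitive growth. Passing tests on synthetic data therefore demonstrate
correctness of the computations, not robustness to every array pathology.

## From intensities to Copper Response Scores

1. **log2 transform** with a linear floor (default 1, so zero intensities
   map to 0 rather than $-\infty$; the floor is configurable).
2. **Group-wise quantile normalization.** Uptags and downtags hybridize
   with systematically different efficiency, and the two pools (full
   homozygous pool, RD sub-pool) contain different tag sets, so
   normalization runs independently in each (pool × tag group) block —
   four blocks in the standard design — across *all* samples of that pool
   (both treatments, all carbon sources, all replicates together). Each
   column is mapped onto the across-sample mean of order statistics; tied
   values receive the mean of the reference values at the positions the
   tie occupies, which keeps the procedure deterministic. Normalizing YPD
   samples together with the respiratory samples follows the single-block
   reading of the design; the block structure is data-driven (it is
   whatever pools/tag groups are present), not hard-coded.
3. **Replicate means** per condition (pool × carbon source × treatment).
4. **CRS.** Per tag, $\Delta$ = mean(treated) − mean(untreated) of
   normalized log2 intensity. Per strain and assay the CRS is the
   $\Delta$ of the tag with maximal $|\Delta|$ (the only tag for
   single-tag strains). An exact tie selects the uptag — ties are measure-
   zero on real data but the rule keeps runs reproducible. Tag selection
   uses normalized means throughout.

The four scored assays are the full pool on YPE, YPG and YPL, and the RD
sub-pool on ethanol (written `YPE*`). YPD samples are used by the RD
filter and the fold-change clustering, not scored for copper response.

## Significance: moderated t, strain-level q-values

Per tag and assay, a two-group comparison of the three treated against the
three untreated replicate samples gives a difference $\Delta$ and a pooled
residual variance $s^2$ on $d = n_t + n_u - 2$ degrees of freedom. With
thousands of tags but only 4 residual df each, per-tag variances are noisy;
the package shrinks them with the standard empirical-Bayes hierarchy: true
variances follow a scaled inverse $\chi^2$ prior with hyperparameters
$(d_0, s_0^2)$, the posterior variance is
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, and
$t = \Delta / \sqrt{\tilde s^2 (1/n_t + 1/n_u)}$ is referred to a
t-distribution on $d_0 + d$ df (normal when $d_0 = \infty$). Two-sided
p-values are used because both increased and decreased copper responses
are biologically meaningful.

The hyperparameters are fitted per assay by method of moments on
$z = \log s^2$: $\operatorname{Var}(z) = \psi'(d/2) + \psi'(d_0/2)$ is
inverted for $d_0$ by Newton iteration on the trigamma function (absolute
tolerance $10^{-10}$), and $s_0^2$ follows from $\operatorname{E}(z)$ with
the digamma correction. When the spread of $z$ does not exceed the
sampling contribution $\psi'(d/2)$ the prior degenerates to
$d_0 = \infty$ with $s_0^2$ set to the geometric mean of the observed
variances (so identical variances recover exactly that value). The fit is
implemented from these published formulas rather than delegated, keeping
the statistic testable against its closed-form limits (ordinary pooled t
as $d_0 \to 0$; fixed-variance z as $d_0 \to \infty$); the test suite
cross-checks the fit against an independent implementation.

The prior is estimated separately per assay, pooling uptags and downtags,
matching the per-assay comparison structure of the CRS. Each strain then
inherits the p-value of its CRS-selected tag, and Benjamini–Hochberg
q-values are computed over the strains present in each assay (the decision
thresholds are applied per strain per assay, so strains are the natural
multiple-testing universe; testing tags instead, or adjusting globally
across assays, are one flag away in `strain_level_inference`). A strain is
called **increased** when CRS > 1.5 and q < 0.05 in at least one assay,
**decreased** when CRS < −1.5 and q < 0.05, **conflicting** when different
assays meet both criteria, else **neutral**. Both thresholds are
`screen_thresholds()` parameters.

## The respiration-deficient filter

Strains that cannot respire wash out of the non-fermentable pools
entirely, so their copper response there is unmeasurable in the full pool.
They are identified from *raw* (un-normalized) log2 fluorescence of the
copper-untreated samples only: a strain is respiration-deficient when the
median over all its tag × sample values is below 7 in the combined YPE,
YPG and YPL samples and above 8 in YPD. Medians pool both tags of a strain
— the per-tag variant is one flag away, but pooling is more robust to a
single weak tag. Raw values are used because the filter thresholds are
absolute fluorescence levels (presence/absence), which normalization would
distort. Treated samples are ignored even if present, since copper rescue
could mask the deficiency the filter is looking for.

## Fold-change clustering

For visual inspection of the hit set, per-replicate copper-induced fold
changes are computed on linear-scale normalized intensities:
$\log_2(I_{\text{treated},r} / \overline{I_{\text{untreated}}})$ per tag,
averaged over a strain's tags, for every treated replicate of every carbon
source (including YPD, where little copper response is expected).
Strain × experiment cells with no tag data are imputed as 0 — no change, a
conservative bias — and counted. Both axes are clustered agglomeratively
with average linkage on 1 − Pearson distance, the common default for
log-ratio heatmaps, and both distance and linkage are arguments; the
merge order for tied distances follows `stats::hclust`'s deterministic
convention. A zero-variance row has no defined correlation and is placed
at distance 1 from everything, with a warning. Trees are exported as
Newick text for external drawing. With replicate noise well below
between-condition differences, replicates of one condition cluster as
nearest neighbors — the reproducibility property the test suite asserts.

## Enrichment

Hit lists (increased and decreased, separately) are tested for Gene
Ontology overrepresentation with the upper-tail hypergeometric
distribution: $P(X \ge k)$ for a term of size $K$ in a universe of $N$
genes and a query of size $n$, followed by Benjamini–Hochberg adjustment
over the tested terms and a q < 0.05 call. The universe is the
user-supplied reference list — the ORFs actually represented in the screen
pool — not the whole genome, because pool membership is the correct null.
Terms with no query gene are not tested (they are counted in the output
metadata). Annotations are propagated up the ontology by the true-path
rule over is_a/part_of edges when an ontology is supplied; pre-propagated
annotation files can be used directly. No evidence-code filtering is
applied.

## Growth curves

Plate-reader follow-up experiments are summarized exactly as in the
screen's companion assays: readings every 15 minutes; the mean of the
first 10 readings is subtracted to zero the baseline (negative corrected
readings are kept — the AUC is defined as a plain sum, not a clipped one);
growth is the **sum** of the first $n$ corrected readings (not a
trapezoidal integral — the summation definition is the one this assay
family uses, and at 15-minute spacing the two differ by a boundary term
only). Defaults are 50 reads (12.5 h) for fermentable and 100 reads (25 h)
for respiratory media, with slower experiments (e.g. severely
copper-starved mutants followed for 40 h) opting into 160. Relative growth
is $(\mathrm{AUC}_{\text{condition}} -
\mathrm{AUC}_{\text{control}})/\mathrm{AUC}_{\text{control}}$ against an
on-plate reference, and dose–response matrices average replicate relative
growth per cell (the aggregation across replicates is not dictated by the
assay definition; the mean is used). The reference cell is exactly 0 by
construction.

## Numerical and design choices

* All randomness flows from integer seeds through a save/restore wrapper,
  so no package function perturbs the caller's RNG state.
* Quantile normalization preserves within-column ranks and the block grand
  mean exactly; normalizing twice is the identity.
* `run_screen()` stamps every output table with a hash of the analysis
  parameters and writes no timestamps, so identical inputs and
  configuration give byte-identical outputs.
* Strains absent from an assay receive `NA` rather than an imputed CRS and
  are excluded from that assay's q-value universe.
* Degenerate inputs fail loudly: fewer than 10 growth readings, a
  log2-scale table passed to `log2_transform`, a non-growing reference
  culture, a cyclic ontology (the cycle is named), or truth tables missing
  a strain (the strain is named).

## Problem sizes used in the tests

The packaged checks run on simulated pools of 40–2500 strains; the
recovery and calibration properties use 1000-strain pools with 50 planted
responders (true log2 effect 3, `sigma_log` 0.3, triplicates) and 20
independent seeds, which is large enough for stable sensitivity and
false-discovery proportions while keeping the whole suite fast on a
laptop. A full-scale 5050-strain, 24-sample screen runs through
`run_screen()` in well under a minute.

## Limitations

* The pipeline starts from extracted intensities; probe-level artifacts
  must be handled upstream.
* The tag→strain aggregation (selected-tag p-value) and the strain-level,
  per-assay multiple-testing universe are reasonable conventions, not the
  only defensible ones; both are isolated behind
  `strain_level_inference()`.
* Enrichment results depend entirely on the annotation release supplied by
  the user.
* The simulator's deterministic growth understates variance for very
  low-abundance strains; enable the multinomial bottleneck to explore
  that regime.
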