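---
title: "Methods: zonation-aware analysis of brain endothelial aging"
author: "zonage maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zonation-aware analysis of brain endothelial aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

Brain endothelial cells (ECs) are not one population: their transcriptomes
vary continuously along the arteriovenous axis, and `zonage` discretises
that gradient into six subtypes — two arterial (aEC1, aEC2), capillary
(capEC), capillary–venous (vcapEC), venous (vEC) and a mixed
arterial/venous subtype (avEC). The package implements a complete,
deterministic pipeline for asking three questions about such data:

1. How does aging change gene expression within each vascular segment?
2. Are those changes enriched for disease-associated genes, and are they
   conserved in human bulk expression data?
3. Does a pharmacological treatment *reverse* the aging signature, beyond
   what chance sign-flipping would produce?

Because real droplet scRNA-seq data of this design is large and its truth
is unknown, the package ships a first-class synthetic-data generator that
emulates the study design — three conditions (young, aged, aged+treated),
six EC subtypes with graded marker programs, contaminating mural/glial
populations, doublets and mitochondrial content — with every planted
effect recorded in a `GroundTruth` object. All statistical claims made by
the test suite are parameter-recovery claims against that truth.

# The synthetic-data generator

Counts are negative binomial: the count of gene $g$ in cell $c$ has mean
$s_c \cdot \rho_{g,p(c),cond(c)}$ and variance $\mu + \mu^2/\theta$, where
$s_c$ is a log-normal library size (default meanlog $\log 3500$, sdlog
0.35, matching shallow droplet libraries of a few thousand UMIs and a few
hundred detected genes per cell) and $\rho$ is the relative expression of
the gene in the cell's population and condition.

Key design choices, in the package's own words:

* **Dispersion** $\theta = 10$ shared across genes. Shallow UMI counts are
  close to Poisson per gene once library size is accounted for;
  regularised per-gene estimates in public droplet data sit mostly at
  $\theta \ge 10$. A smaller $\theta$ (stronger overdispersion) is
  configurable.
* **Marker programs.** Each subtype except avEC owns a private marker set
  (default 44 genes, so five subtypes give a ~220-gene panel emulating a
  ~267-gene arteriovenous zonation panel); avEC expresses a 50/50 union of
  aEC1 and vEC markers rather than a private program, reflecting its mixed
  arterial/venous character. Identity markers for EC as a class and for
  each contaminant population are elevated $e^{2\lambda}$ (default 16-fold);
  zonation markers $e^{\lambda}$ (default 4-fold).
* **EC-enriched genes.** A configurable set (default 30) is elevated in
  all six EC subtypes but no other population (default $e^{1.2}$, clearly
  above the twofold enrichment threshold), and aging effects may land on
  them — these emulate the functionally important endothelial genes whose
  conservation the cross-species comparison is about.
* **Placement band.** Marker, EC-enriched and DEG genes are drawn from the
  67th–97th percentile of baseline expression. The lower bound keeps
  planted programs on robustly detected genes (where real marker genes and
  DE calls live); the upper bound excludes the few library-dominating
  genes, because planting multiplicative effects there shifts every other
  gene's *normalised* expression — a compositional artifact no real DEG
  set produces at this magnitude.
* **Aging effects.** Per subtype, a configurable number of private DEGs
  (plus a set shared by three or more subtypes, with a common sign) get
  |lnFC| drawn uniformly from [0.3, 0.8]; 68% are upregulations,
  mirroring the observed excess of age-upregulated genes. The lower bound
  is kept above the 0.1 significance magnitude threshold by construction.
* **Treatment.** A fraction (default 0.75) of each subtype's affected
  genes is flagged reversed; flagged genes revert fully to young means in
  the treated condition (partial reversion via `reversalStrength`).
  Unflagged genes keep their aged means.
* **Doublets** are sums of two randomly paired cells' rate vectors from
  different populations, and their truth label records both parents.

What the generator does *not* emulate: ambient RNA, UMI collisions,
batch effects (batch correction is out of scope for the pipeline),
per-gene dispersion variation, and correlated gene programs beyond the
planted ones. Passing recovery tests on this generator therefore
demonstrates the statistical machinery is correct and calibrated under
the stated model, not that the model captures every failure mode of real
tissue dissociation.

# Quality control and primary typing

Gene filter: genes detected in fewer than 3 cells are removed (a gene in
exactly 3 cells stays). Cell filter: cells strictly below the 5th or
strictly above the 95th interpolated percentile of either total UMI or
detected-gene count are removed, as are cells with mitochondrial fraction
strictly above 20%; percentiles are computed on the input population, and
an all-equal metric removes nobody.

Primary cell types are assigned by marker scores — the mean normalised
expression of each type's markers — with the label being the argmax.
Cells whose top *two* scores are both high are excluded as dual-high
(doublets or contaminated transcriptomes, e.g. the classic
pericyte-with-endothelial-fragments profile). "High" for a type means
exceeding the type's baseline (median score among cells not labelled as
it) by more than half the gap to its positive level (90th-percentile
score among cells labelled as it). Two simpler absolute bars were
considered and rejected: a fraction of the population-wide 90th
percentile collapses when a type is rare (the population percentile then
reflects baseline, not positive cells), and any absolute bar misfires
when a marker set has high baseline expression. Graph clustering and
embedding are deliberately not part of the package; marker scoring yields
the same primary partition on well-separated data while remaining fully
specified.

# Probabilistic subtype assignment

Zonation subtypes are assigned with a six-component negative-binomial
mixture over the marker panel. Under subtype $t$, marker gene $g$ in cell
$c$ is NB with mean $s_c \beta_g e^{\delta_g \rho_{gt}}$: $s_c$ is a
size factor (marker-gene totals over their median), $\beta_g$ a baseline,
$\delta_g \ge 0$ the marker over-expression and $\rho$ the binary
indicator. The prior over subtypes is uniform and the dispersion is fixed
($\theta = 10$). The E-step computes posteriors; the M-step updates
$\beta$ and $\delta$ with damped per-gene Newton steps on the expected
complete-data log-likelihood (each step is accepted only if it does not
decrease the objective), making the whole procedure a generalised EM
whose observed log-likelihood is non-decreasing — asserted at every
iteration. Convergence is a relative log-likelihood change below 1e-4,
with a 500-iteration cap (non-convergence warns and returns the
best-so-far fit, flagged).

The run seed controls only the initialisation: initial posteriors come
from raw marker-set scores computed with per-gene log-normal weights
(sd 0.3). Jitter is applied per gene, not per subtype column, which makes
the procedure exactly equivariant under permutations of the marker matrix
columns. Consensus assignment repeats the fit with distinct seeds
(default 3) and keeps only cells labelled identically in every run;
downstream subtype-level statistics use consistent cells only. On
well-separated synthetic data the consensus fraction is essentially 1;
on real data it is the filter that removes ambiguous intermediate cells.

# Hurdle differential expression

Counts are normalised as $\ln(1 + 10^4 \, c_{gc} / N_c)$. The effect size
is the expm1-mean log fold change
$\mathrm{lnFC} = \ln(\overline{e^x - 1}_A + 1) - \ln(\overline{e^x - 1}_B + 1)$,
under which $|\mathrm{lnFC}| > 0.1$ is roughly a 10.5% change and 0.7 is
twofold. The test is two-part: a binomial likelihood-ratio test on
detection rates and a Gaussian likelihood-ratio test on the positive log
values, summed and referred to $\chi^2$ with one degree of freedom per
non-degenerate part. The discrete part is dropped when detection is
all-or-none pooled; the continuous part when there are fewer than three
positive cells or a group has none; a gene undetected everywhere gets
p = 1. No cellular-detection-rate covariate is fitted by default (none is
required by the pipeline's contracts); this is the main divergence from
covariate-adjusted hurdle implementations and is visible in the module
boundary, not buried in a default.

Significance is strict on both axes: BH-adjusted p < 0.05 *and*
|lnFC| > 0.1. Genes are classified shared (significant in ≥ 3 subtypes),
shared by 2, or subtype-specific, with sign-concordance across the
significant subtypes reported.

Calibration facts established by the test suite: on 2,000 null genes
(two groups of 150 cells from identical NB distributions) the raw p-value
rate at 0.05 is within [0.035, 0.065]; power at planted lnFC 0.4 with
~300 cells per group exceeds 0.9. The realised false-discovery proportion
of a single run fluctuates around the BH-controlled expectation, so the
recovery test pools calls over three replicates and allows three binomial
standard errors. A residual source of slight anti-conservatism is
compositional: per-cell normalisation transmits a small fraction of the
planted DEG mass to every null gene. The placement band keeps this shift
an order of magnitude below the significance threshold.

# The reversal statistic

Eligibility for reversal analysis is deliberately laxer than DEG calling:
every gene with BH-adjusted p < 0.05 in the aged-vs-young contrast
qualifies, regardless of |lnFC|. An eligible gene is *reversed* when its
treated-vs-aged lnFC has the opposite sign to its aging lnFC (exact zero
counts as not reversed — conservative). The null is constructed from the
data: the chance that an aging-*up* gene flips down is the fraction of
*all* tested genes with negative treated-vs-aged lnFC ($P_{down}$), and
symmetrically $P_{up}$ for down-genes. Each direction's reversed
proportion is tested against its chance level with a one-sided
one-proportion z-test, $z = (k/n - p_0)/\sqrt{p_0(1-p_0)/n}$, and the
treated-vs-aged lnFC is regressed on the aged-vs-young lnFC (slope, $r^2$
and slope p-value); full reversal corresponds to a slope near −1.

Two properties of this construction deserve emphasis:

* The raw reversed proportion does **not** estimate the reversed
  fraction: unreversed genes flip sign with probability near the chance
  level, so $E(k/n) = f + (1 - f)p_0$. `reversalFractionEstimate()`
  inverts this, pooling directions; it carries a small downward bias from
  false-eligible genes (the BH-controlled share of eligibility calls),
  visible in recovery runs as estimates a few points below a strong
  planted fraction until they centre on it with enough eligible genes.
* The z-test treats the estimated chance level as known. That is accurate
  in the regime the method is meant for — eligible genes a percent or
  less of the tested universe, as in genome-wide data — and measurably
  anti-conservative when eligible genes are a large share of a small
  universe (at eligible/universe ≈ 0.2 we observe ~10% rejections at
  nominal 5%). The calibration test therefore runs at eligible/universe
  ≈ 0.01, and users restricting the universe sharply should interpret
  borderline p-values with care.

# Overrepresentation and cross-species concordance

Disease-gene overrepresentation is the hypergeometric upper tail
$P(X \ge k)$ for the overlap between a subtype's DEG orthologs and a
disease list, computed by exact log-gamma summation of PMF terms over the
tail (verified against exhaustive enumeration of all draws for universes
up to 15 genes, relative error < 1e-10). The background universe defaults
to the genes tested for DE in that subtype; disease genes outside the
universe are dropped before testing; no correction across the
subtype-by-disease matrix is applied by default (a BH option exists).
Mouse-to-human mapping expands one-to-many orthologs and falls back to
the upper-case symbol convention, reporting (never silently dropping)
genes absent from the table.

EC-enriched genes are those at least twofold higher (lnFC > 0.7, strictly)
and BH-significant in ECs versus all other cells pooled. Human bulk
comparisons are per-gene Welch t-tests between groups (samples, not
subjects, are the unit — a subject-level option would be the
conservative alternative where repeated samples per brain are strongly
correlated) or per-gene OLS of expression on age (46–70 years in the
simulated design), both BH-adjusted across the tested (mouse EC-enriched
ortholog) set only. Concordance classifies each mouse-significant,
EC-enriched gene by the sign pair: concordant-up/down when the human
change is significant with the same sign, discordant when opposite,
human-ns otherwise.

# Pipeline and problem sizes

`runPipeline()` executes simulate → qc → assign → de → reverse → enrich →
concord with a plain-TSV contract between stages, per-stage seeds derived
from the global seed by fixed offsets, a manifest of MD5 hashes, and
`.partial` renaming of a failed stage's outputs. Reruns with the same
configuration are byte-identical.

Default problem sizes are chosen to keep a full desk run in minutes while
preserving the study's structure: the pipeline default simulates ~1,300
cells per condition over 1,700 genes; recovery tests use 300 cells per
group per subtype (about 1,800 ECs per condition) with 2,100–3,000 genes;
the z-test null calibration uses a 4,000-gene universe with ~30 planted
DEGs per subtype and 200 replicates; full-scale defaults
(`simConfig()` with 3,000 ECs per condition and 8,000 genes) emulate the
study's magnitude. The reversal recovery loop uses the truth subtype
labels for grouping — it isolates the DE-plus-reversal machinery, while
assignment recovery is established separately at ≥ 95% accuracy and
≥ 99% consensus, so composing the two loses little.

# Known limitations

* The NB model has a single shared dispersion; real data shows
  gene-specific dispersion and residual structure the generator does not
  produce.
* Batch effects are neither simulated nor corrected; the batch column
  exists in the metadata contract only.
* The z-test's known-p0 assumption (above) and the compositional
  normalisation leak (above) are inherent to the procedure, not
  implementation artifacts; both are quantified in the test suite.
* Consensus assignment fractions near 1 on synthetic data should not be
  read as a prediction for real tissue, where intermediate zonation
  states are genuinely ambiguous.
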