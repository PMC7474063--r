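# zonage

Zonation-aware analysis of brain endothelial cell (EC) aging and its
pharmacological reversal, for single-cell transcriptomics.

Brain endothelial transcriptomes vary continuously from artery through
capillary to vein ("arteriovenous zonation"). Aging changes gene
expression differently in each vascular segment, and some of those
changes can be reversed by drug treatment. `zonage` is for researchers
who want to quantify exactly that from 10x-style UMI counts: it assigns
each EC to one of six arteriovenous subtypes (aEC1, aEC2, capEC, vcapEC,
vEC, avEC) with a probabilistic marker model, tests per-subtype
differential expression with a two-part hurdle model, measures how much
of the aging signature a treatment reverses against a constructed
chance-level null, tests disease-gene overrepresentation, and classifies
cross-species concordance against human bulk expression. A truth-labelled
synthetic-data generator makes every stage testable without any download.

## The statistics at the core

* **Subtype assignment.** A six-component negative-binomial mixture over a
  zonation marker panel: under subtype *t*, marker gene *g* in cell *c*
  has mean *s<sub>c</sub> β<sub>g</sub> exp(δ<sub>g</sub> ρ<sub>gt</sub>)*
  with binary indicator ρ, fitted by a monotone (generalised) EM.
  The fit is repeated with independent seeds and only cells labelled
  identically in every run enter subtype-level analyses.
* **Differential expression.** Per gene, a binomial likelihood-ratio test
  on detection plus a Gaussian likelihood-ratio test on positive log
  values, summed as χ² (df = number of non-degenerate parts). Effect size
  is lnFC = ln(mean<sub>A</sub>(e<sup>x</sup>−1)+1) −
  ln(mean<sub>B</sub>(e<sup>x</sup>−1)+1); a gene is significant when
  BH-adjusted p < 0.05 **and** |lnFC| > 0.1 (both strict).
* **Reversal.** For genes with adjusted p < 0.05 in the aged-vs-young
  contrast (no lnFC cut), a gene is reversed when its treated-vs-aged
  lnFC has the opposite sign. The observed reversed proportion k/n is
  tested against the chance level — the fraction of *all* genes moving in
  that direction under treatment — with a one-sided one-proportion
  z-test, z = (k/n − p₀)/√(p₀(1−p₀)/n), and the two contrasts' lnFC
  values are regressed (slope near −1 means full reversal).
* **Overrepresentation.** Hypergeometric upper tail P(X ≥ k) for the
  overlap of DEG orthologs with a disease gene list, by exact log-gamma
  summation.

## Worked example

Simulate a three-condition study (young, aged, aged+treated), assign
subtypes by 3-run consensus, and quantify reversal in capillary ECs:

```r
library(zonage)

cfg <- simConfig(nCellsPerCondition = 600, nGenes = 1700,
                 nMarkersPerSubtype = 10, nAgingDEGsPerSubtype = 60,
                 nSharedDEGs = 10, seed = 42)
sim <- simulateCounts(cfg)
sce <- normalizeLog(qcFilterCells(filterGenesMinCells(sim$sce))$sce)

markers <- zonationMarkersFromTruth(sim$truth)
ec  <- colnames(sce)[sce$trueLabel %in% zonationSubtypes()]
asg <- consensusAssign(sce[, ec], markers, nRuns = 3)
asg
#> AssignmentResult: 1604 cells, 3 run(s)
#>   aEC1   aEC2  capEC vcapEC    vEC   avEC
#>    237    200    334    621    165     47
#>   consistent: 1604/1604 (100.0%)

cap  <- ec[consistentCells(asg) & subtypeLabels(asg) == "capEC"]
cond <- setNames(sce$condition, colnames(sce))
deAge   <- hurdleDE(sce, cap[cond[cap] == "aged"],    cap[cond[cap] == "young"])
deTreat <- hurdleDE(sce, cap[cond[cap] == "treated"], cap[cond[cap] == "aged"])
sum(deAge$significant)
#> [1] 57

rep <- reversalReport(deAge, deTreat, "capEC")
rep
#> ReversalReport [capEC]
#>  direction  n  k        p0        z            p
#>         up 41 36 0.4717647 5.211291 9.376569e-08
#>       down 20 17 0.5270588 2.892713 1.909652e-03
#>   regression: slope=-0.740 r2=0.714 p=1.06e-17 (n=61)
reversalFractionEstimate(rep)
#> [1] 0.7434338
```

Reading the output: of 41 aging-upregulated eligible genes, 36 (88%) move
down under treatment, against a 47% chance level — z = 5.2, p ≈ 1e-7.
The lnFC–lnFC regression slope of −0.74 indicates strong (not complete)
transcriptomic reversal, and the chance-corrected estimate 0.74 recovers
the fraction of genes the generator actually reverted (0.75).

`runPipeline(list(outdir = "out"))` runs the same stages file-to-file
(simulate → qc → assign → de → reverse → enrich → concord) with TSV
outputs, per-stage seeds and an MD5 manifest; reruns with the same
configuration are byte-identical. `inst/scripts/zonage-pipeline.R` is a
thin command-line wrapper around it.

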