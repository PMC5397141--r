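# ccgmeth

Analysis of the regulatory coupling between CpG and CpHpG methylation at
CpCpG trinucleotides in plant methylomes.

## The scientific problem

In *Arabidopsis thaliana*, genes with gene-body methylation (gbM) carry CpG
methylation only, while transposable elements are methylated in the CpG,
CpHpG and CpHpH contexts (H = A, C or T). A CpCpG occurrence couples the two
systems within three bases: its first ("external") cytosine is in CHG
context, its second ("internal") cytosine is in CpG context. Bisulfite data
show that of the four joint states CpCpG, Cp<sup>m</sup>CpG,
<sup>m</sup>Cp<sup>m</sup>CpG and <sup>m</sup>CpCpG, the last — external
methylated, internal not — is essentially absent: the external cytosine can
only be methylated when the internal one is, and even then only at roughly
40% of sites. Doubly methylated CpCpGs act as seeds from which CpHpG
methylation spreads through gene bodies when the H3K9me2 demethylase IBM1
is lost, which separates gbM genes into *IBM1 targets* (they contain
Cp<sup>m</sup>CpG and gain CpHpG methylation in *ibm1*) and
*IBM1-independent* genes (CpCpG internals unmethylated; they stay clean).

`ccgmeth` implements the full analysis as reusable Bioconductor-style
components:

- **Context annotation** — strand-aware trinucleotide classification
  (CG / CHG / CHH / unknown) of every cytosine on both strands, and
  pairing of CpCpG external/internal cytosine couples
  (`annotateCytosines`, `findCCGSites`).
- **Methylation IO & filters** — Bismark per-cytosine (CX) report reader
  and writer, the "at least 5 reads in all samples" coverage filter and
  the "at least 50% CpG / 25% non-CpG methylation in WT" filter
  (`readCXReport`, `filterMinCoverage`, `filterWTMethylated`).
- **Site statistics** — per-context relative changes in mutants
  (`contextContrast`), CMT2/3- vs RdDM-dependence of CpCpG externals
  (CDC: mutant level ≤ 1% of WT in *cmt2/3*; RDC: > 20% retained;
  `classifyCCGDependency`), joint pattern calls (`ccgPattern`) and the
  Spearman correlation of internal and external methylation changes in
  the *met1-1* hypomorph (`internalExternalCorrelation`).
- **DMB calling** — 100-bp tiling bins tested with the two-proportion
  score test `z = (p1 - p2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))`
  (z² equals the Pearson chi-square statistic), with effect-size filters
  of 40% (CpG), 20% (CpHpG), 10% (CpHpH), at least 4 cytosines and mean
  depth ≥ 4 per cytosine (`scoreTest`, `callDMBs`, `overlapDMBs`).
- **Tile classification** — 500-bp tile methylation means, the
  TE / gbM-IBM1-target / gbM-IBM1-independent cascade, CpCpG counting per
  tile, Cp<sup>m</sup>CpG-based target prediction, and the cross-ecotype
  homologous-bin comparison (`tileMethylation`, `classifyTiles`,
  `predictIBM1Targets`, `compareEcotypes`).
- **Spreading profiles** — distance-resolved CpHpG methylation gain
  around doubly methylated seed sites and exponential decay fitting
  `a exp(-|d|/lambda)` (`selectSeedSites`, `distanceProfile`,
  `fitDecay`).
- **Synthetic methylomes** — a deterministic generator that plants a WT
  truth (gene bodies CpG-only, TEs methylated in all contexts, external
  CpCpG methylation conditional on the internal with probability 0.4)
  and rule-derived *met1-3*, *met1-1*, *cmt2/3*, *ddcc* and *ibm1*
  methylomes with full ground-truth labels, sampled into CX-format read
  counts (`simulationConfig`, `simulateMethylomes`, `simulateEcotypes`).

## Worked example

Simulate a 200-kb methylome set and run the core analyses:

```r
library(ccgmeth)

cfg <- simulationConfig(seed = 7)
sim <- simulateMethylomes(cfg, mutants = c("cmt2-3", "ibm1"))
sim$profiles$wt
#> MethylationProfile 'wt': 72108 sites, 72108 covered (mean depth 30)
#>   mean level over covered sites: 0.155

## joint CpCpG patterns in WT: the external-only pattern (MU) is absent
round(ccgPattern(sim$profiles$wt, sim$ccgSites)$freq, 3)
#>    UU    UM    MM    MU
#> 0.643 0.259 0.098 0.000

## CMT2/3- vs RdDM-dependence of methylated externals in cmt2/3
dep <- classifyCCGDependency(sim$profiles$wt, sim$profiles$`cmt2-3`, sim$ccgSites)
table(dep$label)
#>       CDC       RDC ambiguous
#>       624       185         1

## tile classes and CpCpG-based IBM1-target prediction
wtTiles   <- tileMethylation(sim$profiles$wt,   sim$annotations, sim$ccgSites)
ibm1Tiles <- tileMethylation(sim$profiles$ibm1, sim$annotations, sim$ccgSites)
classes   <- classifyTiles(wtTiles, ibm1Tiles)
table(classes)
#>      gbM_IBM1_target gbM_IBM1_independent                   TE                other
#>                   42                   76                   97                  185
pred <- predictIBM1Targets(ibm1Tiles, classes)
c(precision = pred$precision, recall = pred$recall)
#> precision    recall
#>         1         1
```

The pattern table reads: 64% of covered CpCpG sites are unmethylated on
both cytosines, 26% on the internal only, 10% on both — and none on the
external only. Among methylated externals, 624 lose ≥ 99% of their WT
level in *cmt2/3* (CDCs) and 185 retain > 20% (RDCs, maintained by RdDM).
Tiles with ≥ 1 internally methylated CpCpG predict the tiles that gain
CpHpG methylation in *ibm1* with perfect precision and recall here.

Spreading of CpHpG methylation away from seed sites is resolved with a
sparse-seed configuration (long gene bodies, one planted
Cp<sup>m</sup>CpG each):

```r
spreadCfg <- simulationConfig(seed = 7, chromLengths = c(chr1 = 500000),
                              geneLength = 5000, geneFraction = 0.6,
                              teFraction = 0.1, pTargetGene = 0.5,
                              pInternalMeth = 0, coverage = 100)
spread <- simulateMethylomes(spreadCfg, mutants = "ibm1")
seeds <- selectSeedSites(spread$profiles$wt, spread$profiles$ibm1, spread$ccgSites)
prof  <- distanceProfile(seeds, spread$profiles$wt, spread$profiles$ibm1,
                         spread$annotations)
fit <- fitDecay(prof)
round(c(amplitude = fit$amplitude, lambda = fit$lambda), 2)
#> amplitude    lambda
#>      0.75    300.25
```

The fitted decay length recovers the planted 300-bp spreading scale.

`runPipeline(cfg, "out/")` chains every stage (annotation, filters,
contrasts, patterns, dependency, DMBs, tiles, spreading) and writes TSV
results plus a manifest; `inst/scripts/ccgmeth-pipeline.R` wraps it for
shell use. See the vignette in `vignettes/` for the models, parameter
choices and limitations.

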