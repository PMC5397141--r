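---
title: "Methods: CpCpG methylation coupling, DMB calling and spreading analysis"
author: "ccgmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CpCpG methylation coupling, DMB calling and spreading analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

Plant methylomes superimpose three maintenance systems: MET1 copies CpG
methylation through replication; CMT2/3 maintain CpHpG (and some CpHpH)
methylation through a positive feedback loop with the H3K9
methyltransferases (KYP/SUVH4, SUVH5/6); and the RdDM pathway targets
methylation through small RNAs. A CpCpG trinucleotide places a CHG-context
cytosine (the *external*, first C) directly 5' of a CpG-context cytosine
(the *internal*, second C), so the two systems meet within one motif.

The analyses in this package quantify three linked observations:

1. **Pattern exclusion.** Classifying each covered CpCpG site by the
   binarized state of its two cytosines gives four possible patterns; the
   external-only pattern (`MU` in `ccgPattern()` notation) is essentially
   absent, and among sites with a methylated internal cytosine, only ~40%
   also methylate the external one.
2. **Quantitative coupling.** In a MET1 hypomorph that lowers CpG
   methylation genome-wide, the loss of internal methylation at a CpCpG
   predicts the loss of external methylation at the same site (Spearman
   rank correlation of the per-site changes).
3. **Spreading from seeds.** In plants lacking the H3K9me2 demethylase
   IBM1, gene bodies containing internally methylated CpCpGs gain CpHpG
   methylation; the gain at CpApG/CpTpG cytosines decreases with distance
   from the doubly methylated seed sites, and gene bodies free of
   Cp^mCpG stay protected. This partitions gene-body-methylated (gbM)
   regions into *IBM1 targets* and *IBM1-independent* regions.

# Conventions shared by all modules

* Coordinates are 1-based on the forward strand (the Bismark cytosine
  report convention). Interval containers are `GRanges`; exported BED-like
  tables use 0-based half-open starts.
* Thresholds phrased "at least" are inclusive (`>=`); "more than" / "less
  than" are strict. This is applied uniformly.
* A site with zero reads has an undefined level and is excluded from every
  level-based rule: no data, no claim.
* Strand-symmetric CpG dyads are *not* pooled: each strand's cytosine is
  an independent site throughout the analysis (the simulator, separately,
  assigns one true level per dyad because MET1 maintenance is
  strand-symmetric).
* Context labels always come from the genome sequence via
  `annotateCytosines()`; the context columns of CX input files are treated
  as display-only, so there is a single source of truth.
* Cytosines with fewer than two determinate downstream bases on their own
  strand (chromosome ends, or neighbours of `N`) are annotated `unknown`
  and excluded downstream; CpCpG occurrences whose internal cytosine is
  such a position are dropped entirely. The treatment of these edge cases
  is a package convention chosen to mirror how unknown contexts are
  usually handled by methylation extractors.

# Estimators and their parameters

## Filters

| parameter | default | meaning |
|---|---|---|
| `minReads` | 5 | minimum total reads per site, in **every** sample |
| `cgMin` | 0.50 | minimum WT level, CpG-context sites |
| `noncgMin` | 0.25 | minimum WT level, CHG/CHH sites (for CpCpG this acts on the external cytosine) |

The 25% non-CpG filter is applied per site, not per subcontext class.

## Relative changes and dependency classes

`contextContrast()` reports `(mutant - WT) / WT` per site, summarised over
the classes CG, CAG, CTG, CCG (externals) and CHH. The quantity is
undefined at WT = 0; such sites cannot pass the WT filter anyway.

`classifyCCGDependency()` labels a methylated external CDC when the
*cmt2/3* level is at most 1% of WT, RDC when more than 20% of WT is
retained, and `ambiguous` otherwise — sites between the two cutoffs are
deliberately left unassigned rather than forced into a class.

`internalExternalCorrelation()` selects sites with both cytosines at
`refMin = 0.5` or more in the reference sample (optionally also below
`selectionMax = 0.4` in a second sample, the selection used when asking
whether regained methylation returns to the same sites), and correlates
the per-site internal and external changes with Spearman's rank
correlation (average ranks on ties). Changes are *relative* to the
reference level by default — "percentage loss" here means percent of the
WT level, consistent with the relative-change convention of the context
contrasts — with `type = "absolute"` available for plain differences.
Relative changes have the additional advantage that the measured
correlation is not diluted by site-to-site variation in absolute WT
levels.

## Pattern calls

`ccgPattern()` binarizes both cytosines at 0.5. The threshold matches the
CpG WT filter and is configurable; the reported ~40% MM share among
internally methylated sites is not sensitive to moderate threshold changes
because methylated and unmethylated sites are well separated.

## DMB calling

Bins are fixed 100-bp tiles anchored at position 1 of each chromosome
(last partial tile kept; no sliding). Bin methylation for testing is the
**pooled-read proportion** (sum of methylated over sum of total reads),
not the mean of per-cytosine levels. The two-proportion score statistic

z = (m1/n1 − m2/n2) / sqrt( p̂ (1 − p̂) (1/n1 + 1/n2) ),  p̂ = (m1+m2)/(n1+n2)

is used two-sided against the standard normal; z is defined as 0 when p̂
is 0 or 1 (no information against the null). z² is algebraically the
Pearson chi-square statistic of the 2×2 table, and the test's decisions
at α = 0.01 agree with Fisher's exact test on ~98% of small tables under
a half-null/half-alternative composition. A DMB requires, conjunctively:
p < 0.01 (raw by default; a Benjamini–Hochberg option exists but is off,
matching standard practice for this binned test), |difference| ≥ 0.40 /
0.20 / 0.10 for CG / CHG / CHH, at least 4 cytosines, and mean reads per
cytosine ≥ 4 **in each sample** (the stricter per-sample reading of the
depth rule). CHG calls can optionally be restricted to subcontexts
(`CAG`/`CTG` vs `CCG`).

## Tile classification

`tileMethylation()` uses 500-bp tiles and the **mean of per-cytosine
levels** over covered cytosines — deliberately a different aggregation
than the DMB caller, since tile classification mirrors a mean-methylation
selection; both conventions are documented and tested. The cascade in
`classifyTiles()` is: TE if WT CHG ≥ 0.50; else gbM if WT CG ≥ 0.10 and
WT CHG < 0.05 and WT CHH < 0.05 (the non-CpG bound applied to CHG and CHH
separately); gbM tiles with ibm1 CHG gain ≥ 0.50 are IBM1 targets, with
gain < 0.05 IBM1-independent, and the band in between stays `other`
(retained, not discarded). The CHG gain is computed context-wide,
including CCG externals. A tile's internal-methylation status
(`nCCGInternalMeth`, threshold 0.5) may be read from an ibm1 sample in
place of WT because the ibm1 mutation does not affect CpG methylation.
`predictIBM1Targets()` predicts "target" from the presence of at least
one internally methylated CpCpG.

`compareEcotypes()` consumes a precomputed homologous-bin table (the
cross-genome alignment itself is out of scope), enforcing alignment
lengths of 400–600 bp and ≥ 1 CpCpG per bin, and classifies each pair by
ibm1 CHG methylation: one-sided gains need ≥ 0.50 in one ecotype and
< 0.05 in the other.

## Spreading profiles

Seeds are CpCpG sites whose external cytosine is below 15% in WT
(strict) and above 25% in the mutant (strict); the thresholds are applied
to the external cytosine only (the site's doubly methylated state is
implied because externals gain only where internals are methylated).
Isolation (no other seed within 500 bp, strand-agnostic and symmetric) is
flagged and can be required. Distances are signed and oriented 5'→3' on
the seed strand with the external cytosine as origin; the window is
half-open `[-window, window)` so every 50-bp bin has full width. A
cytosine within the window of k seeds contributes k times; seed externals
themselves never contribute. The default window of ±2000 bp covers the
visible decay; the CpG-context control profile (same seeds, CG sites) is
the negative control and should be flat at 0.

`fitDecay()` folds the profile on |d| and fits `a exp(-|d|/lambda)` by
weighted least squares (weights = per-bin contribution counts),
initialised from a log-linear regression on the positive bins, via
Levenberg–Marquardt. An all-zero profile returns amplitude 0; a
non-decreasing profile is reported with a `poorFit` flag and a warning,
never an error. Note the estimator assumes seeds sparse relative to the
window: under dense seeds (many per gene) the observed gain field is the
envelope of nearby kernels and the fitted `lambda` is biased upward, which
is why decay estimation uses the sparse-seed configuration below.

# The synthetic methylome generator

`simulationConfig()` fixes every parameter; the same seed always
reproduces byte-identical output (genome, truth, read counts). The genome
is i.i.d. sequence at plant-like 36% GC, partitioned into tile-aligned
gene-body and TE intervals plus background, each gene/TE interval
guaranteed at least one usable CpCpG (bounded rejection resampling).

WT truth rules:

* Gene bodies: CpG dyads at Beta(60, 10) (mean 0.86) — except CpCpG
  internal dyads, which are methylated only in *planted IBM1-target
  genes* (a fraction `pTargetGene = 1/3` of genes, close to the observed
  share of targets among gbM regions). Within a target gene each internal
  dyad is methylated with probability `pInternalMeth` (default 1,
  matching the observation that in target bins nearly all internal
  cytosines are methylated; at least one is always planted, and the value
  0 plants exactly one at the CpCpG nearest the gene midpoint). All
  gene-body non-CpG cytosines sit at the noise floor.
* TEs: CpG at Beta(60, 10), CAG/CTG at Beta(42, 18) (mean 0.70), CHH at
  Beta(6, 14) (mean 0.30). A CpCpG external is methylated only if its
  internal dyad is (level ≥ 0.5), then with probability `qExt = 0.4` —
  the generator never creates the forbidden external-only pattern. A
  fraction `rdmFrac = 0.2` of methylated externals (matching the observed
  RDC share of classified sites) is flagged RdDM-dependent.
* Background and all "unmethylated" cytosines: noise floor
  `epsilon = 0.01`, because real bisulfite data never sit at exactly zero
  and relative-change arithmetic stays defined.

Mutant rules (`deriveMutantState()`):

* *met1-3* (null): CpG and CpCpG externals to the floor; CAG/CTG/CHH
  unchanged.
* *met1-1* (hypomorph): per-dyad retention Beta(0.4, 1.2) (mean 0.25 —
  the hypomorph retains about a quarter of WT CpG methylation); external
  retention coupled to the internal dyad's retention through a Gaussian
  copula with Spearman `met1Rho = 0.87`. The copula is a modelling choice:
  only the observed rank correlation constrains the mechanism.
* *cmt2/3*: CAG/CTG to the floor; CDC externals retain Uniform(0, 0.001)
  of WT — a *relative* residual, because the CDC definition ("at least
  99% of WT methylation lost") is relative to the WT level — and RDC
  externals retain Uniform(0.4, 0.8).
* *ddcc*: all CHG and CHH to the floor; CpG unchanged.
* *ibm1*: CpG and CpHpH unchanged. Within planted target genes, each CHG
  cytosine gains `a exp(-d/lambda)` (defaults a = 0.75, lambda = 300 bp;
  the exponential kernel is itself a modelling choice for testability —
  the real spreading law is only known to decrease with distance), where
  d is the distance to the nearest internally methylated CpCpG external
  of the same gene; CpCpG externals whose internal is unmethylated are
  *excluded* from the gain, because the external-only pattern is excluded
  by the coupling rule — letting them gain would contradict the
  observation that such sites are only negligibly affected.

Read counts are Poisson(coverage) totals (a negative-binomial option via
`dispersion` exists for robustness checks) with Binomial(total, level)
methylated reads.

What the generator does **not** emulate: read-level artefacts (bisulfite
conversion failure, mapping bias, duplicate reads), chromatin covariates
(H3K9me2 levels), realistic gene/TE length and spacing distributions,
linkage between neighbouring sites beyond CpG dyads, and transgenerational
dynamics. Tests passing on it therefore validate the estimators'
correctness and calibration under clean sampling noise — not robustness to
alignment or conversion artefacts in real libraries.

# Study conditions used by the tests and the acceptance script

Chosen once, at design time, as desk-scale analogues of the real
experiments:

* Pattern, dependency, DMB and tile analyses: 200-kb two-chromosome
  genome, coverage 20–30×.
* met1-1 coupling: 400-kb TE-rich genome (TE fraction 0.4) at 150× —
  the measured Spearman is attenuated by binomial sampling noise (a
  property of the estimator, not of the coupling), so this analysis uses
  deep coverage like the pooled libraries it emulates; the recovered
  value is expected slightly below the planted 0.87.
* Spreading: 500-kb genome of 5-kb gene bodies, half of them targets with
  exactly one central seed, 100× — long genes keep the ±2-kb window
  inside the gene and sparse seeds keep kernels non-overlapping, the
  regime in which the decay length is identifiable.

# Numerical choices and degenerate inputs

* Score test with pooled proportion 0 or 1: z = 0, p = 1.
* Bins or tiles with no covered cytosine of a context: `NA` mean;
  classification sends unclassifiable tiles to `other`.
* Spearman correlation requires ≥ 3 selected sites, otherwise an error.
* Decay fitting requires ≥ 5 non-empty bins; convergence failure returns
  the log-linear start values with a warning.
* All set operations and outputs are deterministically ordered
  (chromosome, then position), making pipeline runs byte-reproducible.

# Known limitations

* The CDC/RDC thresholds act on noisy level ratios; at 20× a small
  fraction of true CDCs with a single methylated read land in
  `ambiguous`. Accuracy against planted truth is ~0.99 at that depth.
* `fitDecay()` assumes a single shared kernel; overlapping kernels from
  dense seeds bias `lambda` upward (see above).
* The ecotype comparison consumes a homology table as given; alignment
  quality is the caller's responsibility beyond the length bounds.
* Tiles approximate gene bodies; no gene-model annotation is used.
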