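Package: ccgmeth
Title: CpCpG Methylation Coupling and CpHpG Spreading Analysis for Plant
    Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse the coupling between CpG methylation of the
    internal cytosine of CpCpG trinucleotides and CpHpG methylation of the
    external cytosine in plant bisulfite methylomes. Provides strand-aware
    trinucleotide context annotation of a genome, pairing of CpCpG
    internal/external cytosine couples, readers and writers for Bismark
    per-cytosine (CX) reports with the standard coverage and wild-type
    methylation filters, mutant-versus-wild-type context contrasts, CMT2/3-
    versus RdDM-dependence classification of CpCpG sites, joint
    internal/external methylation pattern calls, a two-proportion score test
    for 100-bp differentially methylated bins, 500-bp tile classification into
    gene-body-methylated IBM1 targets, IBM1-independent regions and
    transposable elements, distance-resolved spreading profiles around doubly
    methylated CpCpG seed sites with exponential decay fitting, a cross-ecotype
    homologous-bin comparison, and a fully deterministic synthetic methylome
    generator with planted truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    data.table,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
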