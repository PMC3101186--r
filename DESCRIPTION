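Package: snpqc
Title: Quality Control of SNP Arrays via Individual-Level Allele Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quality assessment of genome-wide SNP genotyping arrays and DNA
    samples. Estimates individual-level allele frequencies from allele-specific
    hybridization intensities with a coefficient of preferential
    amplification/hybridization (CPA) adjustment, builds genotype-specific
    allele-frequency references, and scores each array with standardized-distance
    quality indices summarized by a winsorized mean (genotype-based Q1 and
    nearest-mean-based Q2). Array-level indices are modeled by lognormal
    distributions; empirical upper confidence limits flag poor-quality arrays.
    Includes a Hardy-Weinberg/beta generative simulator for detection-rate power
    studies, diagnostic plots (allele-frequency profiles, quality-index heatmaps
    and polygon plots, genotype call rates), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
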