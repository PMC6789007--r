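Package: retrotools
Title: Retrotransposition Analysis for Exome-Sequenced Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection and population-genetic analysis of retrotransposition
    events in paired-end exome sequencing cohorts. Implements a two-step
    processed-pseudogene (retrogene) caller driven by discordant and split
    read pairs, post-discovery filtering and consequence annotation of mobile
    element insertion (MEI) call sets, trio de novo candidate identification
    with parental-mosaicism statistics and long-read phasing summaries,
    Watterson-based MEI mutation-rate estimation under accessibility masks
    with genome-wide de novo burden simulation and enrichment tests,
    selective-constraint metrics (singleton and pLI proportions), and a
    case/control CpG methylation-signature classifier. Ships seed-stable
    synthetic-data generators (toy genomes, read sets, cohort site-frequency
    spectra, trio genotypes, beta-value matrices) so every stage can be
    exercised without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
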