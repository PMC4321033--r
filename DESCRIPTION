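Package: mosaicpaint
Title: Ancestry Painting, Karyotyping and Circadian Analysis for Mixed
    Genetic Stocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the pedigree of inbred plant genetic
    stocks from whole-genome resequencing data. Paints a query genome into
    recurrent-parent-like and donor-like ancestry blocks from windowed SNP
    density and donor-panel sharing, refines breakpoints to marker
    resolution, and derives lower bounds on historical crossover and
    meiosis counts. Calls whole-chromosome ploidy from normalized read
    depth, performs exact transmission and segregation tests for trisomic
    and Mendelian models, and estimates circadian period, amplitude and
    relative amplitude error from luminescence time courses. A forward
    simulator of outcross-plus-selfing pedigrees with Poisson crossovers,
    optional trisomy, sequencing-style SNP and depth emission and damped
    sinusoidal traces provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
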