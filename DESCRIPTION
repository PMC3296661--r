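Package: polyBSA
Title: SNP Discovery and Bulked Segregant Analysis for Polyploid Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies varietal polymorphisms (hemi-SNPs and simple SNPs)
    between two parental lines of a polyploid species from RNA-seq pileups
    aligned to a collapsed unigene reference, distinguishing them from fixed
    inter-homoeologue polymorphisms via IUPAC ambiguity consensus calls.
    Ranks candidate markers by the bulk frequency ratio (BFR) of the
    informative base between two phenotype-contrasted bulks of recombinant
    lines, with depth, enrichment and SNP-density (paralogue) filters.
    Includes RPKM expression profiling, closed-form sequencing-coverage and
    mapping-resolution calculators, and a seeded tetraploid transcriptome
    simulator (homoeologue pairs, recombinant substitution lines, bulks,
    pileups) with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
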