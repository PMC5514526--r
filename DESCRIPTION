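Package: rankvar
Title: Weighted Ranking and Inheritance-Model Filtering of Annotated Sequence Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks single-nucleotide variants from ANNOVAR-style annotation
    tables or VCF files by encoding each annotation source (genomic region
    class, deleteriousness predictions, conservation scores, population
    allele frequencies, novelty, regulatory and clinical flags) into a
    weight between 0 and 1 and summing the user-weighted encoded values
    into a single rank score. Provides Mendelian inheritance-model filters
    (autosomal dominant, autosomal recessive, X-linked recessive),
    minor-allele-frequency and functional-class filters, per-gene
    summaries, case-control genotype tallying and filtering for
    multi-sample VCFs, a synthetic exome generator with causal-gene
    spike-ins for benchmarking, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    optparse,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
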