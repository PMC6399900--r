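Package: poolscan
Title: Pool-Seq Genome Scans for Differentiated Regions Between
    Closely Related Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Error-aware allele-frequency and site-frequency-spectrum
    inference from pooled sequencing read counts, Hudson-style pi/FST
    sliding-window genome scans with differentiated-region calling
    against a simulated panmixia null, and a two-locus
    migration-selection-drift forward simulator that shows why regions
    maintained by divergent selection under high gene flow are short
    and carry fixed differences.  Includes a synthetic two-species
    Pool-seq data generator with known truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
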