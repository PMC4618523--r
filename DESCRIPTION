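Package: bsacross
Title: Bulk Segregant Mapping of Higher-Order Epistasis in Yeast Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for bulk segregant analysis (BSA)
    of colony-morphology traits controlled by higher-order genetic
    interactions in Saccharomyces cerevisiae crosses of the lab strain BY and
    the clinical isolate 3S. Provides a seeded meiosis and backcross
    simulator over dense biallelic SNP maps, a penetrance-rule model of the
    five-way and six-way epistatic genotypes that produce rough colony
    morphology in ira2 and sfl1 mutant backgrounds, pooled-sequencing allele
    count simulation, the sliding-window 95%-fixation locus caller with
    smallest-interval delimitation, exact enumeration of genotype-class
    expectations, and TSV/BED/mpileup interfaces with a small command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
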