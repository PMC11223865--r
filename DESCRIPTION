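Package: snvpam
Title: Allele-Specific CRISPR Targeting via SNV-Derived PAM Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies protospacer-adjacent motifs (PAMs) that are created
    by a single-nucleotide variant and absent from the wild-type allele, so
    that a Cas nuclease can cleave the mutant allele while sparing the
    wild-type copy. Ships a curated registry of class-2 Cas enzymes with
    their IUPAC PAM patterns and a selectivity scoring scheme, a
    both-orientation exclusivity search around each variant, batch screening
    statistics over variant sets, and a structural companion protocol:
    detection of PAM-contacting protein residues in a Cas-DNA complex,
    BLOSUM62-guided mutation candidates, an alignment-based conservation
    index, and iterative ranking of candidates over a pluggable
    change-in-binding-energy scorer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
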