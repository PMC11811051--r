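Package: mimircraft
Title: Design and Analysis of miRNA Mimics on Endogenous Hairpin Scaffolds
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for designing microRNA mimics (mimiRs) embedded in an
    endogenous precursor hairpin scaffold, for classifying miRNA-target
    complementarity modes (near-full, seed-only, seed plus supplementary,
    central mismatches), for scanning transcripts for binding sites with
    predicted cleavage coordinates, for building reporter mRNA constructs
    carrying multiple seed sites in the 3' UTR, and for desk-scale
    quantification of guide/star strand loading from AGO-IP small-RNA reads,
    including a seeded synthetic-read simulator. Templates for in vitro
    transcription are handled in the ordered-oligo convention (reverse
    complement of promoter plus transcript) with T7, T7 class II phi2.5,
    CleanCap-AG and SP6 promoter variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    Biostrings,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, SmallRNA, SequenceMatching, Software
RoxygenNote: 7.3.3
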