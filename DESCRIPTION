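Package: phagescan
Title: Phage-Display Peptide Library Design, Enrichment Scoring and Pharmacophore Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for tiled hexadecapeptide phage-display screens
    against chemokine panels: deterministic design of overlapping peptide
    libraries with Cys-to-Ala/Ser variants, NNK saturation-mutagenesis
    libraries and scrambled controls with their arm-flanked 81-mer
    oligonucleotides; conversion of paired-end amplicon reads into peptide
    count tables under strict insert filters; enrichment (log2E) scoring with
    zero-count floor substitution, residue-level mapping with rolling-median
    smoothing and region-of-interest detection, promiscuity filtering and
    mutational delta-log2E; substitution-class bookkeeping with a Monte-Carlo
    Dunnett many-to-one test; aggregation of docked peptide:chemokine pose
    ensembles into per-residue weighted proximity and contact profiles; and a
    seeded synthetic-data generator emulating affinity-weighted multinomial
    panning so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    zoo,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
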