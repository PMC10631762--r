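Package: tcrmhc
Title: Germline-Encoded TCR-MHC Compatibility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Antigen-independent analysis of compatibility between
    germline-encoded T cell receptor (TCR) regions and MHC molecules.
    Encodes CDR loops and MHC helix residues into integer alignment
    matrices, computes position-sensitive Shannon entropy and
    subsampling-averaged mutual information, position-sensitive
    biophysical property profiles (charge, hydropathy), a trigram-based
    residue interaction potential for every V-gene by HLA-allele pair
    with per-residue decomposition, and a structure-based contact
    quantifier for TCR-pMHC complexes with permutation-test group
    comparisons. Includes seeded synthetic-data generators for
    repertoires with controlled conservation and covariation and for
    toy coordinate files with planted contacts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
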