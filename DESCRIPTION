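Package: abfv
Title: Antibody Fv Extraction, Numbering and Antibody-Antigen Set Construction
    from PDB Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processes legacy PDB-format coordinate files containing antibody
    structures. Identifies light, heavy and antigen chains by alignment
    against consensus variable-domain sequences, applies the Kabat, Chothia
    and Martin numbering schemes to the variable (Fv) domains while trimming
    constant domains, reconstructs light-chain dimers from crystallographic
    symmetry (REMARK 350 BIOMT), pairs light and heavy chains by inter-chain
    atomic contacts, classifies candidate antigens (protein, nucleic acid and
    HETATM hapten groups) against antibody-binding proteins using CDR versus
    framework contact rules, resolves anti-idiotype complexes, splits entries
    into individual antibody-antigen sets annotated with REMARK 950 records,
    and clusters identical antibodies across the resulting datasets to
    produce redundancy lists and non-redundant representatives. Includes a
    seeded generator of synthetic PDB entries for testing every pipeline
    stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
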