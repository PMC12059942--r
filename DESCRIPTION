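Package: allobench
Title: Curation of Allosteric-Site Datasets and Benchmarking of Site Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds clean tabular datasets of allosteric and active sites from
    ASD-style XML annotations and PDB-format structures, and scores allosteric
    site predictions against the known sites with the Jaccard index.  The
    curation pipeline reconciles obsolete identifiers, merges active-site
    annotations from UniProt-style and M-CSA-style sources, synchronizes
    residue numbering between canonical sequences and author numbering via
    global sequence alignment, merges multi-model structure files, detects
    missing residues and emits target-template alignments for an external
    modeling engine, gates rebuilt models with the local distance difference
    test (lDDT), and derives allosteric sites geometrically as all residues
    within a distance cutoff of the bound modulator.  A benchmarking harness
    computes Jaccard indices of top-ranked predicted sites against known
    sites, centroid distances, per-tool summaries and accuracy-versus-cutoff
    curves.  A synthetic-fixture generator produces self-consistent
    structures, annotations and mock predictions so the whole pipeline runs
    without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
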