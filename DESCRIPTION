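Package: mapscir
Title: Multiple Protein Structure Alignment with Consensus Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Iterative multiple alignment of protein backbones represented as
    alpha-carbon coordinate triples. Implements the MAPSCI algorithm: a
    consensus pseudo-structure is chosen from the input set, every protein is
    aligned to it by dynamic programming over squared inter-atomic distances,
    the pairwise alignments are merged center-star style, and closed-form
    optimal rigid-body transforms (SVD/Kabsch) are interleaved with centroid
    consensus updates until the Sum-of-Consensus distance converges. Includes
    strict-core and core-RMSD evaluation metrics, PDB and NBRF/PIR input and
    output, and a synthetic backbone-family generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, bio3d, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'geometry.R'
    'pairwise.R'
    'multialign.R'
    'consensus.R'
    'coremetrics.R'
    'driver.R'
    'mapscir-package.R'
    'structio.R'
    'synthetic.R'
    'utils.R'
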