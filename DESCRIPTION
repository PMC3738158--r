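Package: SibJoinR
Title: Half-Sibling Population Reconstruction from Microsatellite Genotypes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs maternal and paternal half-sibling partitions of a
    diploid population from codominant microsatellite genotypes. Implements the
    SibJoin heuristic, a Mendelian-constrained single-linkage agglomerative
    clustering over a bipartite cluster graph; an exact 0/1 integer program that
    finds the minimum set of individuals whose removal makes a candidate
    half-sib partitioning valid under Mendelian inheritance; a MONOTONE
    ONE-IN-THREE SAT to VALID HALF-SIBLING PARTITIONING reduction for generating
    provably hard instances; a forward population simulator with ground truth;
    shared-allele similarity analytics; and accuracy metrics based on the
    variation of information.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, igraph, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Genetics, Clustering, Software
RoxygenNote: 7.3.3
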