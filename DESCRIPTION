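Package: conthread
Title: Contact-Guided Protein Threading by Eigen-Decomposition of Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fold recognition by threading a query sequence through a library
    of structure templates under the guidance of predicted residue-residue
    contact maps. Contact maps are factorised into their top-K
    positive-eigenvalue components, giving each residue a K-dimensional
    contact-profile vector; queries are aligned to templates by semi-global
    Needleman-Wunsch dynamic programming with affine gaps over a combined
    contact/profile/secondary-structure score, searching the 2^K eigenvector
    sign ambiguity either exhaustively or greedily. Templates are ranked by
    contact-map overlap (CMOq) and its library Z-score. Includes readers for
    PDB/mmCIF structures, PSI-BLAST ASCII PSSMs, PSIPRED .ss2 files and CASP
    RR contact lists, a deterministic synthetic-structure fixture generator,
    and the contact-restraint energy and C-score confidence formulas used
    downstream of threading.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
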