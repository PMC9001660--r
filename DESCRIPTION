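Package: tcrdrive
Title: Antigen-Drive Analysis of T Cell Receptor Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bulk and single-cell T cell receptor (TCR)
    repertoires with a focus on clonal lymphoproliferations such as T cell
    large granular lymphocytic leukemia (T-LGLL). Reads AIRR, immunoSEQ and
    10x V(D)J contig tables; removes non-functional clonotypes and
    subsamples repertoires to a fixed read depth; computes clonality and
    expansion metrics (Gini, Shannon, expansion classes) and clonotype
    occurrence across control cohorts; re-implements GLIPH-style CDR3
    amino-acid similarity grouping (local k-mer motif enrichment against a
    reference repertoire plus near-identical global linking) to classify
    expanded leukemic clones as antigen-driven or not; scores gene-set
    modules on expression matrices (expression-matched control bins and
    geometric means) with a simple differential-expression test; and
    simulates repertoires, cohorts and expression matrices with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
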