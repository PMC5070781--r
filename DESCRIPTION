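Package: schoolnet
Title: Friendship-Network Communities in Schools via Spectral Modularity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing friendship-nomination surveys from schools
    as undirected networks. Builds friendship networks by reciprocity
    filtering of directed nominations, flags and optionally removes "mixed"
    links (friendship ties that are also sibling or relative ties), computes
    standard network summaries (degree, density, clustering, components,
    giant component), detects communities by recursive leading-eigenvector
    modularity bisection, classifies communities against classroom
    composition into confined/unconfined x homogeneous/heterogeneous
    classes, and generates synthetic classroom-blocked school networks with
    a kinship overlay and imperfect nomination reciprocity so the full
    pipeline can be exercised without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
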