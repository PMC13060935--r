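Package: tanglepatch
Title: Evidence-Based Traversal of Assembly Graph Tangles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Resolves unresolved tangles in long-read assembly graphs and emits
    model patch sequences for the corresponding scaffold gaps. Given a GFA
    assembly graph, per-node sequencing coverage and long-read-to-graph
    alignments in GAF, the package detects tangles delimited by unique boundary
    edges, estimates integer edge multiplicities by exact optimisation of a
    flow-constrained integer program that minimises absolute deviation from
    coverage-implied copy numbers, expands the solution into a multigraph,
    finds an Eulerian traversal with Hierholzer's algorithm and optimises it
    under subpath-swap moves to maximise the number of reads supported as
    exact substrings in the alphabet of edge labels. Outputs include the model
    sequence in FASTA, the traversal path, and reference-free quality metrics
    (coverage divergence and unsupported-read fraction). A synthetic fixture
    generator plants repeat-array tangles with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
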