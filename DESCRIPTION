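Package: pantag
Title: Tag-Array Indexing for Pangenome Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Lossless haplotype-aware indexing of pangenome graphs with tag
    arrays. Builds a multi-string Burrows-Wheeler transform (FMD layout:
    every haplotype plus its reverse complement) over the haplotype walks of
    a GFA1 graph, annotates each BWT position with the graph position
    (node, offset, orientation) its suffix starts at, and stores the
    annotation run-length compressed. Construction uses unique k-mer
    anchoring, graph-based backward extension and haplotype traversal over a
    run-length B+ tree, with per-component builds and an interleaving merge.
    Queries report all distinct graph positions matching a pattern, find
    maximal exact matches with their tags, and translate an interval on one
    haplotype to all haplotypes traversing the same node starts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
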