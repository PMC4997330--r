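Package: bdpc
Title: Positional Analysis of DNase I Hypersensitive Sites in Bidirectional
    Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies divergent (head-to-head) gene pairs and their
    bidirectional promoters (BDPs) from genome annotation, classifies each
    BDP by the position of DNase I hypersensitive sites (DHSs) within it
    (one centred DHS, one off-centre DHS, two DHSs, or none), and relates
    that positional class to expression level, gene-pair coexpression and
    nucleosome or histone-mark occupancy. Includes two-sample
    Kolmogorov-Smirnov comparisons of FPKM distributions, Pearson
    coexpression with random non-adjacent control pairs, windowed
    per-bp-per-million metagene occupancy profiles oriented by expression,
    and a synthetic-data generator with known ground truth (planted DHS
    categories, pair correlations, distance-dependent expression, and
    phased nucleosome arrays with a nucleosome-depleted region) so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
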