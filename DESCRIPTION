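Package: clipshift
Title: Integrative Analysis of RBP CLIP Binding Maps, RNA Abundance, and
    Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating RNA-binding-protein (RBP) HITS-CLIP binding
    maps to RNA abundance and translation in knockout-versus-wild-type
    designs. Implements peak calling from CLIP tag pileups with a
    permutation FDR against a genic background, robust binding-site
    definition by replicate and antiserum support, cross-link-induced
    truncation site (CITS) detection, target classification by transcript
    region and binding magnitude, cumulative-distribution shift tests on
    fold changes, a translation-efficiency delta statistic with pre-ranked
    running-sum enrichment, sliding-window ribosome-footprint coverage with
    per-transcript binomial tests and metagene profiles, and time-course
    cluster enrichment. A seeded synthetic-data generator produces gene
    models, CLIP tags, count matrices, coverage profiles, and time-course
    matrices with the statistical structure these analyses expect, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rtracklayer,
    GenomicRanges,
    IRanges,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
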