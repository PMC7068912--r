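Package: tripletPhase
Title: Reading-Frame Phase Structure of Genome Fragments in Triplet
    Frequency Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Cuts an annotated genome into overlapping fragments, maps each
    fragment to its non-overlapping triplet (3-mer) frequency dictionary,
    and labels fragments by reading-frame phase on either strand, by
    non-coding ("junk") content, or by membership in dense GC-rich RNA gene
    blocks ("tail").  Provides the 63-dimensional embedding obtained by
    excluding the least-variable triplet, principal-component views,
    K-means verification of the cluster structure, circuit-direction
    (mirror versus rotational) symmetry classification of the six coding
    phase centroids, up/down orientation, phase-abundance statistics, and
    GC-content ensemble summaries.  Includes a seeded generator of
    annotated synthetic genomes with per-position ground truth, plus an
    exact analytic oracle for the triplet distribution expected in each
    phase under an i.i.d. codon model, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'cluster-geometry.R'
    'fragmentation.R'
    'gc-analysis.R'
    'genome-io.R'
    'phase-labeling.R'
    'pipeline.R'
    'record-lengths.R'
    'synthetic-data.R'
    'triplet-space.R'
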