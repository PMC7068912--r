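#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomicRanges GRanges strand start end width seqnames
#' @importFrom IRanges IRanges coverage
#' @importFrom Biostrings DNAString DNAStringSet
NULL

## The 64 triplets over {A,C,G,T} in lexicographic order; every frequency
## vector in the package is indexed by this order.
TRIPLETS <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0), c("A", "C", "G", "T"), paste0))
TRIPLETS <- sort(TRIPLETS)

## The eight fragment labels, in canonical order.
PHASE_LEVELS <- c("F0", "F1", "F2", "B0", "B1", "B2", "JUNK", "TAIL")
CODING_PHASES <- PHASE_LEVELS[1:6]

REGION_CATEGORIES <- c("protein_coding", "tRNA", "rRNA", "other_RNA")

#' GenomeRecord: a sequence plus its annotated regions
#'
#' The unit of analysis: one genome sequence (uppercase, alphabet
#' \{A,C,G,T\} plus possibly ambiguous IUPAC symbols) together with the
#' annotated regions used for phase labeling.  Regions are held as a
#' \link[GenomicRanges]{GRanges} on a single seqname equal to the record id,
#' with strand \code{+}/\code{-} and a metadata column \code{category} in
#' \code{protein_coding}, \code{tRNA}, \code{rRNA}, \code{other_RNA}.
#' All four categories count as "coding" for phase labeling; the category is
#' retained so tail detection can single out RNA genes.
#'
#' @slot id accession or identifier string.
#' @slot sequence a \link[Biostrings]{DNAString}; coordinates are 1-based.
#' @slot regions a \code{GRanges} of annotated regions.
#' @slot isCircular logical flag recorded from the source; the sequence is
#'   stored (and fragmented) linearly regardless.
#'
#' @export
setClass("GenomeRecord",
         representation(id = "character",
                        sequence = "DNAString",
                        regions = "GRanges",
                        isCircular = "logical"))

setValidity("GenomeRecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@sequence) == 0L)
    msg <- c(msg, "sequence must be non-empty")
  rg <- object@regions
  if (length(rg)) {
    if (any(GenomicRanges::start(rg) < 1L) ||
        any(GenomicRanges::end(rg) > length(object@sequence)))
      msg <- c(msg, "region coordinates fall outside [1, genome length]")
    if (is.null(mcols(rg)$category) ||
        !all(as.character(mcols(rg)$category) %in% REGION_CATEGORIES))
      msg <- c(msg, sprintf("regions need a 'category' column with values in {%s}",
                            paste(REGION_CATEGORIES, collapse = ", ")))
    if (any(as.character(GenomicRanges::strand(rg)) == "*"))
      msg <- c(msg, "regions must be stranded (+ or -)")
  }
  if (length(msg)) msg else TRUE
})

#' FragmentSet: overlapping windows cut from one genome
#'
#' Fragments of fixed length \code{L} taken every \code{R} positions,
#' starting at position 1.  \code{L} must be odd and divisible by 3 so the
#' center position \code{start + (L-1)/2} is an integer and every window
#' tiles an integer number of triplets; \code{R} must not be divisible by 3
#' so consecutive fragments sample all three frame offsets.
#'
#' @slot genomeId id of the parent record.
#' @slot L,R fragment length and step (integers).
#' @slot ranges an \link[IRanges]{IRanges} of fragment coordinates.
#' @slot sequences a \code{DNAStringSet}, parallel to \code{ranges}.
#'
#' @export
setClass("FragmentSet",
         representation(genomeId = "character",
                        L = "integer",
                        R = "integer",
                        ranges = "IRanges",
                        sequences = "DNAStringSet"))

setValidity("FragmentSet", function(object) {
  msg <- character()
  if (object@L %% 2L == 0L || object@L %% 3L != 0L)
    msg <- c(msg, "L must be odd and divisible by 3")
  if (object@R %% 3L == 0L)
    msg <- c(msg, "R must not be divisible by 3")
  if (length(object@ranges) != length(object@sequences))
    msg <- c(msg, "ranges and sequences lengths differ")
  if (length(msg)) msg else TRUE
})

#' TripletDictionary: the W(3,3) frequency dictionary of one sequence
#'
#' Frequencies of the 64 triplets counted by tiling the sequence with
#' non-overlapping windows from its first position; windows containing a
#' non-ACGT symbol are skipped and do not contribute to \code{M}.
#' When \code{M > 0} the frequencies sum to 1.
#'
#' @slot freqs named numeric of length 64 (lexicographic triplet order).
#' @slot M integer count of tiled (clean) triplets.
#'
#' @export
setClass("TripletDictionary",
         representation(freqs = "numeric", M = "integer"))

setValidity("TripletDictionary", function(object) {
  msg <- character()
  if (length(object@freqs) != 64L || !identical(names(object@freqs), TRIPLETS))
    msg <- c(msg, "freqs must be named by the 64 triplets in lexicographic order")
  if (object@M > 0L && abs(sum(object@freqs) - 1) > 1e-9)
    msg <- c(msg, "frequencies must sum to 1 when M > 0")
  if (length(msg)) msg else TRUE
})

#' TripletFrequencyMatrix: fragments as points in 63 dimensions
#'
#' Holds the full n x 64 frequency matrix together with the excluded
#' triplet; \code{\link{points63}} returns the n x 63 view used for
#' embedding and clustering.  The excluded triplet is, by construction, the
#' one whose frequency varies least over the fragment ensemble, so dropping
#' it discards the least discriminating coordinate.
#'
#' @slot freqs n x 64 matrix, columns in lexicographic triplet order.
#' @slot M integer vector of clean-triplet counts per fragment.
#' @slot excludedTriplet the dropped triplet.
#' @slot genomeId id of the parent record.
#'
#' @export
setClass("TripletFrequencyMatrix",
         representation(freqs = "matrix",
                        M = "integer",
                        excludedTriplet = "character",
                        genomeId = "character"))

setValidity("TripletFrequencyMatrix", function(object) {
  msg <- character()
  if (ncol(object@freqs) != 64L || !identical(colnames(object@freqs), TRIPLETS))
    msg <- c(msg, "freqs must have the 64 lexicographic triplet columns")
  if (!(object@excludedTriplet %in% TRIPLETS))
    msg <- c(msg, "excludedTriplet must be one of the 64 triplets")
  if (nrow(object@freqs) != length(object@M))
    msg <- c(msg, "M must be parallel to the rows of freqs")
  if (length(msg)) msg else TRUE
})

#' PhaseEmbedding: principal-component coordinates of the fragments
#'
#' Top three principal components of the column-centered 63-dimensional
#' frequency matrix, with a deterministic sign convention (each component is
#' flipped so its largest-magnitude loading is positive).
#'
#' @slot coords n x 3 matrix of PC coordinates.
#' @slot explainedVariance fraction of total variance per component.
#' @slot signFlips the +/-1 applied to each component by the convention.
#'
#' @export
setClass("PhaseEmbedding",
         representation(coords = "matrix",
                        explainedVariance = "numeric",
                        signFlips = "numeric"))

#' PhaseGeometry: centroid geometry and abundance statistics
#'
#' Per-phase centroids in PC space, the signed circuit areas of the forward
#' and backward phase triangles in a chosen PC plane, the resulting symmetry
#' type (\code{mirror} when the circuits are counter-directed, i.e. the
#' signed areas have opposite signs; \code{rotational} otherwise), the
#' up/down orientation of the merged F2/B2 cluster along PC3, and the
#' phase-abundance statistics.
#'
#' @slot centroids matrix of per-label centroids (rows named by label).
#' @slot areaF,areaB signed areas of the (F0,F1,F2) and (B0,B1,B2) circuits.
#' @slot symmetry "mirror" or "rotational".
#' @slot orientation "U" or "D".
#' @slot plane description of the plane used for the circuit areas
#'   ("centroid" or a PC pair such as "PC1,PC2").
#' @slot abundances named integer counts per label (all eight labels).
#' @slot codingSd population standard deviation of the six coding counts.
#' @slot bias named numeric: |F0|-|B0|, |F1|-|B1|, |F2|-|B2|.
#'
#' @export
setClass("PhaseGeometry",
         representation(centroids = "matrix",
                        areaF = "numeric",
                        areaB = "numeric",
                        symmetry = "character",
                        orientation = "character",
                        plane = "character",
                        abundances = "integer",
                        codingSd = "numeric",
                        bias = "numeric"))

#' GCProfile: per-fragment and ensemble GC statistics
#'
#' @slot perFragment data.frame with columns index, center, gc, phase.
#' @slot genomeGC whole-genome GC fraction.
#' @slot ensembleMeans named numeric over genome/coding/junk/tail (tail is
#'   \code{NA} when the genome has no TAIL fragments).
#'
#' @export
setClass("GCProfile",
         representation(perFragment = "data.frame",
                        genomeGC = "numeric",
                        ensembleMeans = "numeric"))

#' SyntheticGenomeSpec: parameters of the synthetic genome generator
#'
#' Describes an annotated synthetic genome: protein-coding genes on both
#' strands emitting i.i.d. codons from a (usually strongly biased) 64-codon
#' usage, neutral intergenic sequence at a given GC, and a dense block of
#' short GC-rich RNA genes that produces the tail cluster.
#'
#' @slot N genome length.
#' @slot codonUsage named numeric of length 64 summing to 1.
#' @slot backwardCodonUsage usage for backward-strand genes; defaults to
#'   \code{codonUsage} (the mirrored construction).
#' @slot nForwardGenes,nBackwardGenes gene counts.
#' @slot geneLengthRange range of gene lengths (multiples of 3).
#' @slot intergenicGC GC fraction of intergenic sequence.
#' @slot tailGenes number of RNA genes in the tail block.
#' @slot tailGeneLengthRange range of RNA gene lengths.
#' @slot tailGC GC fraction of RNA genes (>= 0.55 for a clean tail).
#' @slot tailSpacer spacer length between RNA genes.
#' @slot seed integer seed governing all draws.
#'
#' @export
setClass("SyntheticGenomeSpec",
         representation(N = "integer",
                        codonUsage = "numeric",
                        backwardCodonUsage = "numeric",
                        nForwardGenes = "integer",
                        nBackwardGenes = "integer",
                        geneLengthRange = "integer",
                        intergenicGC = "numeric",
                        tailGenes = "integer",
                        tailGeneLengthRange = "integer",
                        tailGC = "numeric",
                        tailSpacer = "integer",
                        seed = "integer"))

setValidity("SyntheticGenomeSpec", function(object) {
  msg <- character()
  for (nm in c("codonUsage", "backwardCodonUsage")) {
    u <- slot(object, nm)
    if (length(u) != 64L || !identical(names(u), TRIPLETS))
      msg <- c(msg, sprintf("%s must be named by the 64 triplets", nm))
    else if (abs(sum(u) - 1) > 1e-9 || any(u < 0))
      msg <- c(msg, sprintf("%s must be a probability vector summing to 1", nm))
  }
  if (any(object@geneLengthRange %% 3L != 0L))
    msg <- c(msg, "geneLengthRange must contain multiples of 3")
  if (object@tailGC < 0 || object@tailGC > 1 ||
      object@intergenicGC < 0 || object@intergenicGC > 1)
    msg <- c(msg, "GC fractions must lie in [0,1]")
  if (length(msg)) msg else TRUE
})
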