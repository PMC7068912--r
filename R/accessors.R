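#' @include AllClasses.R
NULL

#' Accessors for the core classes
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
genomeId <- function(x) {
  if (is(x, "GenomeRecord")) x@id
  else if (is(x, "FragmentSet") || is(x, "TripletFrequencyMatrix")) x@genomeId
  else stop("no genomeId for class ", class(x))
}

#' @rdname accessors
#' @export
genomeSequence <- function(x) x@sequence

#' @rdname accessors
#' @export
genomeLength <- function(x) length(x@sequence)

#' @rdname accessors
#' @export
genomeRegions <- function(x) x@regions

#' @rdname accessors
#' @export
isCircularRecord <- function(x) x@isCircular

#' @rdname accessors
#' @export
fragmentStarts <- function(x) IRanges::start(x@ranges)

#' @rdname accessors
#' @export
fragmentCenters <- function(x) IRanges::start(x@ranges) + (x@L - 1L) %/% 2L

#' @rdname accessors
#' @export
fragmentSequences <- function(x) x@sequences

#' @rdname accessors
#' @export
fragmentLength <- function(x) x@L

#' @rdname accessors
#' @export
fragmentStep <- function(x) x@R

#' @rdname accessors
#' @export
tripletFreqs <- function(x) x@freqs

#' @rdname accessors
#' @export
tripletCountM <- function(x) x@M

#' @rdname accessors
#' @export
excludedTriplet <- function(x) x@excludedTriplet

#' The 63-dimensional point matrix
#'
#' Drops the excluded-triplet column from the full 64-column frequency
#' matrix; row sums of the result equal 1 minus the excluded frequency.
#'
#' @param x a \linkS4class{TripletFrequencyMatrix}.
#' @return an n x 63 numeric matrix.
#' @export
points63 <- function(x) {
  stopifnot(is(x, "TripletFrequencyMatrix"))
  x@freqs[, setdiff(TRIPLETS, x@excludedTriplet), drop = FALSE]
}

#' @rdname accessors
#' @export
embeddingCoords <- function(x) x@coords

#' @rdname accessors
#' @export
explainedVariance <- function(x) x@explainedVariance

#' @rdname accessors
#' @export
phaseCentroids <- function(x) x@centroids

#' @rdname accessors
#' @export
circuitAreas <- function(x) c(F = x@areaF, B = x@areaB)

#' @rdname accessors
#' @export
symmetryType <- function(x) x@symmetry

#' @rdname accessors
#' @export
orientationType <- function(x) x@orientation

#' @rdname accessors
#' @export
phaseAbundances <- function(x) x@abundances

#' @rdname accessors
#' @export
codingSd <- function(x) x@codingSd

#' @rdname accessors
#' @export
phaseBias <- function(x) x@bias

#' @rdname accessors
#' @export
gcPerFragment <- function(x) x@perFragment

#' @rdname accessors
#' @export
genomeGC <- function(x) x@genomeGC

#' @rdname accessors
#' @export
ensembleMeans <- function(x) x@ensembleMeans

setMethod("length", "FragmentSet", function(x) length(x@ranges))

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord ", object@id, "\n",
      "  length: ", length(object@sequence), " nt",
      if (object@isCircular) " (circular source)" else "", "\n",
      "  regions: ", length(object@regions), "\n", sep = "")
})

setMethod("show", "FragmentSet", function(object) {
  cat("FragmentSet of", length(object@ranges), "fragments from",
      object@genomeId, sprintf("(L=%d, R=%d)\n", object@L, object@R))
})

setMethod("show", "TripletFrequencyMatrix", function(object) {
  cat("TripletFrequencyMatrix:", nrow(object@freqs), "fragments x 63",
      sprintf("(excluded triplet %s)\n", object@excludedTriplet))
})

setMethod("show", "PhaseGeometry", function(object) {
  cat("PhaseGeometry:", object@symmetry, "symmetry, orientation",
      object@orientation, "\n  signed areas:",
      sprintf("F=%.3g B=%.3g (plane %s)\n", object@areaF, object@areaB,
              object@plane),
      " coding abundance sd:", sprintf("%.2f\n", object@codingSd))
})

setMethod("show", "GCProfile", function(object) {
  cat("GCProfile:", nrow(object@perFragment), "fragments; genome GC",
      sprintf("%.3f\n", object@genomeGC))
})

setMethod("show", "SyntheticGenomeSpec", function(object) {
  cat("SyntheticGenomeSpec: N =", object@N, "\n",
      " genes:", object@nForwardGenes, "forward /", object@nBackwardGenes,
      "backward;", object@tailGenes, "RNA genes in tail block\n",
      " seed:", object@seed, "\n")
})
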