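#' @include AllClasses.R
#' @importFrom Biostrings oligonucleotideFrequency
#' @importFrom stats sd
NULL

#' Triplet frequency dictionary of one sequence
#'
#' Tiles the sequence with non-overlapping windows of length \code{q}
#' starting at offsets 0, t, 2t, ... and counts the words observed; counts
#' are divided by the number M of clean windows to give frequencies.
#' Windows containing a non-ACGT symbol are skipped (M is reduced
#' accordingly); an incomplete final window is dropped.  For the W(3,3)
#' dictionaries used throughout, a clean fragment of length 603 has M = 201.
#'
#' @param sequence character string or \code{DNAString}.
#' @param q word length (only 3 is supported).
#' @param t step (only t = q, non-overlapping tiling, is supported).
#' @return a \linkS4class{TripletDictionary}.
#' @export
tripletFrequencies <- function(sequence, q = 3L, t = 3L) {
  if (q != 3L || t != 3L)
    stop("only the non-overlapping triplet dictionary W(3,3) is supported")
  s <- if (is(sequence, "DNAString")) sequence else DNAString(toupper(as.character(sequence)))
  if (length(s) < q) stop("sequence shorter than the word length ", q)
  counts <- oligonucleotideFrequency(s, width = 3L, step = 3L)
  M <- as.integer(sum(counts))
  freqs <- if (M > 0L) counts / M else counts * 0
  freqs <- setNames(as.numeric(freqs), TRIPLETS)
  new("TripletDictionary", freqs = freqs, M = M)
}

## n x 64 frequency matrix (and M vector) for a whole FragmentSet at once.
.tripletFrequencyCounts <- function(fragments) {
  counts <- oligonucleotideFrequency(fragmentSequences(fragments),
                                     width = 3L, step = 3L)
  colnames(counts) <- TRIPLETS
  M <- as.integer(rowSums(counts))
  freqs <- counts / ifelse(M > 0L, M, 1L)
  list(freqs = freqs, M = M)
}

#' Select the excluded triplet
#'
#' Returns the triplet whose frequency has the smallest standard deviation
#' over the fragment ensemble: the least discriminating coordinate, whose
#' removal costs the least information.  The population standard deviation
#' (divisor n) is used; ties are broken lexicographically.
#'
#' @param freqs an n x 64 frequency matrix (n >= 2), a list of
#'   \linkS4class{TripletDictionary}, or a \linkS4class{FragmentSet}.
#' @return a single triplet string.
#' @export
selectExcludedTriplet <- function(freqs) {
  mat <- .asFreqMatrix(freqs)
  if (nrow(mat) < 2L)
    stop("at least 2 dictionaries are needed to measure variability")
  n <- nrow(mat)
  mu <- colMeans(mat)
  sdev <- sqrt(colMeans(mat^2) - mu^2)  # population SD
  TRIPLETS[which.min(sdev)]             # which.min takes the first = lexicographic tie-break
}

.asFreqMatrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(identical(colnames(x), TRIPLETS))
    x
  } else if (is(x, "FragmentSet")) {
    .tripletFrequencyCounts(x)$freqs
  } else if (is.list(x)) {
    do.call(rbind, lapply(x, function(d) d@freqs))
  } else stop("cannot interpret ", class(x)[1], " as a frequency matrix")
}

#' Build the 63-dimensional frequency matrix
#'
#' Converts a fragment ensemble into the n x 64 triplet frequency matrix and
#' records the excluded triplet (chosen by \code{\link{selectExcludedTriplet}}
#' unless given).  \code{\link{points63}} on the result yields the n x 63
#' point matrix whose row sums are 1 minus the excluded frequency.
#'
#' @param fragments a \linkS4class{FragmentSet}, or an n x 64 matrix.
#' @param excluded the triplet to drop; default picks the least-SD triplet.
#' @param genomeId id stored with the matrix (taken from the FragmentSet
#'   when available).
#' @return a \linkS4class{TripletFrequencyMatrix}.
#' @export
buildTripletMatrix <- function(fragments, excluded = NULL, genomeId = "") {
  if (is(fragments, "FragmentSet")) {
    fm <- .tripletFrequencyCounts(fragments)
    mat <- fm$freqs; M <- fm$M
    gid <- fragments@genomeId
  } else {
    mat <- .asFreqMatrix(fragments)
    M <- rep(NA_integer_, nrow(mat))
    gid <- genomeId
  }
  if (is.null(excluded)) excluded <- selectExcludedTriplet(mat)
  if (!(excluded %in% TRIPLETS))
    stop("'excluded' must be one of the 64 triplets")
  new("TripletFrequencyMatrix", freqs = mat, M = M,
      excludedTriplet = excluded, genomeId = gid)
}

#' Euclidean distance between triplet dictionaries
#'
#' The square root of the sum, over all 64 triplets, of squared frequency
#' differences.  Distances computed on the full 64-dimensional vectors are
#' identical to distances on the 63-dimensional points paired with the
#' reconstructed excluded coordinate.
#'
#' @param w1,w2 \linkS4class{TripletDictionary} objects or named length-64
#'   frequency vectors.
#' @return non-negative distance.
#' @export
tripletDistance <- function(w1, w2) {
  f1 <- if (is(w1, "TripletDictionary")) w1@freqs else w1[TRIPLETS]
  f2 <- if (is(w2, "TripletDictionary")) w2@freqs else w2[TRIPLETS]
  sqrt(sum((f1 - f2)^2))
}

#' Export the frequency matrix as TSV
#'
#' Writes the fragments x 63 point matrix with a leading comment line
#' naming the excluded triplet, so the matrix is self-describing.
#'
#' @param mat a \linkS4class{TripletFrequencyMatrix}.
#' @param path output path.
#' @export
exportTripletMatrix <- function(mat, path) {
  pts <- points63(mat)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# excluded_triplet=%s genome_id=%s",
                     excludedTriplet(mat), genomeId(mat)), con)
  df <- data.frame(fragment = seq_len(nrow(pts)) - 1L, pts,
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
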