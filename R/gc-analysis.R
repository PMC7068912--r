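#' @include AllClasses.R
#' @importFrom Biostrings letterFrequency
#' @importFrom stats cor
NULL

#' GC content of a sequence
#'
#' (#G + #C) / (#A + #C + #G + #T); ambiguous symbols are excluded from both
#' numerator and denominator.  Invariant under reverse complementation.
#'
#' @param sequence character, \code{DNAString} or \code{DNAStringSet}.
#' @return GC fraction in [0,1] (vector for a \code{DNAStringSet}).
#' @export
gcContent <- function(sequence) {
  s <- if (is(sequence, "DNAString") || is(sequence, "DNAStringSet")) sequence
       else DNAString(toupper(as.character(sequence)))
  counts <- letterFrequency(s, letters = c("A", "C", "G", "T"))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(counts)))
  denom <- rowSums(counts)
  if (any(denom == 0))
    stop("GC content undefined: no unambiguous A/C/G/T symbols")
  out <- (counts[, "G"] + counts[, "C"]) / denom
  if (length(out) == 1L) unname(out) else unname(out)
}

#' Per-fragment and ensemble GC statistics
#'
#' Computes the GC fraction of every fragment, the whole-genome GC, and the
#' ensemble means for the coding (all six phases), junk and tail fragment
#' ensembles.  When the genome has no tail fragments the tail mean is
#' \code{NA} (some genomes lack the tail cluster entirely).
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param fragments the \linkS4class{FragmentSet} cut from it.
#' @param labels phase labels parallel to the fragments.
#' @return a \linkS4class{GCProfile}.
#' @export
buildGCProfile <- function(genome, fragments, labels) {
  stopifnot(length(fragments) == length(labels))
  labels <- factor(labels, levels = PHASE_LEVELS)
  gc <- gcContent(fragmentSequences(fragments))
  per <- data.frame(index = seq_len(length(fragments)) - 1L,
                    center = fragmentCenters(fragments),
                    gc = gc,
                    phase = as.character(labels),
                    stringsAsFactors = FALSE)
  coding <- labels %in% CODING_PHASES
  means <- c(genome = gcContent(genomeSequence(genome)),
             coding = if (any(coding)) mean(gc[coding]) else NA_real_,
             junk = if (any(labels == "JUNK")) mean(gc[labels == "JUNK"]) else NA_real_,
             tail = if (any(labels == "TAIL")) mean(gc[labels == "TAIL"]) else NA_real_)
  new("GCProfile", perFragment = per, genomeGC = means[["genome"]],
      ensembleMeans = means)
}

#' Cross-genome GC correlations
#'
#' Correlation matrix (Pearson by default) of the four ensemble GC means
#' (genome, coding, junk, tail) across genomes.  Genomes lacking a tail are
#' excluded pairwise (\code{pairwise.complete.obs}).
#'
#' @param profiles list of \linkS4class{GCProfile} objects (>= 3 genomes).
#' @param method "pearson" (default) or "spearman".
#' @return symmetric 4 x 4 correlation matrix with unit diagonal.
#' @export
crossGenomeCorrelations <- function(profiles, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(profiles) < 3L)
    stop("at least 3 genomes are needed for cross-genome correlations")
  mat <- t(vapply(profiles, ensembleMeans, numeric(4)))
  colnames(mat) <- c("genome", "coding", "junk", "tail")
  cm <- suppressWarnings(cor(mat, use = "pairwise.complete.obs", method = method))
  diag(cm) <- 1
  cm
}
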