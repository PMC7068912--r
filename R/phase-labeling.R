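#' @include AllClasses.R
#' @importFrom GenomicRanges findOverlaps reduce
#' @importFrom S4Vectors queryHits subjectHits
NULL

## Per-position coding indicator -> prefix sums, for O(1) window counts.
.coverageCumsum <- function(ranges, N) {
  covered <- logical(N)
  if (length(ranges))
    for (i in seq_along(ranges)) {
      s <- max(1L, GenomicRanges::start(ranges)[i])
      e <- min(N, GenomicRanges::end(ranges)[i])
      if (s <= e) covered[s:e] <- TRUE
    }
  c(0L, cumsum(covered))
}

#' Count non-coding positions inside each fragment
#'
#' Number of fragment positions not covered by any annotated region of any
#' category; drives the junk rule ("half or longer non-coding").
#'
#' @param fragments a \linkS4class{FragmentSet}.
#' @param regions a \code{GRanges} of annotated regions (any category).
#' @param N genome length (needed to clip coverage; defaults to the largest
#'   coordinate touched by fragments or regions).
#' @return integer vector, one count per fragment.
#' @export
noncodingOverlap <- function(fragments, regions, N = NULL) {
  L <- fragmentLength(fragments)
  starts <- fragmentStarts(fragments)
  if (is.null(N)) N <- max(starts + L - 1L,
                           if (length(regions)) max(GenomicRanges::end(regions)) else 0L)
  cs <- .coverageCumsum(regions, N)
  coding <- cs[starts + L] - cs[starts]
  as.integer(L - coding)
}

#' Label fragments by phase, junk or tail
#'
#' Applies, in order of precedence:
#' \enumerate{
#'   \item \strong{JUNK}: at least half the fragment (\code{ceiling(L/2)}
#'     positions) lies outside every annotated region;
#'   \item \strong{TAIL}: at least half the fragment is covered by tRNA or
#'     rRNA regions (the dense GC-rich RNA gene blocks);
#'   \item a coding phase from the region containing the fragment center:
#'     the frame index is the count of nucleotides from the region's first
#'     nucleotide (forward strand) or last nucleotide (backward strand)
#'     through the center, inclusive, taken mod 3 -- giving F0/F1/F2 or
#'     B0/B1/B2.  Under this convention fragments whose triplet tiling is
#'     codon-aligned carry frame index 2, which is what makes the F2 and B2
#'     clusters coincide for usage obeying intra-strand Chargaff parity and
#'     yields the chloroplast centroid pairing F0--B1, F1--B0, F2--B2.
#' }
#' When the center falls in two overlapping regions the region with the
#' larger overlap with the fragment wins (ties: forward strand, then smaller
#' start).  When the center is in a short intergenic gap but the fragment is
#' mostly coding, the phase of the region with the largest overlap with the
#' fragment is assigned, so no fragment is left unlabeled.
#'
#' @param fragments a \linkS4class{FragmentSet}.
#' @param regions a \code{GRanges} of annotated regions with a
#'   \code{category} metadata column.
#' @param N genome length.
#' @return factor with levels F0, F1, F2, B0, B1, B2, JUNK, TAIL.
#' @export
labelFragments <- function(fragments, regions, N = NULL) {
  L <- fragmentLength(fragments)
  n <- length(fragments)
  starts <- fragmentStarts(fragments)
  centers <- fragmentCenters(fragments)
  if (is.null(N)) N <- max(starts + L - 1L,
                           if (length(regions)) max(GenomicRanges::end(regions)) else 0L)
  half <- as.integer(ceiling(L / 2))

  labels <- rep(NA_character_, n)
  nc <- noncodingOverlap(fragments, regions, N)
  labels[nc >= half] <- "JUNK"

  rna <- regions[as.character(mcols(regions)$category) %in% c("tRNA", "rRNA")]
  if (length(rna)) {
    csr <- .coverageCumsum(rna, N)
    rnaCov <- csr[starts + L] - csr[starts]
    labels[is.na(labels) & rnaCov >= half] <- "TAIL"
  }

  todo <- which(is.na(labels))
  if (length(todo) && length(regions)) {
    fragIR <- IRanges(start = starts[todo], width = L)
    regIR <- IRanges(start = GenomicRanges::start(regions),
                     end = GenomicRanges::end(regions))
    centerIR <- IRanges(start = centers[todo], width = 1L)
    chits <- IRanges::findOverlaps(centerIR, regIR)
    fhits <- IRanges::findOverlaps(fragIR, regIR)

    pick <- rep(NA_integer_, length(todo))
    pick <- .pickRegion(chits, pick, fragIR, regIR, regions)
    missing <- which(is.na(pick))
    if (length(missing)) {
      sub <- fhits[queryHits(fhits) %in% missing]
      pick <- .pickRegion(sub, pick, fragIR, regIR, regions)
    }
    ok <- !is.na(pick)
    ridx <- pick[ok]
    cen <- centers[todo][ok]
    fwd <- as.character(GenomicRanges::strand(regions))[ridx] == "+"
    idx <- integer(length(ridx))
    idx[fwd] <- (cen[fwd] - GenomicRanges::start(regions)[ridx[fwd]] + 1L) %% 3L
    idx[!fwd] <- (GenomicRanges::end(regions)[ridx[!fwd]] - cen[!fwd] + 1L) %% 3L
    labels[todo][ok] <- paste0(ifelse(fwd, "F", "B"), idx)
  }
  if (anyNA(labels)) labels[is.na(labels)] <- "JUNK"  # unreachable given the junk rule
  factor(labels, levels = PHASE_LEVELS)
}

## From a Hits object (fragments -> candidate regions), pick per fragment the
## region with the largest overlap with the fragment; ties prefer forward
## strand, then smaller start.  Fills only entries of 'pick' that are NA.
.pickRegion <- function(hits, pick, fragIR, regIR, regions) {
  if (!length(hits)) return(pick)
  q <- queryHits(hits); s <- subjectHits(hits)
  ov <- pmin(IRanges::end(fragIR)[q], IRanges::end(regIR)[s]) -
        pmax(IRanges::start(fragIR)[q], IRanges::start(regIR)[s]) + 1L
  fwd <- as.character(GenomicRanges::strand(regions))[s] == "+"
  ## order so the preferred candidate comes first within each fragment
  ord <- order(q, -ov, !fwd, IRanges::start(regIR)[s])
  q <- q[ord]; s <- s[ord]
  first <- !duplicated(q)
  sel <- is.na(pick[q[first]])
  pick[q[first][sel]] <- s[first][sel]
  pick
}

#' Expected number of border junk fragments
#'
#' Closed-form estimate of how many fragments straddling a coding/non-coding
#' border end up labeled junk: \code{L/(2R) * nRegions * 2}, the factor 2
#' counting both forward and backward oriented regions.  With L = 603,
#' R = 11 and 50 regions this is about 2.7e3 (an order-of-magnitude figure).
#'
#' @param L fragment length.
#' @param R step.
#' @param nRegions number of coding regions.
#' @return the estimate (numeric).
#' @export
estimateBorderJunk <- function(L, R, nRegions) {
  L / (2 * R) * nRegions * 2
}
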