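#' @include AllClasses.R
#' @importFrom IRanges IRanges Views
NULL

#' Cut a genome into overlapping fragments
#'
#' Extracts windows of length \code{L} starting at positions
#' \code{1, 1+R, 1+2R, ...}; the last window is the last one that fits
#' entirely, so the fragment count is \code{floor((N-L)/R) + 1}.  Tiling is
#' linear even for circular records: no window wraps past the end.
#'
#' \code{L} must be odd and divisible by 3 (default 603) so the center
#' position is an integer and every fragment tiles whole triplets;
#' \code{R} must not be divisible by 3 (default 11) so successive fragments
#' visit all three frame offsets.
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param L fragment length.
#' @param R step between fragment starts.
#' @return a \linkS4class{FragmentSet}.
#' @export
fragmentize <- function(genome, L = 603L, R = 11L) {
  L <- as.integer(L); R <- as.integer(R)
  if (L %% 2L == 0L || L %% 3L != 0L)
    stop("fragment length L must be odd and divisible by 3 (got ", L, ")")
  if (R %% 3L == 0L)
    stop("step R must not be divisible by 3 (got ", R, ")")
  N <- genomeLength(genome)
  if (L > N)
    stop("fragment length L = ", L, " exceeds genome length N = ", N)
  starts <- seq.int(1L, N - L + 1L, by = R)
  rng <- IRanges(start = starts, width = L)
  seqs <- DNAStringSet(Views(genomeSequence(genome), rng))
  new("FragmentSet", genomeId = genomeId(genome), L = L, R = R,
      ranges = rng, sequences = seqs)
}

#' Expected fragment count
#'
#' The closed-form fragment count \code{floor((N-L)/R) + 1} for linear
#' tiling; exposed for use in planning and checks.
#'
#' @param N genome length.
#' @param L fragment length.
#' @param R step.
#' @return integer count.
#' @export
fragmentCount <- function(N, L = 603L, R = 11L) {
  as.integer((N - L) %/% R + 1L)
}
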