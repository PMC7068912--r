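#' @include AllClasses.R
#' @importFrom Biostrings reverseComplement writeXStringSet
#' @importFrom stats rgamma runif
NULL

## reverse complement of each of the 64 triplets, as an index permutation
.rcIndex <- local({
  idx <- NULL
  function() {
    if (is.null(idx)) {
      rc <- as.character(reverseComplement(DNAStringSet(TRIPLETS)))
      idx <<- match(rc, TRIPLETS)
    }
    idx
  }
})

#' Reverse-complement permutation of a triplet frequency vector
#'
#' Returns the vector \code{g} with \code{g[w] = freqs[revcomp(w)]}; the
#' coordinate permutation induced on triplet space by reading the other
#' strand.  An involution and an isometry of the Euclidean metric.
#'
#' @param freqs named numeric of length 64 in lexicographic triplet order.
#' @return named numeric of length 64.
#' @export
revcompPermute <- function(freqs) {
  stopifnot(length(freqs) == 64L)
  setNames(as.numeric(freqs[.rcIndex()]), TRIPLETS)
}

#' Chargaff-symmetrize a codon usage
#'
#' Averages a usage with its reverse-complement permutation so that
#' \code{u[w] = u[revcomp(w)]} -- the intra-strand parity that real genomes
#' approximate and that makes the forward and backward phase centroids
#' coincide pairwise.
#'
#' @param usage named numeric of length 64 (normalized on return).
#' @return symmetrized usage.
#' @export
chargaffSymmetrize <- function(usage) {
  u <- (usage + revcompPermute(usage)) / 2
  setNames(as.numeric(u / sum(u)), TRIPLETS)
}

## usage proportional to a product of per-position base weights (ACGT order)
.productUsage <- function(w1, w2, w3) {
  b <- c("A", "C", "G", "T")
  u <- vapply(TRIPLETS, function(tr) {
    i <- match(strsplit(tr, "")[[1]], b)
    w1[i[1]] * w2[i[2]] * w3[i[3]]
  }, numeric(1))
  setNames(u / sum(u), TRIPLETS)
}

#' Default (chloroplast-like) codon usage
#'
#' A strongly non-uniform usage built from per-codon-position base
#' compositions typical of AT-rich plastid coding sequence (coding GC about
#' 0.40), then Chargaff-symmetrized so both strands share triplet
#' statistics; under it the expected phase centroids pair exactly as
#' F0--B1, F1--B0, F2--B2 and the circuit directions mirror.
#'
#' @return named numeric of length 64 summing to 1.
#' @export
defaultCodonUsage <- function() {
  u <- .productUsage(c(0.30, 0.18, 0.34, 0.18),
                     c(0.32, 0.22, 0.16, 0.30),
                     c(0.34, 0.14, 0.16, 0.36))
  chargaffSymmetrize(u)
}

#' Per-strand codon usages for the rotational (bacteria-like) control
#'
#' When the two strands share triplet statistics -- backward genes being
#' reverse-complemented draws from the forward usage, or more generally any
#' usage pair related by reverse complementation -- the backward centroids
#' are the reverse-complement isometry image of forward-type frame readings
#' taken in reversed frame order, so the two circuits are exactly
#' counter-directed in expectation: the mirrored construction cannot
#' produce same-direction circuits.  A bacteria-like control therefore
#' needs genuinely independent per-strand usages.  This function returns a
#' fixed pair of strongly non-uniform usages (a frozen seeded Dirichlet
#' draw) chosen with the analytic expected-centroid oracle
#' (\code{\link{expectedPhaseDistribution}}) so that the expected forward
#' and backward circuits run in the same direction with a margin well above
#' centroid sampling noise.
#'
#' @return list with elements \code{forward} and \code{backward}, each a
#'   named numeric of length 64 summing to 1.
#' @export
controlCodonUsages <- function() {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(436L)
  fwd <- rgamma(64L, shape = 1)
  bwd <- rgamma(64L, shape = 1)
  list(forward = setNames(fwd / sum(fwd), TRIPLETS),
       backward = setNames(bwd / sum(bwd), TRIPLETS))
}

#' Synthetic spec for the rotational control
#'
#' The default study conditions with the per-strand control usages of
#' \code{\link{controlCodonUsages}} substituted; everything else (genome
#' size, gene layout, tail block) matches \code{\link{syntheticSpec}}.
#'
#' @param seed integer seed.
#' @param ... further arguments passed to \code{\link{syntheticSpec}}.
#' @return a \linkS4class{SyntheticGenomeSpec}.
#' @export
controlSpec <- function(seed = 1L, ...) {
  u <- controlCodonUsages()
  syntheticSpec(codonUsage = u$forward, backwardCodonUsage = u$backward,
                seed = seed, ...)
}

#' Specify a synthetic genome
#'
#' Defaults describe the standard study conditions: a 120 kb genome with 25
#' forward and 25 backward protein-coding genes of 900--2400 nt emitting
#' i.i.d. codons from a strongly non-uniform usage, AT-rich intergenic
#' sequence, and a dense block of 30 short RNA genes at GC 0.60 that
#' produces the tail cluster.
#'
#' @param N genome length.
#' @param codonUsage forward-strand codon usage.
#' @param backwardCodonUsage usage for backward-strand genes; the default
#'   (same as forward) gives the mirrored construction.  Use
#'   \code{\link{controlBackwardUsage}} for the rotational control.
#' @param nForwardGenes,nBackwardGenes gene counts.
#' @param geneLengthRange min/max gene length (multiples of 3).
#' @param intergenicGC GC of intergenic sequence.
#' @param tailGenes number of RNA genes in the tail block.
#' @param tailGeneLengthRange min/max RNA gene length.
#' @param tailGC GC of the RNA block (genes and spacers).
#' @param tailSpacer spacer length between RNA genes.
#' @param seed integer seed; same seed, same genome.
#' @return a \linkS4class{SyntheticGenomeSpec}.
#' @export
syntheticSpec <- function(N = 120000L,
                          codonUsage = defaultCodonUsage(),
                          backwardCodonUsage = codonUsage,
                          nForwardGenes = 25L, nBackwardGenes = 25L,
                          geneLengthRange = c(900L, 2400L),
                          intergenicGC = 0.35,
                          tailGenes = 30L,
                          tailGeneLengthRange = c(72L, 150L),
                          tailGC = 0.60,
                          tailSpacer = 21L,
                          seed = 1L) {
  new("SyntheticGenomeSpec",
      N = as.integer(N), codonUsage = codonUsage,
      backwardCodonUsage = backwardCodonUsage,
      nForwardGenes = as.integer(nForwardGenes),
      nBackwardGenes = as.integer(nBackwardGenes),
      geneLengthRange = as.integer(geneLengthRange),
      intergenicGC = intergenicGC,
      tailGenes = as.integer(tailGenes),
      tailGeneLengthRange = as.integer(tailGeneLengthRange),
      tailGC = tailGC, tailSpacer = as.integer(tailSpacer),
      seed = as.integer(seed))
}

.sampleGC <- function(n, gc) {
  if (n == 0L) return(character(0))
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate an annotated synthetic genome with ground truth
#'
#' Forward genes are i.i.d. codon strings from the forward usage; backward
#' genes are reverse-complemented codon strings from the backward usage,
#' placed on the forward strand and annotated on the backward strand;
#' intergenic stretches are i.i.d. nucleotides at the intergenic GC; the
#' tail block is a contiguous run of short tRNA/rRNA-annotated genes (GC-
#' rich, alternating strands) separated by short GC-rich spacers, inserted
#' between the two halves of the gene list.  Same seed, identical output.
#'
#' @param spec a \linkS4class{SyntheticGenomeSpec}.
#' @param id record id.
#' @return list with elements \code{record} (a
#'   \linkS4class{GenomeRecord}) and \code{truth}, a data.frame with one
#'   row per position: \code{position}, \code{stratum} (forward_gene,
#'   backward_gene, rna_gene, intergenic), \code{segment} (id of the
#'   emitted feature or stretch) and \code{codonOffset} (0/1/2 within the
#'   emitting codon, NA outside genes).
#' @export
generateGenome <- function(spec, id = sprintf("synthetic_seed%d", spec@seed)) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec@seed)

  resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
  glen <- function(n, range) {
    if (n == 0L) return(integer(0))
    resample(seq.int(range[1], range[2], by = 3L), n)
  }
  nF <- spec@nForwardGenes; nB <- spec@nBackwardGenes
  geneLens <- glen(nF + nB, spec@geneLengthRange)
  geneStrand <- sample(rep(c("+", "-"), c(nF, nB)))
  rnaLens <- if (spec@tailGenes > 0L)
    resample(seq.int(spec@tailGeneLengthRange[1], spec@tailGeneLengthRange[2]),
             spec@tailGenes) else integer(0)

  ## features in genome order; tail block sits between the two gene halves;
  ## 'gap' marks features after which intergenic sequence may be inserted
  ## (never inside the dense RNA block)
  feats <- list()
  half <- (nF + nB) %/% 2L
  addGene <- function(i) list(kind = if (geneStrand[i] == "+") "forward_gene"
                              else "backward_gene",
                              len = geneLens[i], strand = geneStrand[i],
                              gap = TRUE)
  for (i in seq_len(half)) feats[[length(feats) + 1L]] <- addGene(i)
  for (j in seq_len(spec@tailGenes)) {
    feats[[length(feats) + 1L]] <-
      list(kind = "rna_gene", len = rnaLens[j],
           strand = if (j %% 2L == 1L) "+" else "-",
           category = if (j %% 5L == 0L) "rRNA" else "tRNA",
           gap = j == spec@tailGenes)
    if (j < spec@tailGenes)
      feats[[length(feats) + 1L]] <- list(kind = "rna_spacer",
                                          len = spec@tailSpacer, strand = "*",
                                          gap = FALSE)
  }
  if (half < nF + nB)
    for (i in seq.int(half + 1L, nF + nB))
      feats[[length(feats) + 1L]] <- addGene(i)

  featLen <- sum(vapply(feats, `[[`, numeric(1), "len"))
  free <- spec@N - featLen
  if (free < 0L)
    stop("infeasible packing: features need ", featLen,
         " nt but N = ", spec@N)
  gapAfter <- which(vapply(feats, `[[`, logical(1), "gap"))
  nGaps <- length(gapAfter) + 1L
  ## exponential-like gap-size variability: some gaps are short intergenic
  ## spacers, others junk-sized stretches
  gapW <- rgamma(nGaps, shape = 1)
  gapLens <- as.integer(table(factor(
    sample.int(nGaps, free, replace = TRUE, prob = gapW / sum(gapW)),
    levels = seq_len(nGaps))))

  pieces <- character(0)
  truthOffset <- integer(0)
  regions <- list()
  pos <- 1L
  strata <- character(0); strataLen <- integer(0)
  emit <- function(seqstr, stratum, offsets) {
    n <- nchar(seqstr)
    pieces[[length(pieces) + 1L]] <<- seqstr
    strata[[length(strata) + 1L]] <<- stratum
    strataLen[[length(strataLen) + 1L]] <<- n
    truthOffset <<- c(truthOffset, offsets)
    pos <<- pos + n
  }
  gi <- 0L
  for (fi in seq_along(feats)) {
    f <- feats[[fi]]
    start <- pos
    if (f$kind == "forward_gene") {
      codons <- sample(TRIPLETS, f$len %/% 3L, replace = TRUE,
                       prob = spec@codonUsage)
      emit(paste(codons, collapse = ""), "forward_gene",
           rep(0:2, f$len %/% 3L))
      regions[[length(regions) + 1L]] <-
        data.frame(start = start, end = pos - 1L, strand = "+",
                   category = "protein_coding")
    } else if (f$kind == "backward_gene") {
      codons <- sample(TRIPLETS, f$len %/% 3L, replace = TRUE,
                       prob = spec@backwardCodonUsage)
      s <- as.character(reverseComplement(DNAString(paste(codons, collapse = ""))))
      emit(s, "backward_gene", rep(2:0, f$len %/% 3L))
      regions[[length(regions) + 1L]] <-
        data.frame(start = start, end = pos - 1L, strand = "-",
                   category = "protein_coding")
    } else if (f$kind == "rna_gene") {
      emit(.sampleGC(f$len, spec@tailGC), "rna_gene",
           rep(NA_integer_, f$len))
      regions[[length(regions) + 1L]] <-
        data.frame(start = start, end = pos - 1L, strand = f$strand,
                   category = f$category)
    } else {  # rna_spacer: GC-rich like its block, not annotated
      emit(.sampleGC(f$len, spec@tailGC), "intergenic",
           rep(NA_integer_, f$len))
    }
    if (f$gap) {
      gi <- gi + 1L
      if (gapLens[gi] > 0L)
        emit(.sampleGC(gapLens[gi], spec@intergenicGC), "intergenic",
             rep(NA_integer_, gapLens[gi]))
    }
  }
  if (gapLens[nGaps] > 0L)
    emit(.sampleGC(gapLens[nGaps], spec@intergenicGC), "intergenic",
         rep(NA_integer_, gapLens[nGaps]))

  sequence <- paste(pieces, collapse = "")
  stopifnot(nchar(sequence) == spec@N)
  truth <- data.frame(position = seq_len(spec@N),
                      stratum = rep(strata, strataLen),
                      segment = rep(seq_along(strata), strataLen),
                      codonOffset = truthOffset,
                      stringsAsFactors = FALSE)
  regdf <- do.call(rbind, regions)
  record <- GenomeRecord(id, sequence, regdf, isCircular = FALSE)
  list(record = record, truth = truth)
}

#' Ground-truth labels for fragments of a synthetic genome
#'
#' The label the generator intended for each fragment, derived from the
#' per-position ground truth: the stratum of the fragment center decides
#' JUNK (intergenic), TAIL (rna_gene) or a coding phase; for gene centers
#' the frame index is \code{(codonOffset + 1) mod 3}, matching the
#' inclusive-distance convention of \code{\link{labelFragments}}.  The
#' \code{interior} attribute flags fragments lying entirely within a single
#' stratum run (non-border fragments).
#'
#' @param truth ground-truth data.frame from \code{\link{generateGenome}}.
#' @param fragments the \linkS4class{FragmentSet}.
#' @return factor of labels with attribute \code{interior} (logical).
#' @export
groundTruthLabels <- function(truth, fragments) {
  centers <- fragmentCenters(fragments)
  starts <- fragmentStarts(fragments)
  L <- fragmentLength(fragments)
  st <- truth$stratum[centers]
  off <- truth$codonOffset[centers]
  lab <- character(length(centers))
  lab[st == "intergenic"] <- "JUNK"
  lab[st == "rna_gene"] <- "TAIL"
  fwd <- st == "forward_gene"
  bwd <- st == "backward_gene"
  lab[fwd] <- paste0("F", (off[fwd] + 1L) %% 3L)
  lab[bwd] <- paste0("B", (off[bwd] + 1L) %% 3L)
  ## interior = the whole window sits inside one emitted segment (one gene,
  ## one RNA gene, or one contiguous non-genic stretch)
  runId <- if (!is.null(truth$segment)) truth$segment
           else cumsum(c(1L, diff(as.integer(factor(truth$stratum))) != 0L))
  interior <- runId[starts] == runId[starts + L - 1L]
  out <- factor(lab, levels = PHASE_LEVELS)
  attr(out, "interior") <- interior
  out
}

#' Expected triplet distribution of a phase under i.i.d. codons
#'
#' Exact expected W(3,3) distribution of fragments in a given phase over an
#' infinite i.i.d. codon stream.  Forward phases read the stream at frame
#' offset \code{(j+1) mod 3} from the codon boundary (so F2 is the
#' codon-aligned reading and equals the usage itself); backward phases read
#' the reverse-complemented stream, which reduces to frame
#' \code{(2-k) mod 3} of the reverse-complement-permuted usage.  Off-frame
#' readings are marginalizations over adjacent codon pairs, computed by
#' enumeration of all 64 x 64 pairs.
#'
#' @param codonUsage named numeric of length 64.
#' @param phase one of "F0","F1","F2","B0","B1","B2".
#' @param backwardCodonUsage usage of backward-strand genes (defaults to
#'   \code{codonUsage}).
#' @return named numeric of length 64: the expected triplet distribution.
#' @export
expectedPhaseDistribution <- function(codonUsage, phase,
                                      backwardCodonUsage = codonUsage) {
  stopifnot(phase %in% CODING_PHASES)
  j <- as.integer(substr(phase, 2, 2))
  if (startsWith(phase, "F")) {
    .frameRead(codonUsage, (j + 1L) %% 3L)
  } else {
    q <- revcompPermute(backwardCodonUsage)
    .frameRead(q, (2L - j) %% 3L)
  }
}

## expected distribution of length-3 windows read at 'shift' nucleotides
## past the codon boundary of an iid codon stream with usage u
.frameReadTables <- local({
  tabs <- NULL
  function() {
    if (is.null(tabs)) {
      pairs <- expand.grid(a = TRIPLETS, b = TRIPLETS,
                           stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE)
      w1 <- paste0(substr(pairs$a, 2, 3), substr(pairs$b, 1, 1))
      w2 <- paste0(substr(pairs$a, 3, 3), substr(pairs$b, 1, 2))
      tabs <<- list(a = match(pairs$a, TRIPLETS), b = match(pairs$b, TRIPLETS),
                    w1 = factor(w1, levels = TRIPLETS),
                    w2 = factor(w2, levels = TRIPLETS))
    }
    tabs
  }
})

.frameRead <- function(u, shift) {
  u <- setNames(as.numeric(u[TRIPLETS]), TRIPLETS)
  if (shift == 0L) return(u)
  tb <- .frameReadTables()
  pr <- u[tb$a] * u[tb$b]
  w <- if (shift == 1L) tb$w1 else tb$w2
  out <- vapply(split(pr, w), sum, numeric(1))
  setNames(as.numeric(out), TRIPLETS)
}

#' Write a synthetic genome to disk
#'
#' Emits FASTA, GFF3 and the ground-truth TSV, consumable by the main
#' pipeline unchanged.
#'
#' @param generated the list returned by \code{\link{generateGenome}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the three paths written.
#' @export
exportSynthetic <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- generated$record
  fa <- file.path(dir, paste0(genomeId(rec), ".fasta"))
  seqs <- DNAStringSet(genomeSequence(rec))
  names(seqs) <- genomeId(rec)
  writeXStringSet(seqs, fa)
  gff <- file.path(dir, paste0(genomeId(rec), ".gff3"))
  exportRegionsGFF3(rec, gff)
  tsv <- file.path(dir, paste0(genomeId(rec), "_truth.tsv"))
  writeTable(generated$truth, tsv)
  invisible(c(fasta = fa, gff3 = gff, truth = tsv))
}
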