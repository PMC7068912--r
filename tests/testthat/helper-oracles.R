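## Independent brute-force oracles and small fixtures, built in code.

ALL_TRIPLETS <- names(defaultCodonUsage())

randomSequence <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## brute-force fragment start enumeration (independent of fragmentize)
oracleFragmentStarts <- function(N, L, R) {
  starts <- integer(0); s <- 1L
  while (s + L - 1L <= N) { starts <- c(starts, s); s <- s + R }
  starts
}

## naive triplet tiling by substring loop
oracleTripletFreqs <- function(seqchr) {
  n <- nchar(seqchr)
  counts <- setNames(rep(0L, 64), ALL_TRIPLETS)
  i <- 1L
  while (i + 2L <= n) {
    w <- substr(seqchr, i, i + 2L)
    if (w %in% ALL_TRIPLETS) counts[w] <- counts[w] + 1L
    i <- i + 3L
  }
  M <- sum(counts)
  list(freqs = if (M > 0) counts / M else counts * 0, M = M)
}

## position-by-position coverage count (independent of IRanges)
oracleNoncoding <- function(start, L, regdf) {
  pos <- start:(start + L - 1L)
  covered <- vapply(pos, function(p)
    any(p >= regdf$start & p <= regdf$end), logical(1))
  sum(!covered)
}

## exhaustive, loop-based reimplementation of the labeling rules
oracleLabel <- function(start, L, regdf) {
  center <- start + (L - 1L) %/% 2L
  half <- ceiling(L / 2)
  nc <- if (nrow(regdf) == 0L) L else oracleNoncoding(start, L, regdf)
  if (nc >= half) return("JUNK")
  rna <- regdf[regdf$category %in% c("tRNA", "rRNA"), , drop = FALSE]
  if (nrow(rna) > 0L) {
    pos <- start:(start + L - 1L)
    rcov <- sum(vapply(pos, function(p)
      any(p >= rna$start & p <= rna$end), logical(1)))
    if (rcov >= half) return("TAIL")
  }
  fragEnd <- start + L - 1L
  ov <- pmin(regdf$end, fragEnd) - pmax(regdf$start, start) + 1L
  cand <- which(regdf$start <= center & regdf$end >= center)
  if (length(cand) == 0L) cand <- which(ov > 0L)
  ## larger fragment overlap wins; ties: forward strand, then smaller start
  best <- cand[order(-ov[cand], regdf$strand[cand] != "+", regdf$start[cand])][1]
  if (regdf$strand[best] == "+") {
    paste0("F", (center - regdf$start[best] + 1L) %% 3L)
  } else {
    paste0("B", (regdf$end[best] - center + 1L) %% 3L)
  }
}

## random toy genome with annotation on both strands (for oracle tests)
randomToyGenome <- function(seed, N = 1500L) {
  set.seed(seed)
  nreg <- sample(3:7, 1)
  starts <- sort(sample.int(N - 120L, nreg))
  regdf <- data.frame(
    start = starts,
    end = pmin(N, starts + sample(60:400, nreg, replace = TRUE)),
    strand = sample(c("+", "-"), nreg, replace = TRUE),
    category = sample(c("protein_coding", "protein_coding", "tRNA", "rRNA"),
                      nreg, replace = TRUE),
    stringsAsFactors = FALSE)
  rec <- GenomeRecord(sprintf("toy%d", seed), randomSequence(N),
                      transform(regdf,
                                strand = ifelse(strand == "+", "forward", "backward")))
  list(record = rec, regdf = regdf)
}

## small, fast synthetic spec used across tests (not the default conditions)
smallSpec <- function(seed = 1L, ...) {
  syntheticSpec(N = 30000L, nForwardGenes = 8L, nBackwardGenes = 8L,
                geneLengthRange = c(900L, 1500L), tailGenes = 10L,
                seed = seed, ...)
}

## fixed phase-cluster embedding built from given 2D centroid positions
## (third coordinate keeps the data full-rank); returns embedding + labels
embeddingFromCentroids <- function(centroids2d, nPer = 30L, seed = 99L) {
  set.seed(seed)
  labs <- rownames(centroids2d)
  coords <- do.call(rbind, lapply(labs, function(ph) {
    cbind(matrix(rep(centroids2d[ph, ], each = nPer), ncol = 2) +
            matrix(rnorm(2 * nPer, sd = 1e-3), ncol = 2),
          rnorm(nPer, sd = 1e-3))
  }))
  colnames(coords) <- paste0("PC", 1:3)
  list(embedding = new("PhaseEmbedding", coords = coords,
                       explainedVariance = c(0.5, 0.3, 0.2),
                       signFlips = c(1, 1, 1)),
       labels = factor(rep(labs, each = nPer), levels = tripletPhase:::PHASE_LEVELS))
}

## regular hexagon-ish mirror configuration: B triangle = F triangle
## reflected across the x axis
mirrorCentroids <- function() {
  ang <- c(90, 210, 330) * pi / 180
  Fc <- cbind(cos(ang), sin(ang))
  Bc <- cbind(Fc[, 1], -Fc[, 2]) * 0.8 + 0.1
  out <- rbind(Fc, Bc)
  rownames(out) <- c("F0", "F1", "F2", "B0", "B1", "B2")
  out
}

rotatedCentroids <- function(theta = pi / 3) {
  ang <- c(90, 210, 330) * pi / 180
  Fc <- cbind(cos(ang), sin(ang))
  Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  Bc <- Fc %*% t(Rm) * 0.8 + 0.1
  out <- rbind(Fc, Bc)
  rownames(out) <- c("F0", "F1", "F2", "B0", "B1", "B2")
  out
}
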