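test_that("generation is deterministic in the seed and honors the layout", {
  g1 <- generateGenome(smallSpec(seed = 3L))
  g2 <- generateGenome(smallSpec(seed = 3L))
  expect_identical(as.character(genomeSequence(g1$record)),
                   as.character(genomeSequence(g2$record)))
  expect_identical(g1$truth, g2$truth)
  g3 <- generateGenome(smallSpec(seed = 4L))
  expect_false(identical(as.character(genomeSequence(g1$record)),
                         as.character(genomeSequence(g3$record))))
  expect_identical(genomeLength(g1$record), 30000L)
  ## annotation and ground truth agree position by position
  rg <- as.data.frame(genomeRegions(g1$record))
  genePos <- unlist(Map(seq.int, rg$start[rg$category == "protein_coding"],
                        rg$end[rg$category == "protein_coding"]))
  expect_true(all(g1$truth$stratum[genePos] %in% c("forward_gene", "backward_gene")))
  rnaPos <- unlist(Map(seq.int, rg$start[rg$category %in% c("tRNA", "rRNA")],
                       rg$end[rg$category %in% c("tRNA", "rRNA")]))
  expect_true(all(g1$truth$stratum[rnaPos] == "rna_gene"))
})

test_that("a gene-free spec yields pure junk through the whole pipeline", {
  spec <- syntheticSpec(N = 20000L, nForwardGenes = 0L, nBackwardGenes = 0L,
                        tailGenes = 0L, seed = 9L)
  gen <- generateGenome(spec)
  expect_true(all(gen$truth$stratum == "intergenic"))
  fr <- fragmentize(gen$record, 603L, 11L)
  labs <- labelFragments(fr, genomeRegions(gen$record), genomeLength(gen$record))
  expect_true(all(labs == "JUNK"))
})

test_that("fragments inside a single forward gene follow the construction exactly", {
  spec <- syntheticSpec(N = 12000L, nForwardGenes = 1L, nBackwardGenes = 0L,
                        geneLengthRange = c(9000L, 9000L), tailGenes = 0L,
                        seed = 10L)
  gen <- generateGenome(spec)
  fr <- fragmentize(gen$record, 603L, 11L)
  labs <- labelFragments(fr, genomeRegions(gen$record), genomeLength(gen$record))
  rg <- as.data.frame(genomeRegions(gen$record))
  inGene <- fragmentStarts(fr) >= rg$start & fragmentStarts(fr) + 602L <= rg$end
  centers <- fragmentCenters(fr)[inGene]
  expect_identical(as.character(labs[inGene]),
                   paste0("F", (centers - rg$start + 1L) %% 3L))
})

test_that("ground-truth labels match pipeline labels away from borders", {
  gen <- generateGenome(smallSpec(seed = 6L))
  fr <- fragmentize(gen$record, 603L, 11L)
  labs <- labelFragments(fr, genomeRegions(gen$record), genomeLength(gen$record))
  gt <- groundTruthLabels(gen$truth, fr)
  interior <- attr(gt, "interior")
  agree <- mean(as.character(labs[interior]) == as.character(gt[interior]))
  expect_gte(agree, 0.99)
})

test_that("the analytic phase distributions obey their exact identities", {
  set.seed(47)
  u <- rgamma(64, 1); u <- setNames(u / sum(u), ALL_TRIPLETS)
  ub <- rgamma(64, 1); ub <- setNames(ub / sum(ub), ALL_TRIPLETS)
  ## the codon-aligned forward phase is the usage itself
  expect_equal(expectedPhaseDistribution(u, "F2"), u)
  ## uniform usage gives the uniform distribution in every phase
  unif <- setNames(rep(1 / 64, 64), ALL_TRIPLETS)
  for (ph in c("F0", "F1", "F2", "B0", "B1", "B2"))
    expect_equal(expectedPhaseDistribution(unif, ph), unif)
  ## every distribution is a probability vector
  for (ph in c("F0", "F1", "B0", "B2"))
    expect_equal(sum(expectedPhaseDistribution(u, ph, ub)), 1)
  ## each backward phase is the reverse-complement permutation of exactly
  ## one forward-type reading of the backward usage -- the same frame index
  for (k in 0:2) {
    bk <- expectedPhaseDistribution(u, paste0("B", k), backwardCodonUsage = ub)
    hits <- vapply(0:2, function(j) {
      fj <- revcompPermute(expectedPhaseDistribution(ub, paste0("F", j)))
      max(abs(bk - fj)) < 1e-12
    }, logical(1))
    expect_identical(which(hits) - 1L, k)
  }
})

test_that("empirical phase centroids converge to the analytic distributions", {
  ## overlapping fragments re-read the same codons, so the effective sample
  ## per phase is the distinct codon content of the genes, not the fragment
  ## count; pool many generated genomes (with a sparser fragment stride,
  ## which costs nothing in information) to estimate each centroid
  pooled <- lapply(2:25, function(s) {
    gen <- generateGenome(syntheticSpec(seed = s))
    fr <- fragmentize(gen$record, 603L, 113L)
    gt <- groundTruthLabels(gen$truth, fr)
    counts <- Biostrings::oligonucleotideFrequency(fragmentSequences(fr),
                                                   width = 3, step = 3)
    list(freqs = counts / rowSums(counts), gt = gt,
         interior = attr(gt, "interior"))
  })
  u <- defaultCodonUsage()
  for (ph in c("F0", "F1", "F2", "B0", "B1", "B2")) {
    emp <- colMeans(do.call(rbind, lapply(pooled, function(p)
      p$freqs[p$interior & p$gt == ph, , drop = FALSE])))
    ana <- expectedPhaseDistribution(u, ph)
    expect_lt(sum(abs(emp - ana)), 0.02)
  }
})

test_that("reverse-complementing the genome swaps forward and backward phases", {
  ## N chosen so the reversed tiling lands on the same windows
  L <- 603L; R <- 11L
  spec <- syntheticSpec(N = L + R * 2600L, nForwardGenes = 8L,
                        nBackwardGenes = 8L, geneLengthRange = c(900L, 1500L),
                        tailGenes = 10L, seed = 12L)
  gen <- generateGenome(spec)
  N <- genomeLength(gen$record)
  fr <- fragmentize(gen$record, L, R)
  labs <- labelFragments(fr, genomeRegions(gen$record), N)

  rcseq <- as.character(Biostrings::reverseComplement(genomeSequence(gen$record)))
  rg <- as.data.frame(genomeRegions(gen$record))
  rcdf <- data.frame(start = N + 1L - rg$end, end = N + 1L - rg$start,
                     strand = ifelse(as.character(rg$strand) == "+",
                                     "backward", "forward"),
                     category = rg$category, stringsAsFactors = FALSE)
  rcrec <- GenomeRecord("rc", rcseq, rcdf)
  labsRC <- labelFragments(fragmentize(rcrec, L, R), genomeRegions(rcrec), N)
  swap <- c(F0 = "B0", F1 = "B1", F2 = "B2", B0 = "F0", B1 = "F1", B2 = "F2",
            JUNK = "JUNK", TAIL = "TAIL")
  expect_identical(as.character(rev(labsRC)),
                   unname(swap[as.character(labs)]))
})

test_that("tail fragments are GC-rich under the default conditions", {
  gen <- generateGenome(syntheticSpec(seed = 3L))
  fr <- fragmentize(gen$record, 603L, 11L)
  labs <- labelFragments(fr, genomeRegions(gen$record), genomeLength(gen$record))
  gc <- gcContent(fragmentSequences(fr))
  tailGC <- gc[labs == "TAIL"]
  expect_gt(length(tailGC), 0L)
  expect_gte(mean(tailGC >= 0.5), 0.99)
})

test_that("synthetic output files feed back through the readers unchanged", {
  dir <- withr::local_tempdir()
  gen <- generateGenome(smallSpec(seed = 8L))
  paths <- exportSynthetic(gen, dir)
  rec2 <- readGenome(paths[["fasta"]], paths[["gff3"]])
  expect_identical(as.character(genomeSequence(rec2)),
                   as.character(genomeSequence(gen$record)))
  a <- as.data.frame(genomeRegions(gen$record))
  b <- as.data.frame(genomeRegions(rec2))
  expect_identical(nrow(a), nrow(b))
  expect_identical(sort(a$start), sort(b$start))
  truth2 <- read.delim(paths[["truth"]])
  expect_identical(nrow(truth2), genomeLength(gen$record))
})
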