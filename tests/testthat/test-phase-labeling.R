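test_that("noncoding overlap counts match a position-by-position oracle", {
  N <- 400L
  regdf <- data.frame(start = c(50L, 180L, 300L), end = c(120L, 260L, 340L),
                      strand = c("+", "-", "+"),
                      category = c("protein_coding", "protein_coding", "tRNA"),
                      stringsAsFactors = FALSE)
  rec <- GenomeRecord("nc", randomSequence(N), regdf)
  fr <- fragmentize(rec, L = 21L, R = 4L)
  got <- noncodingOverlap(fr, genomeRegions(rec), N)
  want <- vapply(fragmentStarts(fr), oracleNoncoding, integer(1),
                 L = 21L, regdf = regdf)
  expect_identical(got, want)
  ## fully inside a region -> 0; fully outside every region -> L
  inside <- which(fragmentStarts(fr) >= 50L & fragmentStarts(fr) + 20L <= 120L)
  expect_true(all(got[inside] == 0L))
  outside <- which(fragmentStarts(fr) + 20L < 50L)
  expect_true(all(got[outside] == 21L))
})

test_that("frame indices follow the inclusive-distance convention on both strands", {
  N <- 200L
  ## one forward gene covering everything: codon-aligned windows -> F2
  fwd <- GenomeRecord("f", randomSequence(N),
                      data.frame(start = 1L, end = N, strand = "forward",
                                 category = "protein_coding"))
  fr <- fragmentize(fwd, L = 9L, R = 1L)
  labs <- labelFragments(fr, genomeRegions(fwd), N)
  starts <- fragmentStarts(fr)
  centers <- fragmentCenters(fr)
  expect_identical(as.character(labs),
                   paste0("F", (centers - 1L + 1L) %% 3L))
  ## a fragment whose tiling aligns with codon boundaries carries index 2
  expect_identical(as.character(labs[starts %% 3L == 1L]),
                   rep("F2", sum(starts %% 3L == 1L)))

  ## one backward gene: distance measured from the region end
  bwd <- GenomeRecord("b", randomSequence(N),
                      data.frame(start = 1L, end = N, strand = "backward",
                                 category = "protein_coding"))
  labsB <- labelFragments(fragmentize(bwd, L = 9L, R = 1L),
                          genomeRegions(bwd), N)
  expect_identical(as.character(labsB),
                   paste0("B", (N - centers + 1L) %% 3L))
})

test_that("labels agree with the exhaustive oracle on random toy genomes", {
  for (seed in c(3L, 21L, 77L, 123L)) {
    toy <- randomToyGenome(seed, N = sample(1200:2000, 1))
    fr <- fragmentize(toy$record, L = 21L, R = 4L)
    got <- labelFragments(fr, genomeRegions(toy$record),
                          genomeLength(toy$record))
    want <- vapply(fragmentStarts(fr), oracleLabel, "", L = 21L,
                   regdf = toy$regdf)
    expect_identical(as.character(got), want)
    ## the eight counts always add up to the fragment total
    expect_identical(sum(phaseAbundanceStats(got)$abundances), length(fr))
  }
})

test_that("junk takes precedence and gap-centered coding fragments are rescued", {
  N <- 300L
  ## two abutting genes with a 5 nt gap; fragments centered in the gap are
  ## mostly coding and must inherit the larger-overlap gene's phase
  regdf <- data.frame(start = c(1L, 156L), end = c(150L, 300L),
                      strand = c("+", "+"),
                      category = c("protein_coding", "protein_coding"),
                      stringsAsFactors = FALSE)
  rec <- GenomeRecord("gap", randomSequence(N), regdf)
  fr <- fragmentize(rec, L = 33L, R = 1L)
  labs <- labelFragments(fr, genomeRegions(rec), N)
  expect_false(any(is.na(labs)))
  centers <- fragmentCenters(fr)
  inGap <- centers >= 151L & centers <= 155L
  expect_true(all(labs[inGap] %in% c("F0", "F1", "F2")))
  want <- vapply(fragmentStarts(fr), oracleLabel, "", L = 33L, regdf = regdf)
  expect_identical(as.character(labs), want)
})

test_that("tail requires half-or-more RNA-gene coverage", {
  N <- 600L
  regdf <- data.frame(
    start = c(100L, 201L, 290L),
    end = c(200L, 280L, 360L),
    strand = c("+", "-", "+"),
    category = c("tRNA", "rRNA", "tRNA"),
    stringsAsFactors = FALSE)
  rec <- GenomeRecord("tail", randomSequence(N), regdf)
  fr <- fragmentize(rec, L = 201L, R = 4L)
  labs <- labelFragments(fr, genomeRegions(rec), N)
  want <- vapply(fragmentStarts(fr), oracleLabel, "", L = 201L, regdf = regdf)
  expect_identical(as.character(labs), want)
  expect_true("TAIL" %in% labs)
})

test_that("the border-junk estimate is the exact closed form", {
  expect_equal(estimateBorderJunk(603, 11, 50), 603 / 22 * 100)
  expect_equal(estimateBorderJunk(8, 4, 1), 2)        # L = 2R, one region
  expect_equal(estimateBorderJunk(603, 11, 100),
               2 * estimateBorderJunk(603, 11, 50))   # linear in n
})
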