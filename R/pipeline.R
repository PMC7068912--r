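#' @include AllClasses.R
NULL

#' Pipeline configuration
#'
#' Validates the fragmentation arithmetic (L odd and divisible by 3, R not
#' divisible by 3) and collects the knobs of the per-genome analysis.
#'
#' @param fragmentLength fragment length L.
#' @param step step R between fragment starts.
#' @param kmeansK number of K-means clusters for verification.
#' @param seed seed for K-means restarts.
#' @param restarts K-means restarts.
#' @param plane plane for circuit directions: \code{"centroid"} (the
#'   best-fit plane of the six phase centroids) or two PC indices.
#' @param orientationFlip global flip of the U/D call.
#' @return a validated list of class \code{tripletPhaseConfig}.
#' @export
runConfig <- function(fragmentLength = 603L, step = 11L, kmeansK = 4L,
                      seed = 0L, restarts = 10L, plane = "centroid",
                      orientationFlip = FALSE) {
  L <- as.integer(fragmentLength); R <- as.integer(step)
  if (L %% 2L == 0L || L %% 3L != 0L)
    stop("fragmentLength must be odd and divisible by 3")
  if (R %% 3L == 0L) stop("step must not be divisible by 3")
  if (kmeansK < 2L) stop("kmeansK must be at least 2")
  if (!identical(plane, "centroid")) {
    plane <- as.integer(plane)
    if (length(plane) != 2L || any(is.na(plane)) || any(plane < 1L))
      stop("plane must be \"centroid\" or two PC indices")
  }
  structure(list(fragmentLength = L, step = R, kmeansK = as.integer(kmeansK),
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 plane = plane,
                 orientationFlip = isTRUE(orientationFlip)),
            class = "tripletPhaseConfig")
}

#' Run the full per-genome analysis
#'
#' Executes fragmentation, triplet counting, least-SD triplet exclusion,
#' phase labeling, PCA embedding, K-means verification, centroid geometry
#' and the GC profile, returning everything as a result bundle.  When
#' \code{outDir} is given, the fragment table, frequency matrix, embedding
#' coordinates, geometry summary and GC profile are written as TSV;
#' outputs are byte-identical across reruns with the same inputs and
#' config.  A genome with an empty coding phase yields
#' \code{geometry = NULL} with the condition message in
#' \code{geometryError}; all other outputs remain intact.
#'
#' @param genome a \linkS4class{GenomeRecord}.
#' @param config a configuration from \code{\link{runConfig}}.
#' @param outDir optional output directory.
#' @return a list with elements \code{fragments}, \code{labels},
#'   \code{matrix}, \code{embedding}, \code{kmeans}, \code{geometry}
#'   (or NULL), \code{geometryError} (or NULL), \code{gc},
#'   \code{fragmentTable}.
#' @export
runGenome <- function(genome, config = runConfig(), outDir = NULL) {
  stopifnot(inherits(config, "tripletPhaseConfig"))
  frags <- fragmentize(genome, config$fragmentLength, config$step)
  mat <- buildTripletMatrix(frags)
  labels <- labelFragments(frags, genomeRegions(genome), genomeLength(genome))
  emb <- pcaEmbed(mat)
  km <- kmeansVerify(mat, K = config$kmeansK, seed = config$seed,
                     restarts = config$restarts)
  geometry <- NULL; geometryError <- NULL
  geometry <- tryCatch(
    classifyGeometry(emb, labels, plane = config$plane,
                     orientationFlip = config$orientationFlip),
    error = function(e) { geometryError <<- conditionMessage(e); NULL })
  gc <- buildGCProfile(genome, frags, labels)

  fragmentTable <- data.frame(
    genome_id = genomeId(genome),
    index = seq_len(length(frags)) - 1L,
    start = fragmentStarts(frags),
    center = fragmentCenters(frags),
    gc = gcPerFragment(gc)$gc,
    phase = as.character(labels),
    kmeans = km,
    stringsAsFactors = FALSE)

  bundle <- list(fragments = frags, labels = labels, matrix = mat,
                 embedding = emb, kmeans = km, geometry = geometry,
                 geometryError = geometryError, gc = gc,
                 fragmentTable = fragmentTable)
  if (!is.null(outDir)) .writeBundle(bundle, genome, config, outDir)
  bundle
}

.geometryRow <- function(genome, bundle) {
  g <- bundle$geometry
  ab <- phaseAbundanceStats(bundle$labels)
  row <- data.frame(genome_id = genomeId(genome),
                    excluded_triplet = excludedTriplet(bundle$matrix),
                    area_F = if (is.null(g)) NA_real_ else g@areaF,
                    area_B = if (is.null(g)) NA_real_ else g@areaB,
                    symmetry = if (is.null(g)) NA_character_ else g@symmetry,
                    orientation = if (is.null(g)) NA_character_ else g@orientation,
                    stringsAsFactors = FALSE)
  cnt <- as.list(ab$abundances)
  names(cnt) <- paste0("n_", names(cnt))
  cbind(row, as.data.frame(cnt),
        data.frame(coding_sd = ab$codingSd,
                   bias0 = ab$bias[["bias0"]],
                   bias1 = ab$bias[["bias1"]],
                   bias2 = ab$bias[["bias2"]]))
}

.writeBundle <- function(bundle, genome, config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  id <- genomeId(genome)
  hdr <- sprintf("# genome_id=%s L=%d R=%d K=%d seed=%d plane=%s",
                 id, config$fragmentLength, config$step, config$kmeansK,
                 config$seed, paste(config$plane, collapse = ","))
  wt <- function(df, name) {
    path <- file.path(outDir, paste0(id, "_", name, ".tsv"))
    con <- file(path, "w", encoding = "UTF-8")
    writeLines(hdr, con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  wt(bundle$fragmentTable, "fragments")
  coords <- as.data.frame(embeddingCoords(bundle$embedding))
  coords$phase <- as.character(bundle$labels)
  wt(coords, "embedding")
  wt(.geometryRow(genome, bundle), "geometry")
  wt(gcPerFragment(bundle$gc), "gc")
  exportTripletMatrix(bundle$matrix, file.path(outDir, paste0(id, "_matrix.tsv")))
  invisible(NULL)
}

#' Run the analysis over a corpus of genomes
#'
#' One geometry row per genome, the tally of excluded triplets, the
#' orientation-by-excluded-triplet contingency over the two most frequent
#' excluded triplets (emitted only when both dimensions have at least two
#' levels), and the cross-genome GC correlation matrix (when at least three
#' genomes are usable).
#'
#' @param genomes list of \linkS4class{GenomeRecord}.
#' @param config a configuration from \code{\link{runConfig}}.
#' @param outDir optional output directory for per-genome TSVs and the
#'   corpus summary.
#' @return list with \code{summary} (data.frame), \code{excludedTally},
#'   \code{contingency} (or NULL), \code{gcCorrelations} (or NULL),
#'   \code{bundles}.
#' @export
runCorpus <- function(genomes, config = runConfig(), outDir = NULL) {
  stopifnot(length(genomes) >= 1L)
  bundles <- lapply(genomes, runGenome, config = config, outDir = outDir)
  rows <- do.call(rbind, Map(.geometryRow, genomes, bundles))
  tally <- sort(table(rows$excluded_triplet), decreasing = TRUE)

  contingency <- NULL
  top2 <- names(tally)[seq_len(min(2L, length(tally)))]
  sub <- rows[rows$excluded_triplet %in% top2 & !is.na(rows$orientation), ]
  if (length(unique(sub$excluded_triplet)) >= 2L &&
      length(unique(sub$orientation)) >= 2L)
    contingency <- table(orientation = sub$orientation,
                         excluded = sub$excluded_triplet)

  gcCorrelations <- NULL
  profiles <- lapply(bundles, `[[`, "gc")
  if (length(profiles) >= 3L) {
    mat <- t(vapply(profiles, ensembleMeans, numeric(4)))
    zerovar <- apply(mat, 2, function(v) {
      v <- v[!is.na(v)]; length(v) < 2L || sd(v) == 0
    })
    gcCorrelations <- crossGenomeCorrelations(profiles)
    attr(gcCorrelations, "zeroVariance") <-
      c("genome", "coding", "junk", "tail")[zerovar]
  }
  if (!is.null(outDir)) {
    writeTable(rows, file.path(outDir, "corpus_geometry.tsv"))
    writeTable(data.frame(triplet = names(tally),
                          count = as.integer(tally)),
               file.path(outDir, "corpus_excluded_tally.tsv"))
    if (!is.null(gcCorrelations))
      writeTable(data.frame(ensemble = rownames(gcCorrelations),
                            as.data.frame(unclass(gcCorrelations[, , drop = FALSE]))),
                 file.path(outDir, "corpus_gc_correlations.tsv"))
  }
  list(summary = rows, excludedTally = tally, contingency = contingency,
       gcCorrelations = gcCorrelations, bundles = bundles)
}
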