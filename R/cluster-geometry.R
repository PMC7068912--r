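#' @include AllClasses.R
#' @importFrom stats prcomp kmeans
NULL

#' PCA embedding of the frequency matrix
#'
#' Top three principal components of the column-centered 63-dimensional
#' point matrix.  Because principal-component signs are arbitrary, each
#' component is flipped so that its largest-magnitude loading is positive;
#' the flips applied are recorded so runs are comparable.
#'
#' @param mat a \linkS4class{TripletFrequencyMatrix} (or plain matrix with
#'   at least 4 rows).
#' @return a \linkS4class{PhaseEmbedding}.
#' @export
pcaEmbed <- function(mat) {
  x <- if (is(mat, "TripletFrequencyMatrix")) points63(mat) else as.matrix(mat)
  if (nrow(x) < 4L) stop("PCA embedding needs at least 4 points")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  nz <- sum(pc$sdev > max(pc$sdev) * 1e-9)
  if (nz < 3L)
    stop("degenerate embedding: matrix rank ", nz, " < 3")
  flips <- vapply(1:3, function(k) {
    lo <- pc$rotation[, k]
    if (lo[which.max(abs(lo))] < 0) -1 else 1
  }, numeric(1))
  coords <- sweep(pc$x[, 1:3, drop = FALSE], 2, flips, `*`)
  colnames(coords) <- paste0("PC", 1:3)
  ev <- (pc$sdev^2 / sum(pc$sdev^2))[1:3]
  new("PhaseEmbedding", coords = coords, explainedVariance = ev,
      signFlips = flips)
}

#' K-means verification of the cluster structure
#'
#' Runs K-means (Euclidean inertia) with several restarts on the
#' 63-dimensional points and returns the best-inertia assignment with a
#' stable relabeling: clusters are renumbered by ascending centroid norm so
#' that identical data give identical labels across runs and seeds.
#'
#' @param mat a \linkS4class{TripletFrequencyMatrix} or plain matrix.
#' @param K number of clusters (the verification in this workflow uses 4:
#'   three coding-phase arrays plus the tail).
#' @param seed RNG seed for the restarts.
#' @param restarts number of random starts.
#' @return integer vector of cluster labels in 1..K.
#' @export
kmeansVerify <- function(mat, K = 4L, seed = 0L, restarts = 10L) {
  x <- if (is(mat, "TripletFrequencyMatrix")) points63(mat) else as.matrix(mat)
  if (K < 2L) stop("K must be at least 2")
  if (nrow(x) < K) stop("fewer points (", nrow(x), ") than clusters (", K, ")")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ## Hartigan-Wong emits a benign Quick-TRANSfer note on heavily structured
  ## data; convergence is still reached within iter.max
  km <- withCallingHandlers(
    kmeans(x, centers = K, nstart = restarts, iter.max = 100L),
    warning = function(w) {
      if (grepl("Quick-TRANSfer", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  norms <- sqrt(rowSums(km$centers^2))
  relabel <- match(seq_len(K), order(norms))
  as.integer(relabel[km$cluster])
}

#' Signed area of a triangle
#'
#' Half the cross product of the edge vectors from \code{p0}; positive when
#' the circuit p0 -> p1 -> p2 runs counterclockwise.  Antisymmetric under
#' swapping any two vertices, zero for collinear points.
#'
#' @param p0,p1,p2 numeric 2-vectors.
#' @return signed area.
#' @export
signedArea <- function(p0, p1, p2) {
  unname(((p1[1] - p0[1]) * (p2[2] - p0[2]) -
          (p1[2] - p0[2]) * (p2[1] - p0[1])) / 2)
}

#' Centroid geometry and symmetry classification
#'
#' Computes per-phase centroids in PC coordinates, the signed areas of the
#' (F0,F1,F2) and (B0,B1,B2) circuits in a chosen PC plane, and classifies
#' the configuration as \code{mirror} when the two circuits run in opposite
#' directions (signed areas of opposite signs) or \code{rotational} when
#' they agree -- the chloroplast versus bacteria dichotomy.  Orientation is
#' \code{U} when the pooled F2/B2 fragments sit above the pooled remaining
#' coding fragments along PC3 (after the deterministic sign convention),
#' else \code{D}; \code{orientationFlip} applies the one-time global flip
#' needed to align this proxy with a reference genome set, if desired.
#'
#' @param embedding a \linkS4class{PhaseEmbedding}.
#' @param labels factor of phase labels parallel to the embedding rows.
#' @param plane either \code{"centroid"} (default): the best-fit plane of
#'   the six coding-phase centroids within the embedding, i.e. the plane
#'   the phase hexagon actually spans, with a deterministic axis sign
#'   convention; or an integer pair of PC indices, e.g. \code{c(1, 2)}.
#'   The mirror/rotational call compares the two area signs, so it does
#'   not depend on the overall orientation of the chosen plane.
#' @param orientationFlip logical; flip the U/D call.
#' @return a \linkS4class{PhaseGeometry}.
#' @export
classifyGeometry <- function(embedding, labels, plane = "centroid",
                             orientationFlip = FALSE) {
  coords <- embeddingCoords(embedding)
  labels <- factor(labels, levels = PHASE_LEVELS)
  counts <- table(labels)
  missing <- CODING_PHASES[counts[CODING_PHASES] == 0L]
  if (length(missing))
    stop("geometry undefined: empty coding phase(s) ",
         paste(missing, collapse = ", "))
  present <- names(counts)[counts > 0L]
  centroids <- t(vapply(present, function(ph)
    colMeans(coords[labels == ph, , drop = FALSE]), numeric(3)))
  if (identical(plane, "centroid")) {
    hex <- centroids[CODING_PHASES, , drop = FALSE]
    pcp <- prcomp(hex, center = TRUE, scale. = FALSE)
    basis <- pcp$rotation[, 1:2, drop = FALSE]
    for (k in 1:2)
      if (basis[which.max(abs(basis[, k])), k] < 0) basis[, k] <- -basis[, k]
    P <- sweep(hex, 2, colMeans(hex)) %*% basis
    rownames(P) <- CODING_PHASES
    planeLabel <- "centroid"
  } else {
    plane <- as.integer(plane)
    P <- centroids[, plane]
    planeLabel <- paste0("PC", plane, collapse = ",")
  }
  areaF <- signedArea(P["F0", ], P["F1", ], P["F2", ])
  areaB <- signedArea(P["B0", ], P["B1", ], P["B2", ])
  symmetry <- if (areaF * areaB < 0) "mirror" else "rotational"

  merged <- labels %in% c("F2", "B2")
  rest <- labels %in% c("F0", "F1", "B0", "B1")
  up <- mean(coords[merged, 3]) > mean(coords[rest, 3])
  if (orientationFlip) up <- !up
  stats <- phaseAbundanceStats(labels)
  new("PhaseGeometry", centroids = centroids, areaF = areaF, areaB = areaB,
      symmetry = symmetry, orientation = if (up) "U" else "D",
      plane = planeLabel, abundances = stats$abundances,
      codingSd = stats$codingSd, bias = stats$bias)
}

#' Phase abundance statistics
#'
#' Counts per label, the population standard deviation of the six coding
#' phase counts, and the three signed forward/backward differences
#' |F0|-|B0|, |F1|-|B1|, |F2|-|B2|.
#'
#' @param labels factor (or character) of phase labels.
#' @return list with elements \code{abundances} (named integer),
#'   \code{codingSd} and \code{bias} (named numeric).
#' @export
phaseAbundanceStats <- function(labels) {
  labels <- factor(labels, levels = PHASE_LEVELS)
  ab <- table(labels)
  abundances <- setNames(as.integer(ab), PHASE_LEVELS)
  coding <- abundances[CODING_PHASES]
  codingSd <- sqrt(mean((coding - mean(coding))^2))
  bias <- c(bias0 = abundances[["F0"]] - abundances[["B0"]],
            bias1 = abundances[["F1"]] - abundances[["B1"]],
            bias2 = abundances[["F2"]] - abundances[["B2"]])
  list(abundances = abundances, codingSd = codingSd, bias = as.numeric(bias) |>
         setNames(names(bias)))
}
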