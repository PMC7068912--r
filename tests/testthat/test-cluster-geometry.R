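test_that("PCA embedding is centered, sign-stable and matches an SVD oracle", {
  set.seed(31)
  x <- matrix(rnorm(200 * 63), 200, 63)
  emb <- pcaEmbed(x)
  expect_identical(dim(embeddingCoords(emb)), c(200L, 3L))
  expect_lt(max(abs(colMeans(embeddingCoords(emb)))), 1e-9)
  ## component orthogonality
  cp <- crossprod(embeddingCoords(emb))
  expect_lt(max(abs(cp[upper.tri(cp)])) / max(diag(cp)), 1e-9)

  ## independent oracle: rank-3 reconstruction error from plain SVD
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  recon <- sv$u[, 1:3] %*% diag(sv$d[1:3]) %*% t(sv$v[, 1:3])
  errOracle <- sum((xc - recon)^2)
  errPca <- sum(xc^2) - sum(embeddingCoords(emb)^2)
  expect_lt(abs(errOracle - errPca), 1e-8)

  ## duplicating every row leaves the component directions unchanged
  emb2 <- pcaEmbed(rbind(x, x))
  expect_equal(embeddingCoords(emb2)[1:200, ], embeddingCoords(emb),
               tolerance = 1e-9)
})

test_that("near-planar data concentrate variance in two components", {
  set.seed(33)
  basis <- qr.Q(qr(matrix(rnorm(63 * 2), 63, 2)))
  x <- matrix(rnorm(120 * 2), 120, 2) %*% t(basis) +
    matrix(rnorm(120 * 63, sd = 1e-6), 120, 63)
  emb <- pcaEmbed(x)
  expect_lt(explainedVariance(emb)[3], 1e-9)
  ## exactly rank-2 data are refused with the achievable rank
  x2 <- matrix(rnorm(50 * 2), 50, 2) %*% t(basis)
  expect_error(pcaEmbed(x2), "rank 2")
})

test_that("K-means recovers well-separated blobs deterministically", {
  set.seed(35)
  centers <- matrix(rnorm(4 * 63, sd = 4), 4, 63)
  truth <- rep(1:4, each = 50)
  x <- centers[truth, ] + matrix(rnorm(200 * 63, sd = 0.1), 200, 63)
  k1 <- kmeansVerify(x, K = 4, seed = 0)
  expect_identical(length(unique(k1)), 4L)
  ## perfect recovery: each blob maps to exactly one cluster label
  expect_true(all(vapply(split(k1, truth),
                         function(v) length(unique(v)) == 1L, logical(1))))
  expect_identical(kmeansVerify(x, K = 4, seed = 0), k1)  # determinism
  ## stability across seeds after canonical relabeling
  k2 <- kmeansVerify(x, K = 4, seed = 1)
  expect_gte(mean(k1 == k2), 0.95)
  expect_error(kmeansVerify(x[1:3, ], K = 4), "fewer points")
})

test_that("signed areas obey orientation, antisymmetry and degeneracy", {
  expect_equal(signedArea(c(0, 0), c(1, 0), c(0, 1)), 0.5)
  expect_equal(signedArea(c(0, 0), c(0, 1), c(1, 0)), -0.5)
  expect_equal(signedArea(c(0, 0), c(1, 1), c(2, 2)), 0)
  set.seed(37)
  for (i in 1:20) {
    p <- matrix(rnorm(6), 3, 2)
    a <- signedArea(p[1, ], p[2, ], p[3, ])
    expect_equal(signedArea(p[2, ], p[1, ], p[3, ]), -a)  # swap 1,2
    expect_equal(signedArea(p[1, ], p[3, ], p[2, ]), -a)  # swap 2,3
    expect_equal(signedArea(p[3, ], p[2, ], p[1, ]), -a)  # swap 1,3
  }
})

test_that("mirrored and rotated centroid configurations classify correctly", {
  m <- embeddingFromCentroids(mirrorCentroids())
  gm <- classifyGeometry(m$embedding, m$labels)
  expect_identical(symmetryType(gm), "mirror")
  expect_lt(gm@areaF * gm@areaB, 0)

  r <- embeddingFromCentroids(rotatedCentroids())
  gr <- classifyGeometry(r$embedding, r$labels)
  expect_identical(symmetryType(gr), "rotational")
  expect_gt(gr@areaF * gr@areaB, 0)
})

test_that("the classification is invariant under rotations and flips under reflection", {
  m <- embeddingFromCentroids(mirrorCentroids())
  coords <- embeddingCoords(m$embedding)
  g0 <- classifyGeometry(m$embedding, m$labels, plane = c(1, 2))
  set.seed(39)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi)
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    rot <- coords; rot[, 1:2] <- coords[, 1:2] %*% t(Rm)
    embR <- new("PhaseEmbedding", coords = rot,
                explainedVariance = explainedVariance(m$embedding),
                signFlips = c(1, 1, 1))
    gR <- classifyGeometry(embR, m$labels, plane = c(1, 2))
    expect_identical(symmetryType(gR), symmetryType(g0))
    expect_equal(gR@areaF, g0@areaF, tolerance = 1e-6)
  }
  ## reflecting the plane negates both signed areas, preserving the call
  refl <- coords; refl[, 1] <- -refl[, 1]
  embF <- new("PhaseEmbedding", coords = refl,
              explainedVariance = explainedVariance(m$embedding),
              signFlips = c(1, 1, 1))
  gF <- classifyGeometry(embF, m$labels, plane = c(1, 2))
  expect_equal(gF@areaF, -g0@areaF, tolerance = 1e-6)
  expect_equal(gF@areaB, -g0@areaB, tolerance = 1e-6)
  expect_identical(symmetryType(gF), symmetryType(g0))
  ## the centroid-plane call agrees with the explicit-plane call here
  expect_identical(symmetryType(classifyGeometry(m$embedding, m$labels)),
                   symmetryType(g0))
})

test_that("an empty coding phase is reported by name", {
  m <- embeddingFromCentroids(mirrorCentroids())
  labs <- as.character(m$labels)
  labs[labs == "B1"] <- "JUNK"
  expect_error(classifyGeometry(m$embedding, factor(labs, levels = levels(m$labels))),
               "B1")
})

test_that("phase abundance statistics count, spread and bias correctly", {
  labs <- factor(rep(c("F0", "F1", "F2", "B0", "B1", "B2"), each = 10),
                 levels = tripletPhase:::PHASE_LEVELS)
  st <- phaseAbundanceStats(labs)
  expect_equal(st$codingSd, 0)
  expect_identical(sum(st$abundances), 60L)

  labs2 <- factor(c(rep("F0", 3), "B0"), levels = tripletPhase:::PHASE_LEVELS)
  st2 <- phaseAbundanceStats(labs2)
  expect_equal(st2$bias[["bias0"]], 2)
  expect_equal(st2$bias[["bias1"]], 0)
})
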