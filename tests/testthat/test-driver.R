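params <- alignParams()

test_that("median strategy picks the protein of lower-median length", {
  s <- lapply(c(50, 60, 70), function(n) randomBackbone(n, seed = n))
  expect_equal(selectInitialConsensus(s, "median", params), 2L)
  s4 <- lapply(c(70, 50, 60, 80), function(n) randomBackbone(n, seed = n))
  expect_equal(selectInitialConsensus(s4, "median", params), 3L)  # lower median
})

test_that("center strategy picks the structurally central protein", {
  set.seed(61)
  template <- caCoords(randomBackbone(40, seed = 31))
  bump <- 3 * sin(seq_len(40) / 3) %o% c(1, 0, 0)
  mk <- function(X) applyTransform(X, randomMotion())
  s <- list(mk(template), mk(template + bump / 2), mk(template + bump))
  expect_equal(selectInitialConsensus(s, "center", params), 2L)
  expect_equal(selectInitialConsensus(s, "minmax", params), 2L)
})

test_that("maxcore strategy breaks ties to the lowest index", {
  set.seed(62)
  template <- randomBackbone(25, seed = 32)
  s <- lapply(1:3, function(i)
    applyTransform(template, invertTransform(randomMotion())))
  expect_equal(selectInitialConsensus(s, "maxcore", params), 1L)
  expect_error(selectInitialConsensus(s[1], "maxcore", params),
               "at least two")
})

test_that("interleaved transforms/consensus collapses scrambled rigid copies", {
  set.seed(63)
  X <- caCoords(randomBackbone(30, seed = 33))
  K <- 4
  coords <- lapply(1:K, function(k) applyTransform(X, randomMotion()))
  idx <- do.call(rbind, rep(list(seq_len(30)), K + 1))
  H <- mapscir:::newCorrespondence(idx, coords[[1]], coords)
  out <- optimalTransformsAndConsensus(H, params)
  expect_lt(out$sc, 1e-6)
  moved <- alignedCoords(out$correspondence)
  for (k in 2:K)
    expect_lt(max(abs(moved[[k]] - moved[[1]])), 1e-4)
})

test_that("interleaved refinement is a no-op at a fixed point", {
  X <- caCoords(randomBackbone(20, seed = 34))
  idx <- rbind(1:20, 1:20, 1:20)
  H <- mapscir:::newCorrespondence(idx, X, list(X, X))
  out <- optimalTransformsAndConsensus(H, params)
  expect_equal(out$sc, 0, tolerance = 1e-12)
  for (tf in out$transforms) {
    expect_equal(rotationMatrix(tf), diag(3), tolerance = 1e-9)
    expect_equal(translationVector(tf), c(0, 0, 0), tolerance = 1e-9)
  }
  expect_equal(consensusCoords(out$correspondence), X, tolerance = 1e-12)
})

test_that("a single protein yields its own consensus and identity transform", {
  X <- caCoords(randomBackbone(15, seed = 35))
  H <- mapscir:::newCorrespondence(rbind(1:15, 1:15), X, list(X))
  out <- optimalTransformsAndConsensus(H, params)
  expect_equal(consensusCoords(out$correspondence), X, tolerance = 1e-9)
  expect_equal(rotationMatrix(out$transforms[[1]]), diag(3),
               tolerance = 1e-9)
})

test_that("rigid families align to machine precision with a full core", {
  fam <- makeFamily(familySpec(templateLength = 50, K = 4, seed = 36))
  res <- mapsci(fam$structures)
  expect_lt(tail(scTrace(res), 1), 1e-4)
  rep <- coreReport(res)
  expect_equal(rep$core_percent, 100)
  expect_lt(rep$core_rmsd, 0.01)
  expect_true(all(diff(scTrace(res)) <= 1e-9))
})

test_that("noisy families converge with bounded core RMSD and no gaps", {
  fam <- makeFamily(familySpec(templateLength = 50, K = 4, noiseSigma = 0.5,
                               seed = 37))
  res <- mapsci(fam$structures)
  expect_true(all(diff(scTrace(res)) <= 1e-9))
  expect_false(anyNA(correspondenceMatrix(res)[-1, ]))  # all residues matched
  rep <- coreReport(res)
  expect_gt(rep$core_rmsd, 0)
  expect_lte(rep$core_rmsd, 1.2)
  expect_equal(rep$core_percent, 100)
})

test_that("for K = 2 the consensus sits at the column midpoints", {
  fam <- makeFamily(familySpec(templateLength = 30, K = 2, noiseSigma = 0.4,
                               seed = 38))
  res <- mapsci(fam$structures)
  idx <- correspondenceMatrix(res)
  g <- alignedCoords(res)
  match <- !is.na(idx[2, ]) & !is.na(idx[3, ])
  a <- g[[1]][idx[2, match], ]; b <- g[[2]][idx[3, match], ]
  cons <- consensusCoords(res)[idx[1, match], ]
  expect_equal(cons, (a + b) / 2, tolerance = 1e-6)
  # the centroid halves the pairwise squared distance per column
  handSC <- sum(rowSums((a - b)^2)) / 2 +
    gapCostSq(params) * sum(is.na(idx[2, ]) != is.na(idx[3, ]))
  expect_equal(tail(scTrace(res), 1), handSC, tolerance = 1e-6)
})

test_that("final SC is invariant under one rigid motion of all inputs", {
  fam <- makeFamily(familySpec(templateLength = 35, K = 3, noiseSigma = 0.4,
                               seed = 39))
  res0 <- mapsci(fam$structures)
  set.seed(101)
  tf <- randomMotion()
  moved <- lapply(fam$structures, applyTransform, transform = tf)
  res1 <- mapsci(moved)
  sc0 <- tail(scTrace(res0), 1); sc1 <- tail(scTrace(res1), 1)
  expect_lt(abs(sc0 - sc1) / max(sc0, 1e-12), 1e-6)
})

test_that("input order barely affects the final SC-distance", {
  fam <- makeFamily(familySpec(templateLength = 35, K = 4, noiseSigma = 0.4,
                               seed = 40))
  res0 <- mapsci(fam$structures)
  res1 <- mapsci(rev(fam$structures))
  sc0 <- tail(scTrace(res0), 1); sc1 <- tail(scTrace(res1), 1)
  expect_lt(abs(sc0 - sc1) / max(sc0, sc1), 0.01)
})

test_that("driver rejects degenerate inputs", {
  s <- list(randomBackbone(10, seed = 1))
  expect_error(mapsci(s), "at least two")
  s2 <- list(randomBackbone(10, seed = 1), caStructure(matrix(0, 1, 3)))
  expect_error(mapsci(s2), "at least 3")
})
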