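params <- alignParams()

test_that("merging a single pair alignment reproduces it", {
  set.seed(31)
  cons <- matrix(rnorm(15, sd = 4), 5, 3)
  pa <- randomPairAlignment(cons, 7, params)
  H <- mergeCenterStar(cons, list(pa$alignment), list(pa$coords))
  back <- mapscir:::projectPair(H, 1, params)
  expect_identical(back@fixedIdx, pa$alignment@fixedIdx)
  expect_identical(back@movingIdx, pa$alignment@movingIdx)
  expect_equal(back@cost, pa$alignment@cost, tolerance = 1e-9)
})

test_that("insertions at distinct consensus slots get distinct columns", {
  # consensus of 3; protein 1 inserts after position 1, protein 2 after
  # position 2 -> width 5, and each insertion column is gapped for the other
  cons <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE)
  a1 <- mapscir:::newPairAlignment(c(1L, NA, 2L, 3L), c(1L, 2L, 3L, 4L), 0, 3L, 4L)
  a2 <- mapscir:::newPairAlignment(c(1L, 2L, NA, 3L), c(1L, 2L, 3L, 4L), 0, 3L, 4L)
  c1 <- matrix(rnorm(12), 4, 3); c2 <- matrix(rnorm(12), 4, 3)
  H <- mergeCenterStar(cons, list(a1, a2), list(c1, c2))
  idx <- correspondenceMatrix(H)
  expect_equal(ncol(idx), 5L)
  expect_equal(idx[1, ], c(1L, NA, 2L, NA, 3L))
  expect_equal(idx[2, ], c(1L, 2L, 3L, NA, 4L))
  expect_equal(idx[3, ], c(1L, NA, 2L, 3L, 4L))
})

test_that("insertions at the same slot share left-aligned columns", {
  cons <- matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE)
  a1 <- mapscir:::newPairAlignment(c(1L, NA, 2L), c(1L, 2L, 3L), 0, 2L, 3L)
  a2 <- mapscir:::newPairAlignment(c(1L, NA, NA, 2L), c(1L, 2L, 3L, 4L), 0, 2L, 4L)
  H <- mergeCenterStar(cons, list(a1, a2),
                       list(matrix(rnorm(9), 3, 3), matrix(rnorm(12), 4, 3)))
  idx <- correspondenceMatrix(H)
  expect_equal(ncol(idx), 4L)   # 2 consensus + max(1, 2) insertion columns
  expect_equal(idx[1, ], c(1L, NA, NA, 2L))
  expect_equal(idx[2, ], c(1L, 2L, NA, 3L))
  expect_equal(idx[3, ], c(1L, 2L, 3L, 4L))
})

test_that("gapless equal-length alignments merge with no gaps", {
  cons <- matrix(rnorm(12), 4, 3)
  pas <- lapply(1:3, function(i) mapscir:::identityAlignment(4L))
  H <- mergeCenterStar(cons, pas, replicate(3, cons, simplify = FALSE))
  expect_equal(ncol(correspondenceMatrix(H)), 4L)
  expect_false(anyNA(correspondenceMatrix(H)))
})

test_that("merge projection reproduces every input pairwise alignment", {
  set.seed(32)
  for (trial in 1:30) {
    n0 <- sample(4:12, 1)
    K <- sample(2:5, 1)
    cons <- matrix(rnorm(3 * n0, sd = 5), n0, 3)
    pas <- lapply(seq_len(K), function(j)
      randomPairAlignment(cons, sample(3:15, 1), params))
    H <- mergeCenterStar(cons, lapply(pas, `[[`, "alignment"),
                         lapply(pas, `[[`, "coords"))
    for (j in seq_len(K)) {
      back <- mapscir:::projectPair(H, j, params)
      expect_identical(back@fixedIdx, pas[[j]]$alignment@fixedIdx)
      expect_identical(back@movingIdx, pas[[j]]$alignment@movingIdx)
      expect_equal(back@cost, pas[[j]]$alignment@cost, tolerance = 1e-9)
    }
  }
})

test_that("merge rejects a consensus-length mismatch", {
  cons <- matrix(rnorm(9), 3, 3)
  pa <- mapscir:::identityAlignment(4L)
  expect_error(mergeCenterStar(cons, list(pa), list(matrix(rnorm(12), 4, 3))),
               "consensus length")
})

test_that("SC-distance matches hand-computed cases", {
  g <- gapCostSq(params)
  cons <- matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE)
  # single protein identical to the consensus, gapless
  H <- mapscir:::newCorrespondence(rbind(1:2, 1:2), cons, list(cons))
  expect_equal(scDistance(H, params), 0)
  # protein gap against a consensus triple contributes exactly the gap cost
  H2 <- mapscir:::newCorrespondence(rbind(1:2, c(1L, NA)), cons,
                                    list(cons[1, , drop = FALSE]))
  expect_equal(scDistance(H2, params), g)
  # K identical proteins: zero regardless of K
  H3 <- mapscir:::newCorrespondence(rbind(1:2, 1:2, 1:2, 1:2), cons,
                                    list(cons, cons, cons))
  expect_equal(scDistance(H3, params), 0)
  # matched triples contribute squared distance
  shifted <- cons + rep(c(2, 0, 0), each = 2)
  H4 <- mapscir:::newCorrespondence(rbind(1:2, 1:2), cons, list(shifted))
  expect_equal(scDistance(H4, params), 8)
})

test_that("SC-distance is invariant under a common rigid motion", {
  set.seed(33)
  cons <- matrix(rnorm(18, sd = 5), 6, 3)
  pas <- lapply(1:3, function(j) randomPairAlignment(cons, 8, params))
  H <- mergeCenterStar(cons, lapply(pas, `[[`, "alignment"),
                       lapply(pas, `[[`, "coords"))
  sc0 <- scDistance(H, params)
  tf <- randomMotion()
  Hm <- mapscir:::newCorrespondence(
    correspondenceMatrix(H), applyTransform(consensusCoords(H), tf),
    lapply(alignedCoords(H), applyTransform, transform = tf))
  expect_equal(scDistance(Hm, params), sc0, tolerance = 1e-8)
})

test_that("stripping all-gap columns is idempotent and SC-preserving", {
  cons <- matrix(rnorm(9), 3, 3)
  prot <- matrix(rnorm(9), 3, 3)
  idx <- rbind(c(1L, NA, 2L, NA, 3L), c(1L, NA, 2L, NA, 3L))
  H <- mapscir:::newCorrespondence(idx, cons, list(prot))
  sc0 <- scDistance(H, params)
  Hs <- stripAllGapColumns(H)
  expect_equal(ncol(correspondenceMatrix(Hs)), 3L)
  expect_equal(scDistance(Hs, params), sc0)
  expect_identical(correspondenceMatrix(stripAllGapColumns(Hs)),
                   correspondenceMatrix(Hs))
  # no all-gap columns: unchanged
  expect_identical(correspondenceMatrix(stripAllGapColumns(Hs)),
                   correspondenceMatrix(Hs))
})
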