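# Independent oracles and fixture builders used across the suite.

# Exhaustively enumerate every global alignment of two coordinate sets and
# return the minimum cost. Independent of the DP: plain recursion over the
# three column types. Only for tiny inputs (lengths <= 6).
bruteForceAlignCost <- function(fixed, moving, gapCost) {
  n <- nrow(fixed); m <- nrow(moving)
  rec <- function(i, j) {
    if (i > n && j > m) return(0)
    best <- Inf
    if (i <= n && j <= m)
      best <- min(best, sum((fixed[i, ] - moving[j, ])^2) + rec(i + 1L, j + 1L))
    if (i <= n) best <- min(best, gapCost + rec(i + 1L, j))
    if (j <= m) best <- min(best, gapCost + rec(i, j + 1L))
    best
  }
  rec(1L, 1L)
}

# random rigid motion applied to row-vector coordinates
randomMotion <- function() {
  rigidTransform(rotation = randomRotation(),
                 translation = stats::runif(3, -15, 15))
}

# Minimal fixed-column PDB CA record (columns per the PDB spec).
pdbCaLine <- function(serial, resid, chain, resno, xyz, alt = " ",
                      type = "ATOM") {
  sprintf("%-6s%5d  CA %s%-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          type, serial, alt, resid, chain, resno, xyz[1], xyz[2], xyz[3])
}

writePdbFixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a straight 3-residue chain fixture used in several I/O tests
threeResidueFixture <- function() {
  writePdbFixture(c(
    pdbCaLine(1, "ALA", "A", 1, c(0, 0, 0)),
    pdbCaLine(2, "GLY", "A", 2, c(3.8, 0, 0)),
    pdbCaLine(3, "SER", "A", 3, c(7.6, 0, 0))))
}

# Random (consensus, protein) pair alignment produced by the package's own
# DP on random coordinates; used as merge-fixture input.
randomPairAlignment <- function(consensus, lenMoving, params = alignParams()) {
  moving <- matrix(stats::rnorm(lenMoving * 3, sd = 6), lenMoving, 3)
  list(alignment = dpAlign(consensus, moving, params), coords = moving)
}
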