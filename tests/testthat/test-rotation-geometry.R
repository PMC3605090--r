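# structure with one P atom per residue per chain, from named coord list
structFromCoords <- function(coordsByChain, label = "toy") {
  atoms <- do.call(rbind, lapply(names(coordsByChain), function(ch) {
    m <- coordsByChain[[ch]]
    data.frame(chain = ch, resno = seq_len(nrow(m)), resid = "U",
               elety = "P", x = m[, 1], y = m[, 2], z = m[, 3],
               b = NA_real_, stringsAsFactors = FALSE)
  }))
  new("RiboStructure", atoms = atoms, label = label)
}

test_that("idealization returns an exactly rigid, correctly oriented copy", {
  set.seed(31)
  refS <- matrix(rnorm(600, sd = 8), ncol = 3)
  expect_equal(idealizeCore(refS, refS), refS, tolerance = 1e-10)

  R <- rotMat(c(1, 2, 2), 9)
  frameS <- refS %*% t(R) + matrix(rnorm(600, sd = 0.3), ncol = 3)
  # internal geometry identical to the reference (exactly rigid)
  expect_lt(max(abs(dist(idealizeCore(frameS, refS)) - dist(refS))),
            1e-9)

  # recovered rotation within 0.2 degrees of the applied 9 degrees
  # (orientation error shrinks as 1 / sqrt(core size))
  ref <- matrix(rnorm(6000, sd = 8), ncol = 3)
  frame <- ref %*% t(R) + matrix(rnorm(6000, sd = 0.3), ncol = 3)
  rec <- superpose(ref, frame)@rotation
  angle <- acos((sum(diag(rec %*% t(R))) - 1) / 2) * 180 / pi
  expect_lt(angle, 0.2)
})

test_that("the maximal-rotation P pair matches brute-force search and the known angle", {
  set.seed(32)
  # 12-atom toy core with shared z-levels so in-plane pairs exist
  mov <- cbind(rnorm(12, sd = 8), rnorm(12, sd = 8),
               rep(c(0, 2, 5), each = 4))
  fix <- matrix(rnorm(30, sd = 8), ncol = 3) + 30
  movB <- mov %*% t(rotMat(c(0, 0, 1), 10))
  A <- structFromCoords(list(F = fix, M = mov))
  B <- structFromCoords(list(F = fix, M = movB))
  fixedKeys <- paste0("F:", 1:10)
  movingKeys <- paste0("M:", 1:12)
  ax <- suppressMessages(
    findMaxRotationPair(A, B, movingKeys, fixedKeys))
  expect_equal(ax@maxAngleChange, 10, tolerance = 1e-6)
  # winning pair vector lies in the xy-plane
  vC <- ax@movingRef[ax@pairRows[2], ] - ax@movingRef[ax@pairRows[1], ]
  expect_lt(abs(vC[3]) / sqrt(sum(vC^2)), 1e-9)
  # equals the exhaustive oracle maximum
  oracle <- oracleMaxPair(mov, movB)
  expect_equal(ax@maxAngleChange, oracle$angle, tolerance = 1e-9)

  expect_error(findMaxRotationPair(A, A, movingKeys, fixedKeys),
               "no rotation detected")
})

test_that("pair search about a random axis reaches the prescribed rotation and the oracle maximum", {
  set.seed(33)
  u <- c(1, -1, 2) / sqrt(6)
  basis <- qr.Q(qr(cbind(u, rnorm(3), rnorm(3))))
  lat <- cbind(rnorm(40, sd = 10), rnorm(40, sd = 10),
               sample(seq(-6, 6, 3), 40, replace = TRUE))
  mov <- lat %*% t(basis[, c(2, 3, 1)])  # snapped coordinate along u
  fix <- matrix(rnorm(36, sd = 10), ncol = 3) - 40
  movB <- mov %*% t(rotMat(u, 7))
  A <- structFromCoords(list(F = fix, M = mov))
  B <- structFromCoords(list(F = fix, M = movB))
  ax <- suppressMessages(
    findMaxRotationPair(A, B, movingCore = paste0("M:", 1:40),
                        fixedCore = paste0("F:", 1:12)))
  expect_gte(ax@maxAngleChange, 7 - 1e-6)
  expect_equal(ax@maxAngleChange, oracleMaxPair(mov, movB)$angle,
               tolerance = 1e-9)
  # plane normal recovers the rotation axis up to sign
  expect_equal(abs(sum(ax@planeNormal * u)), 1, tolerance = 1e-9)
})

test_that("angles are recovered signed, frame-invariant, and zero at the reference", {
  asm <- genAssemblyTrajectory(assemblySpec(
    nFixedCore = 20, nMovingCore = 30, nMobile = 0, coreJitterSigma = 0,
    rotationPath = c(0, 20), seed = 34))
  ax <- suppressMessages(findMaxRotationPair(
    asm$classical, asm$rotated,
    movingCore = residueKeys(selectResidues(asm$topology, "all", "B")),
    fixedCore = residueKeys(selectResidues(asm$topology, "all", "A"))))

  expect_equal(computeAngle(asm$classical, ax), 0, tolerance = 1e-9)

  # round trip over signed angles, noiseless
  u <- asm$truth$axis; ctr <- asm$truth$centre
  mkFrame <- function(alpha) {
    co <- frameCoords(asm$classical)
    mi <- ax@movingIdx
    co[mi, ] <- sweep(sweep(co[mi, ], 2, ctr) %*% t(rotMat(u, alpha)),
                      2, ctr, "+")
    co
  }
  for (alpha in c(-10, -5, 0, 5, 10, 20))
    expect_equal(computeAngle(mkFrame(alpha), ax), alpha,
                 tolerance = 0.05)

  # global rigid transforms leave the angle unchanged
  set.seed(35)
  fr <- mkFrame(7)
  for (k in 1:3)
    expect_equal(computeAngle(applyRigid(fr, randomRigid()), ax),
                 computeAngle(fr, ax), tolerance = 1e-6)

  # with atomic noise sigma = 0.5 A on a >= 100-atom core: within 0.5 deg
  set.seed(36)
  big <- genAssemblyTrajectory(assemblySpec(
    nFixedCore = 40, nMovingCore = 60, nMobile = 0, coreJitterSigma = 0,
    rotationPath = c(0, 20), seed = 37))
  ax2 <- suppressMessages(findMaxRotationPair(
    big$classical, big$rotated,
    movingCore = residueKeys(selectResidues(big$topology, "all", "B")),
    fixedCore = residueKeys(selectResidues(big$topology, "all", "A"))))
  co <- frameCoords(big$classical)
  mi <- ax2@movingIdx
  co[mi, ] <- sweep(sweep(co[mi, ], 2, big$truth$centre) %*%
                      t(rotMat(big$truth$axis, 8)),
                    2, big$truth$centre, "+")
  noisy <- co + matrix(rnorm(length(co), sd = 0.5), ncol = 3)
  expect_equal(computeAngle(noisy, ax2), 8, tolerance = 0.5)
})

test_that("landmark centroid distances follow the Euclidean contract", {
  co <- list(X = rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0)),
             Y = rbind(c(3, 4, 0), c(0, 5, 0)))
  st <- structFromCoords(co)
  d1 <- landmarkDefinition(st, "X:1", "Y:1", label = "d")
  expect_equal(landmarkDistance(st, d1), 5)
  # centroid of two atoms at +/- (1,0,0) sits at the origin
  d2 <- landmarkDefinition(st, c("X:2", "X:3"), "Y:2")
  expect_equal(landmarkDistance(st, d2), 5)
  d3 <- landmarkDefinition(st, "X:1", "X:1")
  expect_equal(landmarkDistance(st, d3), 0)
})

test_that("coordinate series track the generator path and honour stride", {
  path <- seq(0, 10, length.out = 100)
  asm <- genAssemblyTrajectory(assemblySpec(
    nFixedCore = 15, nMovingCore = 25, nMobile = 0, coreJitterSigma = 0,
    rotationPath = path, seed = 41))
  ax <- suppressMessages(findMaxRotationPair(
    asm$classical, asm$rotated,
    movingCore = residueKeys(selectResidues(asm$topology, "all", "B")),
    fixedCore = residueKeys(selectResidues(asm$topology, "all", "A"))))
  s <- angleSeries(asm$trajectory, ax)
  expect_equal(s@values, path, tolerance = 0.05)
  expect_equal(s@units, "degrees")
  s10 <- angleSeries(asm$trajectory, ax, stride = 10L)
  expect_length(s10@values, 10L)

  static <- genAssemblyTrajectory(assemblySpec(
    nFixedCore = 15, nMovingCore = 25, nMobile = 0, coreJitterSigma = 0,
    rotationPath = rep(5, 10), seed = 42))
  sS <- angleSeries(static$trajectory, ax)
  expect_lt(diff(range(sS@values)), 1e-9)
})

test_that("idealizing over core residues only minimizes angle-series variance", {
  # noisy cores plus wildly mobile periphery; constant true rotation
  asm <- genAssemblyTrajectory(assemblySpec(
    nFixedCore = 20, nMovingCore = 20, nMobile = 10,
    coreJitterSigma = 0.3, mobileSigma = 2,
    rotationPath = c(0, rep(5, 79)), seed = 43))
  coreB <- residueKeys(selectResidues(asm$topology, "all", "B"))
  coreA <- residueKeys(selectResidues(asm$topology, "all", "A"))
  ax <- suppressMessages(findMaxRotationPair(
    asm$classical, asm$rotated, movingCore = coreB, fixedCore = coreA))

  frames <- 2:nFrames(asm$trajectory)
  idealized <- vapply(frames, function(i)
    computeAngle(asm$trajectory, ax, i = i), numeric(1))

  # (a) no idealization: raw pair vector after fixed-frame alignment
  raw <- vapply(frames, function(i) {
    xyz <- frameCoords(asm$trajectory, i)
    tr <- superpose(xyz[ax@fixedIdx, ], ax@fixedRef)
    mov <- applyTransform(xyz[ax@movingIdx, ], tr)
    v <- mov[ax@pairRows[2], ] - mov[ax@pairRows[1], ]
    n <- ax@planeNormal
    vp <- v - sum(v * n) * n
    r <- ax@referenceVector
    atan2(sum((c(r[2] * vp[3] - r[3] * vp[2],
                 r[3] * vp[1] - r[1] * vp[3],
                 r[1] * vp[2] - r[2] * vp[1])) * n),
          sum(r * vp)) * 180 / pi
  }, numeric(1))

  # (b) idealizing over all candidates (core + mobile periphery)
  axAll <- ax
  allIdx <- sort(c(ax@movingIdx,
                   riboLandscape:::.atomIndices(asm$topology,
                     residueKeys(selectResidues(asm$topology, "all",
                                                "C")))))
  axAll@movingIdx <- allIdx
  axAll@movingRef <- frameCoords(asm$classical)[allIdx, ]
  axAll@pairRows <- match(ax@movingIdx[ax@pairRows], allIdx)
  idealAll <- vapply(frames, function(i)
    computeAngle(asm$trajectory, axAll, i = i), numeric(1))

  expect_lte(var(idealized), var(raw))
  expect_lte(var(idealized), var(idealAll))
})
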