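test_that("PDB fixtures round-trip through read with field preservation", {
  asm <- genAssemblyTrajectory(assemblySpec(
    nFixedCore = 10, nMovingCore = 10, nMobile = 0,
    coreJitterSigma = 0, rotationPath = c(0, 5), seed = 11))
  f <- tempfile(fileext = ".pdb")
  writeFixturePdb(asm, 1, f)
  st <- readStructure(f)
  expect_s4_class(st, "RiboStructure")
  expect_equal(nAtoms(st), nAtoms(asm$topology))
  expect_equal(atomTable(st)$elety, atomTable(asm$topology)$elety)
  expect_equal(atomTable(st)$chain, atomTable(asm$topology)$chain)
  expect_equal(length(residueKeys(st)), 20L)
  # coordinates at PDB text precision
  expect_lt(max(abs(frameCoords(st) - frameCoords(asm$trajectory, 1))),
            1e-3)
  expect_error(readStructure(tempfile()), "not found")
})

test_that("B-factor columns survive a write/read cycle", {
  st <- chainFixture(5)
  st@atoms$b <- c(10, 20.5, 31.25, 0, 5.75)
  f <- tempfile(fileext = ".pdb")
  writeFixturePdb(st, path = f)
  back <- readStructure(f)
  expect_equal(atomTable(back)$b, st@atoms$b, tolerance = 1e-6)
})

test_that("residue selections resolve inclusively and report the printed candidate sizes", {
  ssu <- chainFixture(1542)   # complete small-subunit rRNA-like chain
  lsu <- chainFixture(2903)   # complete large-subunit rRNA-like chain
  expect_length(residueKeys(selectResidues(ssu, "5-920,1397-1540")), 1060L)
  expect_length(residueKeys(selectResidues(ssu, "935-1047,1210-1380")),
                284L)
  expect_length(residueKeys(selectResidues(lsu, "all")), 2903L)
  # order of ranges does not matter
  expect_setequal(
    residueKeys(selectResidues(ssu, "1397-1540,5-920")),
    residueKeys(selectResidues(ssu, "5-920,1397-1540")))
  # single residue and errors
  expect_length(residueKeys(selectResidues(ssu, "7")), 1L)
  expect_error(selectResidues(chainFixture(10), "5-12"), "missing residues")
  expect_error(selectResidues(ssu, "9-5"), "reversed")
})

test_that("superposition recovers known transforms and forbids reflections", {
  set.seed(1)
  x <- matrix(rnorm(60, sd = 5), ncol = 3)
  s0 <- superpose(x, x)
  expect_equal(s0@rmsd, 0, tolerance = 1e-10)
  expect_equal(s0@rotation, diag(3), tolerance = 1e-10)
  expect_equal(s0@translation, rep(0, 3), tolerance = 1e-10)

  R <- rotMat(c(0, 0, 1), 17)
  y <- sweep(x %*% t(R), 2, c(1, 2, 3), "+")
  s <- superpose(y, x)                    # recover the inverse transform
  expect_lt(s@rmsd, 1e-8)
  expect_equal(applyTransform(y, s), x, tolerance = 1e-8)
  expect_equal(det(s@rotation), 1, tolerance = 1e-9)

  expect_error(superpose(x[1:5, ], x), "dimensions")
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(superpose(line, line + 0.0), "collinear")
})

test_that("superposition agrees with the bio3d fitting oracle", {
  set.seed(7)
  x <- matrix(rnorm(90, sd = 4), ncol = 3)
  y <- applyRigid(x, randomRigid()) + matrix(rnorm(90, sd = 0.3), ncol = 3)
  ours <- superpose(y, x)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(x)), mobile = as.vector(t(y))))
  oracle <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3, byrow = TRUE) - x)^2)))
  expect_equal(ours@rmsd, oracle, tolerance = 1e-6)
})

test_that("superposition rmsd under Gaussian jitter matches the Monte-Carlo expectation", {
  # with per-axis jitter sigma on n points, the fitted rmsd concentrates
  # near sigma*sqrt(3) (fit removes 6 of 3n degrees of freedom)
  set.seed(42)
  x <- matrix(rnorm(300, sd = 5), ncol = 3)
  rmsds <- vapply(1:50, function(i) {
    y <- x + matrix(rnorm(300, sd = 0.1), ncol = 3)
    superpose(y, x)@rmsd
  }, numeric(1))
  expected <- 0.1 * sqrt(3) * sqrt(1 - 6 / 300)
  expect_lt(abs(mean(rmsds) - expected),
            3 * sd(rmsds) / sqrt(length(rmsds)))
})

test_that("superposition is invariant to pre-applied global rigid transforms", {
  set.seed(3)
  for (k in 1:5) {
    x <- matrix(rnorm(45, sd = 3), ncol = 3)
    y <- x + matrix(rnorm(45, sd = 0.5), ncol = 3)
    rig <- randomRigid()
    expect_equal(superpose(applyRigid(x, rig), applyRigid(y, rig))@rmsd,
                 superpose(x, y)@rmsd, tolerance = 1e-9)
  }
})

test_that("per-residue rmsf vanishes for static trajectories and matches the jitter closed form", {
  spec <- assemblySpec(nFixedCore = 8, nMovingCore = 8, nMobile = 0,
                       coreJitterSigma = 0, rotationPath = rep(0, 10),
                       seed = 2)
  asm <- genAssemblyTrajectory(spec)
  sel <- selectResidues(asm$topology, "all", chain = "A")
  r <- perResidueRmsf(asm$trajectory, sel)
  expect_true(all(r < 1e-9))

  # isotropic jitter sigma per axis -> per-atom rmsf -> sigma * sqrt(3)
  sigma <- 0.5
  spec2 <- assemblySpec(nFixedCore = 20, nMovingCore = 3, nMobile = 0,
                        coreJitterSigma = sigma,
                        rotationPath = rep(0, 2000), seed = 9)
  asm2 <- genAssemblyTrajectory(spec2)
  selA <- selectResidues(asm2$topology, "all", chain = "A")
  r2 <- perResidueRmsf(asm2$trajectory, selA)
  expect_lt(max(abs(r2 - sigma * sqrt(3))) / (sigma * sqrt(3)), 0.05)
})

test_that("rmsf separates rigid and mobile populations and is rigid-transform invariant", {
  spec <- assemblySpec(nFixedCore = 15, nMovingCore = 5, nMobile = 8,
                       coreJitterSigma = 0.2, mobileSigma = 2,
                       rotationPath = rep(0, 60), seed = 4)
  asm <- genAssemblyTrajectory(spec)
  keys <- c(residueKeys(selectResidues(asm$topology, "all", chain = "A")),
            residueKeys(selectResidues(asm$topology, "all", chain = "C")))
  r <- perResidueRmsf(asm$trajectory, keys,
                      alignOn = selectResidues(asm$topology, "all",
                                               chain = "A"))
  rigid <- r[grep("^A:", names(r))]
  mobile <- r[grep("^C:", names(r))]
  expect_lt(max(rigid), min(mobile))  # zero overlap in the ranking

  set.seed(10)
  rT <- perResidueRmsf(transformTrajectory(asm$trajectory, randomRigid()),
                       keys,
                       alignOn = selectResidues(asm$topology, "all",
                                                chain = "A"))
  expect_equal(r, rT, tolerance = 1e-6)
})

test_that("B-factor conversion follows the isotropic convention", {
  expect_equal(bfactorToRmsf(0), 0)
  expect_equal(bfactorToRmsf(8 * pi^2 / 3), 1)
  b <- c(0.5, 1, 5, 20, 80)
  out <- bfactorToRmsf(b)
  expect_true(all(diff(out) > 0))
  expect_equal(out, sqrt(3 * b / (8 * pi^2)))
  expect_error(bfactorToRmsf(-1), ">= 0")
})
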