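## Synthetic ground-truth generators: multi-domain rigid-body assemblies
## with prescribed rotations plus independently mobile peripheral
## residues, overdamped Langevin paths on known landscapes, and PDB
## fixtures.  All generators are deterministic given the same seed.

#' Specification for a synthetic multi-domain assembly
#'
#' Describes a geometric stand-in for a two-subunit assembly: a fixed
#' rigid core (chain A), a moving rigid core (chain B) that rotates about
#' a prescribed axis following `rotationPath`, and independently mobile
#' peripheral residues (chain C) performing unanchored Gaussian random
#' walks.  Core atoms receive isotropic Gaussian jitter of
#' `coreJitterSigma` per axis per frame.  Moving-core atoms snap their
#' axis coordinate to a few discrete levels so that exactly
#' axis-perpendicular P-atom pairs exist, making the prescribed rotation
#' recoverable without projection bias.
#'
#' @param nFixedCore,nMovingCore,nMobile residue counts (> 0; each residue
#'   carries a P and a C1' atom).
#' @param coreJitterSigma Angstrom, per-axis jitter of core atoms
#'   (default 0.2, sub-Angstrom internal fluctuation).
#' @param mobileSigma Angstrom, per-axis random-walk step of mobile
#'   residues (default 3, well separated from the cores).
#' @param rotationPath numeric vector of per-frame angles, degrees; its
#'   length sets the frame count.
#' @param axis rotation axis direction (default z).
#' @param timeStep ns between frames (default 1).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return a list of class `"AssemblySpec"`.
#' @export
assemblySpec <- function(nFixedCore = 25, nMovingCore = 25, nMobile = 20,
                         coreJitterSigma = 0.2, mobileSigma = 3,
                         rotationPath = rep(0, 50), axis = c(0, 0, 1),
                         timeStep = 1, seed) {
  stopifnot(nFixedCore > 0, nMovingCore > 0, nMobile >= 0,
            coreJitterSigma >= 0, mobileSigma >= 0,
            length(rotationPath) >= 1, !missing(seed))
  structure(list(nFixedCore = nFixedCore, nMovingCore = nMovingCore,
                 nMobile = nMobile, coreJitterSigma = coreJitterSigma,
                 mobileSigma = mobileSigma, rotationPath = rotationPath,
                 axis = axis / sqrt(sum(axis^2)), timeStep = timeStep,
                 seed = as.integer(seed)),
            class = "AssemblySpec")
}

## Rodrigues rotation of rows of m about unit axis u through point c
.rotateAbout <- function(m, u, c, angleDeg) {
  th <- angleDeg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(m, 2, c) %*% t(R), 2, c, "+")
}

## orthonormal basis (e1, e2, u) completing a unit axis
.axisBasis <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(.cross3(u, a))
  e2 <- .cross3(u, e1)
  cbind(e1, e2, u)
}

#' Generate a synthetic multi-domain trajectory with known ground truth
#'
#' @param spec an [assemblySpec()].
#' @return list with elements `topology` ([RiboStructure-class], reference
#'   coordinates), `trajectory` ([RiboTrajectory-class]), `classical` and
#'   `rotated` (noiseless endpoint [RiboStructure-class] models at the
#'   path's first and last angle), and `truth` (membership table, per-frame
#'   angle path, axis, rotation centre, and the spec).
#' @examples
#' asm <- genAssemblyTrajectory(assemblySpec(rotationPath = seq(0, 10,
#'   length.out = 20), seed = 1))
#' asm$trajectory
#' @export
genAssemblyTrajectory <- function(spec) {
  stopifnot(inherits(spec, "AssemblySpec"))
  set.seed(spec$seed)
  u <- spec$axis
  Bz <- .axisBasis(u)
  atomOffset <- c(1.1, 0.7, 0.4)  # C1' relative to P within a residue

  baseFor <- function(n, centre, snapAxis) {
    r <- sqrt(stats::runif(n)) * 14
    phi <- stats::runif(n, 0, 2 * pi)
    h <- if (snapAxis) sample(seq(-8, 8, by = 4), n, replace = TRUE)
         else stats::runif(n, -8, 8)
    lat <- cbind(r * cos(phi), r * sin(phi), h)
    sweep(lat %*% t(Bz), 2, centre, "+")
  }
  fixedP <- baseFor(spec$nFixedCore, c(-25, 0, 0), snapAxis = FALSE)
  movCentre <- c(25, 0, 0)
  movP <- baseFor(spec$nMovingCore, movCentre, snapAxis = TRUE)
  mobP <- if (spec$nMobile > 0)
    baseFor(spec$nMobile, c(0, 30, 0), snapAxis = FALSE) else
    matrix(0, 0, 3)

  resBlock <- function(P, chain) {
    n <- nrow(P)
    if (n == 0L) return(NULL)
    data.frame(chain = chain, resno = rep(seq_len(n), each = 2L),
               resid = "U",
               elety = rep(c("P", "C1'"), n),
               x = 0, y = 0, z = 0, b = NA_real_,
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(resBlock(fixedP, "A"), resBlock(movP, "B"),
                 resBlock(mobP, "C"))
  expand <- function(P) {  # P + bonded C1' per residue
    out <- matrix(0, 2 * nrow(P), 3)
    out[seq(1, nrow(out), 2), ] <- P
    out[seq(2, nrow(out), 2), ] <- sweep(P, 2, atomOffset, "+")
    out
  }
  ref <- rbind(expand(fixedP), expand(movP),
               if (nrow(mobP)) expand(mobP))
  atoms$x <- ref[, 1]; atoms$y <- ref[, 2]; atoms$z <- ref[, 3]
  topo <- new("RiboStructure", atoms = atoms, label = "synthetic assembly")

  nF <- length(spec$rotationPath)
  nA <- nrow(ref)
  fixedRows <- seq_len(2L * spec$nFixedCore)
  movRows <- 2L * spec$nFixedCore + seq_len(2L * spec$nMovingCore)
  mobRows <- if (spec$nMobile > 0)
    (2L * (spec$nFixedCore + spec$nMovingCore)) +
      seq_len(2L * spec$nMobile) else integer(0)

  xyz <- matrix(0, nF, 3L * nA)
  mobPos <- ref[mobRows, , drop = FALSE]
  for (f in seq_len(nF)) {
    fr <- ref
    fr[movRows, ] <- .rotateAbout(ref[movRows, , drop = FALSE], u,
                                  movCentre, spec$rotationPath[f])
    coreRows <- c(fixedRows, movRows)
    if (spec$coreJitterSigma > 0)
      fr[coreRows, ] <- fr[coreRows, ] +
        matrix(stats::rnorm(length(coreRows) * 3, 0,
                            spec$coreJitterSigma),
               ncol = 3)
    if (length(mobRows)) {
      if (f > 1L)
        mobPos <- mobPos + matrix(stats::rnorm(length(mobRows) * 3, 0,
                                               spec$mobileSigma),
                                  ncol = 3)
      fr[mobRows, ] <- mobPos
    }
    xyz[f, ] <- as.vector(t(fr))
  }
  traj <- new("RiboTrajectory", topology = topo, xyz = xyz,
              timeStep = spec$timeStep)

  endpoint <- function(angle, label) {
    fr <- ref
    fr[movRows, ] <- .rotateAbout(ref[movRows, , drop = FALSE], u,
                                  movCentre, angle)
    a <- atoms; a$x <- fr[, 1]; a$y <- fr[, 2]; a$z <- fr[, 3]
    new("RiboStructure", atoms = a, label = label)
  }
  membership <- data.frame(
    key = c(.resKey("A", seq_len(spec$nFixedCore)),
            .resKey("B", seq_len(spec$nMovingCore)),
            if (spec$nMobile > 0) .resKey("C", seq_len(spec$nMobile))),
    role = c(rep("fixed_core", spec$nFixedCore),
             rep("moving_core", spec$nMovingCore),
             rep("mobile", spec$nMobile)),
    stringsAsFactors = FALSE)

  list(topology = topo, trajectory = traj,
       classical = endpoint(spec$rotationPath[1], "classical"),
       rotated = endpoint(spec$rotationPath[nF], "rotated"),
       truth = list(membership = membership,
                    angles = spec$rotationPath, axis = u,
                    centre = movCentre, spec = spec))
}

#' Maximum free-energy gradient magnitude of a profile
#' @noRd
.maxGradient <- function(profile) {
  B <- profile@barrier
  wmin <- min(profile@xTs, profile@L - profile@xTs)
  if (profile@family == "piecewise_parabola") 2 * B / wmin
  else 4 * B * (2 / (3 * sqrt(3))) / wmin
}

#' Generate an overdamped Langevin path on a known landscape
#'
#' Euler-Maruyama update `x <- x - D F'(x) dt + sqrt(2 D dt) eta` with F
#' in kT and standard-normal eta, reflecting walls at the domain edges for
#' confined runs.  A step guard rejects time steps for which the
#' deterministic drift per step exceeds a tenth of the thermal step,
#' `D |F'|max dt < 0.1 sqrt(2 D dt)`.
#'
#' @param D diffusion coefficient, units^2 per time unit.
#' @param dt time step.
#' @param nSteps number of steps (the series has `nSteps + 1` points).
#' @param seed integer RNG seed (mandatory).
#' @param profile optional [FreeEnergyProfile-class]; `NULL` for free
#'   (flat, unbounded) diffusion.
#' @param harmonic optional `list(kappa =, centre =)` for an unbounded
#'   harmonic well `F = kappa (x - centre)^2 / 2` (kT); mutually
#'   exclusive with `profile`.  Its Boltzmann stationary variance is
#'   `1 / kappa`.
#' @param x0 starting position (default: mid-domain, well centre, or 0
#'   when free).
#' @param label,units stored on the returned series.
#' @return list with `series` (an [AngleSeries-class]) and `truth` (the
#'   generating parameters).
#' @examples
#' g <- genLangevin(D = 1, dt = 0.1, nSteps = 1000, seed = 42)
#' g$series
#' @export
genLangevin <- function(D, dt, nSteps, seed, profile = NULL,
                        harmonic = NULL, x0 = NULL, label = "langevin",
                        units = "units") {
  stopifnot(D > 0, dt > 0, nSteps >= 1, !missing(seed))
  if (!is.null(profile) && !is.null(harmonic))
    stop("give either a profile or a harmonic well, not both")
  if (!is.null(harmonic)) {
    fam <- 3L; L <- Inf; xts <- harmonic$centre; B <- harmonic$kappa
    if (is.null(x0)) x0 <- harmonic$centre
    reflect <- FALSE
    if (D * B * dt >= 0.2)  # relaxation must be resolved
      stop("time step too large for this well stiffness: reduce dt")
  } else if (is.null(profile)) {
    fam <- 0L; L <- Inf; xts <- 1; B <- 0
    if (is.null(x0)) x0 <- 0
    reflect <- FALSE
  } else {
    stopifnot(is(profile, "FreeEnergyProfile"))
    fam <- match(profile@family,
                 c("piecewise_parabola", "quartic_smooth"))
    L <- profile@L; xts <- profile@xTs; B <- profile@barrier
    if (is.null(x0)) x0 <- L / 2
    reflect <- TRUE
    gmax <- .maxGradient(profile)
    if (D * gmax * dt >= 0.1 * sqrt(2 * D * dt))
      stop("time step too large for this landscape: reduce dt so that ",
           "D |F'| dt < 0.1 sqrt(2 D dt)")
  }
  set.seed(seed)
  vals <- cpp_langevin_path(x0, as.integer(nSteps), dt, D, fam, L, xts,
                            B, reflect)
  list(series = new("AngleSeries", label = label,
                    times = dt * (0:nSteps), values = vals,
                    units = units),
       truth = list(D = D, dt = dt, nSteps = nSteps, seed = seed,
                    profile = profile, harmonic = harmonic, x0 = x0))
}

#' Sample first-passage times on a free-energy profile
#'
#' Simulates independent overdamped Langevin passages from `x0`
#' (reflecting wall at 0) to the absorbing boundary at `L` and returns the
#' passage times; their mean is the empirical MFPT matched against
#' [mfpt()].
#'
#' @param profile a [FreeEnergyProfile-class].
#' @param D diffusion coefficient.
#' @param n number of passages.
#' @param dt time step (guarded as in [genLangevin()]).
#' @param seed integer RNG seed.
#' @param x0 starting position (default 0, the initial minimum).
#' @param maxSteps per-passage step cap; exceeding it yields `NA`.
#' @return numeric vector of passage times (length n).
#' @export
firstPassageTimes <- function(profile, D, n, dt, seed, x0 = 0,
                              maxSteps = 1e9) {
  stopifnot(is(profile, "FreeEnergyProfile"), D > 0, n >= 1, dt > 0,
            !missing(seed))
  gmax <- .maxGradient(profile)
  if (D * gmax * dt >= 0.1 * sqrt(2 * D * dt))
    stop("time step too large for this landscape; reduce dt")
  fam <- match(profile@family, c("piecewise_parabola", "quartic_smooth"))
  set.seed(seed)
  cpp_first_passage(as.integer(n), x0, dt, D, fam, profile@L,
                    profile@xTs, profile@barrier, maxSteps)
}

#' Write a trajectory frame (or structure) as a PDB fixture
#'
#' Produces a parseable PDB snapshot that round-trips through
#' [readStructure()] at PDB coordinate precision (1e-3 Angstrom).  Output
#' is byte-deterministic for identical inputs.
#'
#' @param x a `genAssemblyTrajectory()` result list, a
#'   [RiboTrajectory-class], or a [RiboStructure-class].
#' @param frame frame index (ignored for a structure).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFixturePdb <- function(x, frame = 1L, path) {
  if (is.list(x) && !isS4(x)) x <- x$trajectory
  if (is(x, "RiboTrajectory")) {
    topo <- x@topology
    co <- frameCoords(x, frame)
  } else {
    stopifnot(is(x, "RiboStructure"))
    topo <- x
    co <- frameCoords(x)
  }
  a <- atomTable(topo)
  bio3d::write.pdb(file = path, xyz = as.vector(t(co)),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety,
                   b = ifelse(is.na(a$b), 0, a$b))
  invisible(path)
}
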