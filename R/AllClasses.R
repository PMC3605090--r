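#' @import methods
NULL

#' Static structural model
#'
#' Container for a single structural model: an ordered table of atoms with
#' chain identifiers, residue numbers and names, atom names, Cartesian
#' coordinates in Angstrom and (optionally) isotropic B-factors.  Atom order
#' is preserved from the source file and is the frame convention used by
#' [RiboTrajectory-class] objects built on the same topology.
#'
#' @slot atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`, `b` (B-factor, `NA` when absent).
#' @slot label character scalar naming the model.
#' @seealso [readStructure()], [selectResidues()]
#' @export
setClass("RiboStructure",
  representation(atoms = "data.frame", label = "character"),
  validity = function(object) {
    a <- object@atoms
    need <- c("chain", "resno", "resid", "elety", "x", "y", "z", "b")
    if (!all(need %in% names(a)))
      return(paste("atoms must have columns:", paste(need, collapse = ", ")))
    if (nrow(a) == 0L) return("structure has no atoms")
    if (!all(is.finite(a$x)) || !all(is.finite(a$y)) || !all(is.finite(a$z)))
      return("non-finite coordinates")
    TRUE
  })

#' Conformational trajectory on a fixed topology
#'
#' Frames are stored row-wise in the bio3d `xyz` convention: row `i` holds
#' the flattened coordinates `(x1, y1, z1, x2, ...)` of frame `i`, congruent
#' with the atom ordering of the topology.  Frames are uniformly spaced in
#' time; non-uniform trajectories are rejected at construction.
#'
#' @slot topology a [RiboStructure-class] defining atom identities.
#' @slot xyz numeric matrix, `nFrames` x `3 * nAtoms`.
#' @slot timeStep numeric, ns between stored frames (> 0).
#' @export
setClass("RiboTrajectory",
  representation(topology = "RiboStructure", xyz = "matrix",
                 timeStep = "numeric"),
  validity = function(object) {
    if (length(object@timeStep) != 1L || !is.finite(object@timeStep) ||
        object@timeStep <= 0)
      return("timeStep must be a single positive number (ns)")
    if (ncol(object@xyz) != 3L * nrow(object@topology@atoms))
      return("frame width does not match topology atom count")
    if (nrow(object@xyz) < 1L) return("trajectory has no frames")
    TRUE
  })

#' Resolved residue selection
#'
#' @slot ranges data.frame with columns `chain`, `start`, `end`
#'   (inclusive 1-based residue numbers), or zero rows for "all".
#' @slot keys character vector of resolved residue keys, `"chain:resno"`.
#' @slot label character scalar.
#' @export
setClass("ResidueSelection",
  representation(ranges = "data.frame", keys = "character",
                 label = "character"),
  validity = function(object) {
    if (anyDuplicated(object@keys)) return("duplicate residue keys")
    if (length(object@keys) == 0L) return("empty selection")
    TRUE
  })

#' Least-squares rigid superposition result
#'
#' The transform maps mobile coordinates onto the reference:
#' `y = x R' + t` (rowwise).  The rotation is proper (`det = +1`);
#' reflections are never returned.
#'
#' @slot rotation 3x3 orthonormal matrix, det +1.
#' @slot translation length-3 numeric, Angstrom.
#' @slot rmsd numeric, Angstrom, of the fitted mobile set onto the reference.
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric"),
  validity = function(object) {
    if (!all(dim(object@rotation) == c(3L, 3L))) return("rotation must be 3x3")
    if (abs(det(object@rotation) - 1) > 1e-6)
      return("rotation must be proper (det = +1)")
    if (object@rmsd < 0) return("rmsd must be >= 0")
    TRUE
  })

#' Converged rigid-core residue set
#'
#' Result of the iterative-exclusion algorithm: the residues of a candidate
#' region whose internal RMSF, after self-alignment of the surviving set,
#' is below the final threshold of the schedule.
#'
#' @slot regionLabel character, e.g. `"50S"`, `"30S-body"`, `"30S-head"`.
#' @slot members character vector of residue keys.
#' @slot finalRmsf named numeric, Angstrom, one value per member.
#' @slot iterationLog data.frame with columns `threshold`, `pass`,
#'   `n_removed`, `n_remaining`.
#' @export
setClass("CoreSet",
  representation(regionLabel = "character", members = "character",
                 finalRmsf = "numeric", iterationLog = "data.frame"),
  validity = function(object) {
    if (!all(names(object@finalRmsf) %in% object@members) ||
        length(object@finalRmsf) != length(object@members))
      return("finalRmsf must be named by members")
    TRUE
  })

#' Collective rotation coordinate definition
#'
#' Defines a signed rotation angle from two endpoint models: the fixed core
#' supplies the frame of reference, the moving core is idealized (replaced
#' by its rigidly fitted reference configuration) in every frame, and the
#' angle is measured by projecting the maximal-change P-atom pair vector
#' into the rotation plane.  Counter-clockwise rotation about `planeNormal`
#' is positive.
#'
#' @slot label coordinate name, e.g. `"theta_body"`.
#' @slot fixedIdx integer atom indices (topology order) of the fixed core.
#' @slot movingIdx integer atom indices of the moving core (heavy atoms).
#' @slot fixedRef matrix, reference coordinates of the fixed core.
#' @slot movingRef matrix, idealized reference coordinates of the moving
#'   core expressed in the fixed-core frame (classical model).
#' @slot pairRows integer length 2, rows of `movingRef` giving the P-atom
#'   pair with maximal angle change.
#' @slot pairKeys character length 2, atom keys of the pair.
#' @slot planeNormal unit 3-vector, rotation-plane normal.
#' @slot referenceVector unit 3-vector in the plane (classical orientation).
#' @slot maxAngleChange numeric, degrees, the endpoint-to-endpoint change.
#' @export
setClass("RotationAxis",
  representation(label = "character", fixedIdx = "integer",
                 movingIdx = "integer", fixedRef = "matrix",
                 movingRef = "matrix", pairRows = "integer",
                 pairKeys = "character", planeNormal = "numeric",
                 referenceVector = "numeric", maxAngleChange = "numeric"),
  validity = function(object) {
    n <- object@planeNormal; v <- object@referenceVector
    if (abs(sqrt(sum(n^2)) - 1) > 1e-10) return("planeNormal not unit length")
    if (abs(sqrt(sum(v^2)) - 1) > 1e-10)
      return("referenceVector not unit length")
    if (abs(sum(n * v)) > 1e-10)
      return("referenceVector not perpendicular to planeNormal")
    TRUE
  })

#' Landmark centroid-distance coordinate definition
#'
#' A scalar coordinate measuring the Euclidean distance between the
#' centroids of two atom selections (e.g. a tRNA elbow landmark against a
#' ribosomal reference group).
#'
#' @slot label coordinate name.
#' @slot idxA,idxB integer atom indices of the two selections.
#' @export
setClass("LandmarkDistance",
  representation(label = "character", idxA = "integer", idxB = "integer"),
  validity = function(object) {
    if (length(object@idxA) == 0L || length(object@idxB) == 0L)
      return("empty landmark selection")
    TRUE
  })

#' Time series of one collective coordinate
#'
#' @slot label coordinate name.
#' @slot times numeric, ns, strictly increasing, uniform.
#' @slot values numeric, degrees or Angstrom.
#' @slot units `"degrees"` or `"angstrom"` (or other scalar unit).
#' @export
setClass("AngleSeries",
  representation(label = "character", times = "numeric", values = "numeric",
                 units = "character"),
  validity = function(object) {
    if (length(object@times) != length(object@values))
      return("times and values differ in length")
    if (length(object@times) >= 2L) {
      d <- diff(object@times)
      if (any(d <= 0)) return("times must be strictly increasing")
      if (max(abs(d - d[1])) > 1e-6 * max(d[1], 1))
        return("times must be uniformly spaced")
    }
    TRUE
  })

#' Mean-squared displacement curve
#'
#' @slot lags numeric, ns, strictly increasing, starting at 0.
#' @slot msd numeric, squared coordinate units.
#' @slot nPairs integer, frame pairs contributing to each lag.
#' @slot units character, units of the underlying coordinate.
#' @export
setClass("MSDCurve",
  representation(lags = "numeric", msd = "numeric", nPairs = "integer",
                 units = "character"),
  validity = function(object) {
    if (length(object@lags) != length(object@msd)) return("length mismatch")
    if (any(diff(object@lags) <= 0)) return("lags must be strictly increasing")
    if (object@lags[1] == 0 && abs(object@msd[1]) > 0)
      return("msd at zero lag must be 0")
    TRUE
  })

#' Effective diffusion estimate from an MSD fit
#'
#' One-dimensional convention: `msd = 2 D tau`, so `D = slope / 2`.
#'
#' @slot D numeric, squared coordinate units per ns (floored at 0).
#' @slot tauMin,tauMax fit window bounds, ns.
#' @slot slope,intercept ordinary least-squares line over the window.
#' @slot corrCoeff linear correlation coefficient over the window.
#' @slot flags character vector of quality flags (may be empty): e.g.
#'   `"negative_slope"`, `"non_diffusive_curvature"`, `"low_correlation"`.
#' @export
setClass("DiffusionEstimate",
  representation(D = "numeric", tauMin = "numeric", tauMax = "numeric",
                 slope = "numeric", intercept = "numeric",
                 corrCoeff = "numeric", flags = "character"),
  validity = function(object) {
    if (object@D < 0) return("D must be >= 0")
    if (!is.na(object@corrCoeff) &&
        (object@corrCoeff < -1 || object@corrCoeff > 1))
      return("corrCoeff outside [-1, 1]")
    TRUE
  })

#' Energetic roughness estimate
#'
#' Scale of short-length-scale energy fluctuations inferred from the
#' attenuation of effective relative to free diffusion,
#' `D_eff = D_free * exp(-(epsilon/kT)^2)`.
#'
#' @slot epsilonKT roughness in kT units (>= 0).
#' @slot epsilonKcal roughness in kcal/mol at the stated temperature.
#' @slot dEff,dFree the two diffusion coefficients (same units).
#' @slot temperature Kelvin.
#' @export
setClass("RoughnessEstimate",
  representation(epsilonKT = "numeric", epsilonKcal = "numeric",
                 dEff = "numeric", dFree = "numeric",
                 temperature = "numeric"),
  validity = function(object) {
    if (object@epsilonKT < 0) return("epsilon must be >= 0")
    TRUE
  })

#' Linear drift estimate over a time window
#'
#' @slot window numeric length 2, (t_start, t_end) ns.
#' @slot slope numeric, coordinate units per microsecond.
#' @slot intercept numeric.
#' @export
setClass("DriftEstimate",
  representation(window = "numeric", slope = "numeric",
                 intercept = "numeric"))

#' Parameterized one-dimensional free-energy profile
#'
#' Barrier shape on `[0, L]` with endpoint minima at zero free energy and a
#' single transition state of height `barrier` (kT) at `xTs`.  Two families:
#' `"piecewise_parabola"` joins two inverted parabolas at the peak;
#' `"quartic_smooth"` is a double-well quartic rescaled to the same three
#' constraints, with zero-slope endpoint minima.
#'
#' @slot L domain length, coordinate units (degrees or Angstrom).
#' @slot xTs transition-state position, in (0, L).
#' @slot barrier barrier height, kT.
#' @slot family `"piecewise_parabola"` or `"quartic_smooth"`.
#' @export
setClass("FreeEnergyProfile",
  representation(L = "numeric", xTs = "numeric", barrier = "numeric",
                 family = "character"),
  validity = function(object) {
    if (object@L <= 0) return("L must be > 0")
    if (object@xTs <= 0 || object@xTs >= object@L)
      return("xTs must lie strictly inside (0, L)")
    if (object@barrier < 0) return("barrier must be >= 0")
    if (!object@family %in% c("piecewise_parabola", "quartic_smooth"))
      return("unknown profile family")
    TRUE
  })

#' Rate versus barrier-height curve
#'
#' @slot barriers numeric grid, kT.
#' @slot rates numeric, reciprocal time units of `D / L^2`.
#' @slot D,L,xTs geometry and diffusion used.
#' @slot family profile family used.
#' @export
setClass("RateBarrierCurve",
  representation(barriers = "numeric", rates = "numeric", D = "numeric",
                 L = "numeric", xTs = "numeric", family = "character"),
  validity = function(object) {
    if (length(object@barriers) != length(object@rates))
      return("length mismatch")
    if (any(diff(object@rates) >= 0))
      return("rates must be strictly decreasing in barrier")
    TRUE
  })

#' Barrier-crossing attempt frequency
#'
#' Prefactor of `k = nu * exp(-barrier)` fitted with slope constrained to
#' -1 per kT over a high-barrier range.
#'
#' @slot nu attempt frequency, reciprocal time units.
#' @slot fitRange numeric length 2, barrier range used, kT.
#' @slot residualRMS RMS residual of the constrained fit, ln units.
#' @export
setClass("AttemptFrequency",
  representation(nu = "numeric", fitRange = "numeric",
                 residualRMS = "numeric"),
  validity = function(object) {
    if (object@nu <= 0) return("nu must be > 0")
    TRUE
  })
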