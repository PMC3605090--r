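## Collective rotation coordinates: idealization of rigid cores,
## maximal-rotation atom-pair search, signed angle evaluation, landmark
## distances and per-frame series.

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

.unit <- function(v) v / sqrt(sum(v^2))

#' Idealize a core: replace observed coordinates by the fitted reference
#'
#' Rigidly superposes the reference core configuration onto the observed
#' core coordinates of a frame and returns the transformed reference.  The
#' result carries the frame's average orientation of the core while
#' discarding internal fluctuations: its internal geometry is exactly that
#' of the reference.
#'
#' @param frameCoords observed core coordinates, n x 3, row order matching
#'   `referenceCoords`.
#' @param referenceCoords reference core coordinates, n x 3.
#' @return n x 3 matrix: the reference rigidly fitted onto the frame.
#' @export
idealizeCore <- function(frameCoords, referenceCoords) {
  tr <- superpose(referenceCoords, frameCoords)
  applyTransform(referenceCoords, tr)
}

## angle (degrees) between two 3-vectors
.vecAngle <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}

#' Define a rotation coordinate from two endpoint models
#'
#' Both models are first expressed in the fixed-core frame (the rotated
#' model is superposed onto the classical one over the fixed core), and the
#' moving core of the rotated model is idealized against the classical
#' moving-core configuration.  Every unordered pair of P atoms in the
#' moving core is then scored by the angle between its vector in the two
#' idealized configurations; the maximizing pair defines the rotation
#' plane (normal = unit cross product of the two orientations) and the
#' reference direction (the classical orientation projected into the
#' plane).  Ties are broken by larger inter-atom distance, then
#' lexicographic atom key (a message is emitted when this applies).
#'
#' @param classical,rotated [RiboStructure-class] endpoint models on the
#'   same topology (congruent atom ordering).
#' @param movingCore,fixedCore [CoreSet-class] objects (or character
#'   residue-key vectors) for the rotating and reference regions.
#' @param label coordinate label stored on the result.
#' @return a [RotationAxis-class]; evaluate with [computeAngle()].
#' @export
findMaxRotationPair <- function(classical, rotated, movingCore, fixedCore,
                                label = "theta") {
  mKeys <- if (is.character(movingCore)) movingCore else members(movingCore)
  fKeys <- if (is.character(fixedCore)) fixedCore else members(fixedCore)
  a <- atomTable(classical)
  fixedIdx <- .atomIndices(classical, fKeys, heavyOnly = TRUE)
  movingIdx <- .atomIndices(classical, mKeys, heavyOnly = TRUE)
  cc <- frameCoords(classical); rc <- frameCoords(rotated)

  fixedRef <- cc[fixedIdx, , drop = FALSE]
  trFix <- superpose(rc[fixedIdx, , drop = FALSE], fixedRef)
  rcMov <- applyTransform(rc[movingIdx, , drop = FALSE], trFix)

  movingRef <- cc[movingIdx, , drop = FALSE]
  idealRot <- idealizeCore(rcMov, movingRef)

  pRows <- which(a$elety[movingIdx] == "P")
  if (length(pRows) < 2L)
    stop("moving core must contain at least two P atoms")
  atomKey <- paste0(a$chain[movingIdx], ":", a$resno[movingIdx], ":",
                    a$elety[movingIdx])

  pairs <- utils::combn(pRows, 2L)
  nP <- ncol(pairs)
  ang <- dist <- numeric(nP)
  for (j in seq_len(nP)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    vC <- movingRef[i2, ] - movingRef[i1, ]
    vR <- idealRot[i2, ] - idealRot[i1, ]
    ang[j] <- .vecAngle(vC, vR)
    dist[j] <- sqrt(sum(vC^2))
  }
  if (max(ang) < 1e-3)
    stop("no rotation detected: endpoint models are indistinguishable")
  best <- which(ang > max(ang) - 1e-9)
  if (length(best) > 1L) {
    message("rotation-pair tie among ", length(best),
            " pairs; breaking by distance then atom key")
    keyA <- atomKey[pairs[1, best]]; keyB <- atomKey[pairs[2, best]]
    best <- best[order(-dist[best], keyA, keyB)]
  }
  win <- best[1]
  i1 <- pairs[1, win]; i2 <- pairs[2, win]
  vC <- movingRef[i2, ] - movingRef[i1, ]
  vR <- idealRot[i2, ] - idealRot[i1, ]
  n <- .unit(.cross3(vC, vR))
  refVec <- .unit(vC - sum(vC * n) * n)
  new("RotationAxis", label = label, fixedIdx = fixedIdx,
      movingIdx = movingIdx, fixedRef = fixedRef, movingRef = movingRef,
      pairRows = c(i1, i2), pairKeys = atomKey[c(i1, i2)],
      planeNormal = n, referenceVector = refVec,
      maxAngleChange = ang[win])
}

#' Evaluate a rotation coordinate for one frame
#'
#' The frame is superposed onto the fixed-core reference (removing global
#' motion), the moving core is idealized, and the signed angle between the
#' in-plane projection of the winning pair vector and the reference
#' direction is returned.  Counter-clockwise rotation viewed down the
#' plane normal is positive.  The result is invariant under any global
#' proper rigid transform of the input frame.
#'
#' @param frame full-topology coordinates: an `nAtoms` x 3 matrix, a
#'   [RiboStructure-class], or a [RiboTrajectory-class] plus frame index
#'   via `i`.
#' @param axis a [RotationAxis-class].
#' @param i frame index when `frame` is a trajectory.
#' @return signed angle in degrees.
#' @export
computeAngle <- function(frame, axis, i = 1L) {
  xyz <- if (is(frame, "RiboTrajectory")) frameCoords(frame, i)
         else if (is(frame, "RiboStructure")) frameCoords(frame)
         else as.matrix(frame)
  trFix <- superpose(xyz[axis@fixedIdx, , drop = FALSE], axis@fixedRef)
  mov <- applyTransform(xyz[axis@movingIdx, , drop = FALSE], trFix)
  ideal <- idealizeCore(mov, axis@movingRef)
  v <- ideal[axis@pairRows[2], ] - ideal[axis@pairRows[1], ]
  n <- axis@planeNormal
  vp <- v - sum(v * n) * n
  if (sqrt(sum(vp^2)) < 1e-6 * sqrt(sum(v^2)))
    stop("pair vector parallel to rotation axis; angle undefined")
  r <- axis@referenceVector
  atan2(sum(.cross3(r, vp) * n), sum(r * vp)) * 180 / pi
}

#' Define a landmark centroid-distance coordinate
#'
#' @param structure topology [RiboStructure-class] used to resolve
#'   selections.
#' @param selectionA,selectionB [ResidueSelection-class] objects or residue
#'   key vectors; reduced by centroid over their (heavy) atoms.
#' @param label coordinate label, e.g. `"R_elbow"`.  Note the tRNA elbow
#'   distance shipped in examples is a configurable stand-in: the atom
#'   selections defining it must be supplied by the user from an external
#'   definition.
#' @param heavyOnly restrict to non-hydrogen atoms.
#' @return a [LandmarkDistance-class].
#' @export
landmarkDefinition <- function(structure, selectionA, selectionB,
                               label = "distance", heavyOnly = TRUE) {
  new("LandmarkDistance", label = label,
      idxA = .atomIndices(structure, selectionA, heavyOnly),
      idxB = .atomIndices(structure, selectionB, heavyOnly))
}

#' Evaluate a landmark centroid distance for one frame
#'
#' @inheritParams computeAngle
#' @param def a [LandmarkDistance-class].
#' @return distance in Angstrom.
#' @export
landmarkDistance <- function(frame, def, i = 1L) {
  xyz <- if (is(frame, "RiboTrajectory")) frameCoords(frame, i)
         else if (is(frame, "RiboStructure")) frameCoords(frame)
         else as.matrix(frame)
  ca <- colMeans(xyz[def@idxA, , drop = FALSE])
  cb <- colMeans(xyz[def@idxB, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' Evaluate a coordinate over every frame of a trajectory
#'
#' @param trajectory a [RiboTrajectory-class].
#' @param coordinate a [RotationAxis-class] or [LandmarkDistance-class].
#' @param stride evaluate every `stride`-th frame (default 1).
#' @return an [AngleSeries-class] with times in ns carried from the
#'   trajectory.
#' @export
angleSeries <- function(trajectory, coordinate, stride = 1L) {
  idx <- seq(1L, nFrames(trajectory), by = stride)
  isAngle <- is(coordinate, "RotationAxis")
  vals <- vapply(idx, function(i) {
    if (isAngle) computeAngle(trajectory, coordinate, i = i)
    else landmarkDistance(trajectory, coordinate, i = i)
  }, numeric(1))
  new("AngleSeries", label = coordinate@label,
      times = (idx - 1L) * timeStep(trajectory), values = vals,
      units = if (isAngle) "degrees" else "angstrom")
}
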