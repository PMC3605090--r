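#' @rdname RiboStructure-class
#' @param object,x an object.
#' @export
setGeneric("atomTable", function(object) standardGeneric("atomTable"))

#' @rdname RiboStructure-class
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))

#' @rdname RiboTrajectory-class
#' @param object an object.
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname RiboTrajectory-class
#' @export
setGeneric("timeStep", function(object) standardGeneric("timeStep"))

#' Extract one frame's coordinates
#'
#' @param object a [RiboTrajectory-class] or [RiboStructure-class].
#' @param i frame index (ignored for a static structure).
#' @return numeric matrix, `nAtoms` x 3, Angstrom.
#' @export
setGeneric("frameCoords", function(object, i = 1L)
  standardGeneric("frameCoords"))

#' @rdname ResidueSelection-class
#' @param object an object.
#' @export
setGeneric("residueKeys", function(object) standardGeneric("residueKeys"))

#' @rdname CoreSet-class
#' @param object an object.
#' @export
setGeneric("members", function(object) standardGeneric("members"))

#' @rdname CoreSet-class
#' @export
setGeneric("finalRmsf", function(object) standardGeneric("finalRmsf"))

#' @rdname CoreSet-class
#' @export
setGeneric("iterationLog", function(object) standardGeneric("iterationLog"))

#' @rdname DiffusionEstimate-class
#' @param object an object.
#' @export
setGeneric("diffusionCoefficient", function(object)
  standardGeneric("diffusionCoefficient"))

#' Evaluate a free-energy profile
#'
#' @param profile a [FreeEnergyProfile-class].
#' @param x numeric vector of positions in `[0, L]`.
#' @return `profileEnergy`: free energy in kT; `profileGradient`: dF/dx in
#'   kT per coordinate unit.
#' @export
setGeneric("profileEnergy", function(profile, x)
  standardGeneric("profileEnergy"))

#' @rdname profileEnergy
#' @export
setGeneric("profileGradient", function(profile, x)
  standardGeneric("profileGradient"))

## -- accessors ---------------------------------------------------------------

#' @rdname RiboStructure-class
#' @export
setMethod("atomTable", "RiboStructure", function(object) object@atoms)

#' @rdname RiboStructure-class
#' @export
setMethod("nAtoms", "RiboStructure", function(object) nrow(object@atoms))

#' @rdname RiboTrajectory-class
#' @export
setMethod("nAtoms", "RiboTrajectory",
          function(object) nrow(object@topology@atoms))

#' @rdname RiboTrajectory-class
#' @export
setMethod("nFrames", "RiboTrajectory", function(object) nrow(object@xyz))

#' @rdname RiboTrajectory-class
#' @export
setMethod("timeStep", "RiboTrajectory", function(object) object@timeStep)

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "RiboTrajectory", function(object, i = 1L) {
  stopifnot(i >= 1L, i <= nrow(object@xyz))
  matrix(object@xyz[i, ], ncol = 3L, byrow = TRUE)
})

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "RiboStructure", function(object, i = 1L) {
  as.matrix(object@atoms[, c("x", "y", "z")])
})

#' @rdname ResidueSelection-class
#' @export
setMethod("residueKeys", "ResidueSelection", function(object) object@keys)

#' @rdname RiboStructure-class
#' @export
setMethod("residueKeys", "RiboStructure", function(object) {
  unique(paste(object@atoms$chain, object@atoms$resno, sep = ":"))
})

#' @rdname CoreSet-class
#' @export
setMethod("members", "CoreSet", function(object) object@members)

#' @rdname CoreSet-class
#' @export
setMethod("finalRmsf", "CoreSet", function(object) object@finalRmsf)

#' @rdname CoreSet-class
#' @export
setMethod("iterationLog", "CoreSet", function(object) object@iterationLog)

#' @rdname DiffusionEstimate-class
#' @export
setMethod("diffusionCoefficient", "DiffusionEstimate",
          function(object) object@D)

## -- show methods ------------------------------------------------------------

setMethod("show", "RiboStructure", function(object) {
  a <- object@atoms
  cat("RiboStructure \"", object@label, "\": ", nrow(a), " atoms, ",
      length(unique(paste(a$chain, a$resno))), " residues, ",
      length(unique(a$chain)), " chain(s)\n", sep = "")
})

setMethod("show", "RiboTrajectory", function(object) {
  cat("RiboTrajectory: ", nrow(object@xyz), " frames x ", nAtoms(object),
      " atoms, dt = ", object@timeStep, " ns\n", sep = "")
})

setMethod("show", "ResidueSelection", function(object) {
  cat("ResidueSelection \"", object@label, "\": ", length(object@keys),
      " residues\n", sep = "")
})

setMethod("show", "CoreSet", function(object) {
  cat("CoreSet \"", object@regionLabel, "\": ", length(object@members),
      " core residues, max rmsf ",
      format(max(object@finalRmsf), digits = 3), " A (",
      nrow(object@iterationLog), " rmsf passes)\n", sep = "")
})

setMethod("show", "RotationAxis", function(object) {
  cat("RotationAxis \"", object@label, "\": pair ",
      paste(object@pairKeys, collapse = " - "),
      ", endpoint change ", format(object@maxAngleChange, digits = 4),
      " deg\n", sep = "")
})

setMethod("show", "AngleSeries", function(object) {
  cat("AngleSeries \"", object@label, "\": ", length(object@values),
      " points, t in [", min(object@times), ", ", max(object@times),
      "] ns, ", object@units, "\n", sep = "")
})

setMethod("show", "DiffusionEstimate", function(object) {
  cat("DiffusionEstimate: D = ", format(object@D, digits = 4),
      " units^2/ns over [", object@tauMin, ", ", object@tauMax,
      "] ns, c.c. = ", format(object@corrCoeff, digits = 3), sep = "")
  if (length(object@flags)) cat(" [", paste(object@flags, collapse = ", "),
                                "]", sep = "")
  cat("\n")
})

setMethod("show", "FreeEnergyProfile", function(object) {
  cat("FreeEnergyProfile (", object@family, "): L = ", object@L,
      ", peak ", object@barrier, " kT at x = ", object@xTs, "\n", sep = "")
})

setMethod("show", "RateBarrierCurve", function(object) {
  cat("RateBarrierCurve: ", length(object@barriers),
      " barriers in [", min(object@barriers), ", ", max(object@barriers),
      "] kT, D = ", object@D, ", L = ", object@L, "\n", sep = "")
})

setMethod("show", "RoughnessEstimate", function(object) {
  cat("RoughnessEstimate: epsilon = ",
      format(object@epsilonKT, digits = 4), " kT (",
      format(object@epsilonKcal, digits = 4), " kcal/mol at ",
      object@temperature, " K)\n", sep = "")
})
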