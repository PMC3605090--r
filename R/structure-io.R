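## Structure and trajectory input, residue selection, superposition and
## per-residue fluctuation statistics.

.resKey <- function(chain, resno) paste(chain, resno, sep = ":")

.isHydrogen <- function(elety) grepl("^[0-9]*H", elety)

#' Read a structural model from a PDB file
#'
#' Parses ATOM/HETATM records via \pkg{bio3d} and returns a
#' [RiboStructure-class] with atoms in file order.  Hydrogens are retained;
#' operations that work on heavy atoms only take a `heavyOnly` flag instead.
#' Alternate-location ambiguity is rejected with an error rather than
#' silently resolved.
#'
#' @param path path to a PDB file.
#' @param label optional model label (defaults to the file name).
#' @return a [RiboStructure-class].
#' @examples
#' spec <- assemblySpec(nFixedCore = 4, nMovingCore = 4, nMobile = 2,
#'                      rotationPath = c(0, 5), seed = 1)
#' asm <- genAssemblyTrajectory(spec)
#' f <- tempfile(fileext = ".pdb")
#' writeFixturePdb(asm, 1, f)
#' readStructure(f)
#' @export
readStructure <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("PDB parse error in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty model in '", path, "'")
  alt <- a$alt
  if (!is.null(alt) && any(!is.na(alt) & !alt %in% c("", "A")))
    stop("alternate locations present in '", path,
         "'; ambiguous models are not supported")
  b <- suppressWarnings(as.numeric(a$b))
  new("RiboStructure",
      atoms = data.frame(chain = as.character(a$chain),
                         resno = as.integer(a$resno),
                         resid = as.character(a$resid),
                         elety = as.character(a$elety),
                         x = a$x, y = a$y, z = a$z,
                         b = b, stringsAsFactors = FALSE),
      label = label)
}

#' Read a multi-model PDB as a trajectory
#'
#' Each MODEL block becomes one frame on the topology of the first model.
#' Frames are assumed uniformly spaced at `timeStep` ns.
#'
#' @param path path to a multi-model PDB file.
#' @param timeStep ns between frames (> 0).
#' @return a [RiboTrajectory-class].
#' @export
readTrajectory <- function(path, timeStep = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("PDB parse error in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  topo <- readStructure(path)
  xyz <- unclass(pdb$xyz)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  new("RiboTrajectory", topology = topo, xyz = xyz, timeStep = timeStep)
}

#' Construct a trajectory from in-memory frames
#'
#' @param topology a [RiboStructure-class].
#' @param frames list of `nAtoms` x 3 coordinate matrices, or an
#'   `nFrames` x `3 nAtoms` matrix in xyz layout.
#' @param timeStep ns between frames.
#' @return a [RiboTrajectory-class].
#' @export
makeTrajectory <- function(topology, frames, timeStep = 1) {
  if (is.list(frames))
    frames <- do.call(rbind, lapply(frames, function(m) as.vector(t(m))))
  new("RiboTrajectory", topology = topology, xyz = frames,
      timeStep = timeStep)
}

#' Select residues by inclusive number ranges
#'
#' Ranges follow PDB residue numbering, inclusive on both ends, e.g.
#' `"5-920,1397-1540"`; `"all"` selects every residue of the chain.  Order
#' of ranges does not matter.  Every residue number in a requested range
#' must exist in the chain.
#'
#' @param structure a [RiboStructure-class].
#' @param spec range specification text, `"start-end[,start-end...]"` or
#'   `"all"`; single residues may be given as a bare number.
#' @param chain chain identifier (defaults to the first chain).
#' @param label selection label.
#' @return a [ResidueSelection-class].
#' @export
selectResidues <- function(structure, spec, chain = NULL,
                           label = spec) {
  a <- atomTable(structure)
  if (is.null(chain)) chain <- a$chain[1]
  present <- sort(unique(a$resno[a$chain == chain]))
  if (length(present) == 0L) stop("no residues in chain '", chain, "'")
  spec <- gsub("[[:space:]]", "", spec)
  if (identical(tolower(spec), "all")) {
    keys <- .resKey(chain, present)
    ranges <- data.frame(chain = chain, start = min(present),
                         end = max(present), stringsAsFactors = FALSE)
    return(new("ResidueSelection", ranges = ranges, keys = keys,
               label = label))
  }
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  resnos <- integer(0)
  ranges <- data.frame(chain = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  for (p in parts) {
    ends <- suppressWarnings(as.integer(strsplit(p, "-", fixed = TRUE)[[1]]))
    if (any(is.na(ends)) || !length(ends) %in% c(1L, 2L))
      stop("malformed range: '", p, "'")
    if (length(ends) == 1L) ends <- c(ends, ends)
    if (ends[2] < ends[1]) stop("reversed range: '", p, "'")
    want <- seq.int(ends[1], ends[2])
    missing <- setdiff(want, present)
    if (length(missing))
      stop("missing residues in chain '", chain, "': ",
           paste(.resKey(chain, utils::head(missing, 10L)), collapse = ", "),
           if (length(missing) > 10L) " ...")
    resnos <- c(resnos, want)
    ranges <- rbind(ranges, data.frame(chain = chain, start = ends[1],
                                       end = ends[2],
                                       stringsAsFactors = FALSE))
  }
  resnos <- sort(unique(resnos))
  new("ResidueSelection", ranges = ranges, keys = .resKey(chain, resnos),
      label = label)
}

## atom indices (topology order) of a selection; selection may be a
## ResidueSelection or a character vector of residue keys
.atomIndices <- function(structure, selection, heavyOnly = TRUE) {
  keys <- if (is.character(selection)) selection else residueKeys(selection)
  a <- atomTable(structure)
  ak <- .resKey(a$chain, a$resno)
  idx <- which(ak %in% keys)
  if (heavyOnly) idx <- idx[!.isHydrogen(a$elety[idx])]
  if (length(idx) == 0L) stop("selection resolves to no atoms")
  idx
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the unweighted RMSD
#' of `mobile` onto `reference`.  Reflections are never returned: the
#' smallest singular direction is sign-corrected so that `det(R) = +1`.
#'
#' @param mobile,reference numeric matrices, n x 3 with n >= 3, in
#'   corresponding row order.
#' @return a [SuperpositionResult-class]; apply with [applyTransform()].
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' s <- superpose(x, x)
#' s@rmsd  # 0
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have the same dimensions")
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  for (M in list(X, Y)) {
    sv <- svd(M, nu = 0, nv = 0)$d
    if (sv[2] < 1e-8 * max(sv[1], 1e-12))
      stop("degenerate geometry: points are collinear")
  }
  s <- svd(crossprod(X, Y))  # H = X' Y
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cr - R %*% cm)
  fitted <- X %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  new("SuperpositionResult", rotation = R, translation = tr, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords numeric matrix, n x 3.
#' @param transform a [SuperpositionResult-class].
#' @return transformed n x 3 matrix.
#' @export
applyTransform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% t(transform@rotation), 2,
        transform@translation, "+")
}

## rmsf engine on an extracted coordinate array.
## coords: nFrames x nA x 3 array of the working atom set;
## alignCols: indices (into the working set) used for fitting;
## reference: "mean" refits onto the time average once, "first" uses frame 1.
.rmsfEngine <- function(coords, alignCols, reference = c("mean", "first")) {
  reference <- match.arg(reference)
  nf <- dim(coords)[1]
  alignOnce <- function(refA) {
    out <- coords
    for (f in seq_len(nf)) {
      fr <- coords[f, , , drop = TRUE]
      dim(fr) <- dim(coords)[2:3]
      tr <- superpose(fr[alignCols, , drop = FALSE], refA)
      out[f, , ] <- applyTransform(fr, tr)
    }
    out
  }
  fr1 <- coords[1, , , drop = TRUE]; dim(fr1) <- dim(coords)[2:3]
  aligned <- alignOnce(fr1[alignCols, , drop = FALSE])
  if (reference == "mean") {
    mean1 <- apply(aligned, c(2, 3), mean)
    aligned <- alignOnce(mean1[alignCols, , drop = FALSE])
  }
  meanC <- apply(aligned, c(2, 3), mean)
  dev2 <- (aligned - rep(meanC, each = nf))^2
  sqrt(apply(dev2, 2, sum) / nf)  # per-atom rmsf, summed over x,y,z
}

## extract a frame-subset coordinate array for a set of atom indices
.coordArray <- function(trajectory, atomIdx, frameIdx) {
  cols <- as.vector(rbind(3L * (atomIdx - 1L) + 1L,
                          3L * (atomIdx - 1L) + 2L,
                          3L * (atomIdx - 1L) + 3L))
  sub <- trajectory@xyz[frameIdx, cols, drop = FALSE]
  arr <- array(0, dim = c(length(frameIdx), length(atomIdx), 3L))
  for (j in 1:3) arr[, , j] <- sub[, seq(j, ncol(sub), by = 3L),
                                   drop = FALSE]
  arr
}

#' Per-residue root-mean-square fluctuation
#'
#' Every sampled frame is first superposed onto the reference configuration
#' of `alignOn` (by default the time-average configuration, as in the
#' Gromacs `g_rmsf` convention; set `reference = "first"` to use the first
#' frame).  The per-atom RMSF is the root-mean-square deviation from the
#' mean position; the residue value is the mean over its non-hydrogen atoms
#' when `heavyOnly`.
#'
#' @param trajectory a [RiboTrajectory-class].
#' @param selection residues to report: a [ResidueSelection-class] or
#'   character vector of `"chain:resno"` keys.
#' @param alignOn residues used for the superposition (default: the
#'   selection itself).
#' @param heavyOnly exclude hydrogens (default `TRUE`).
#' @param reference `"mean"` (time-average, default) or `"first"`.
#' @param frames optional integer frame indices to analyse (default all).
#' @return named numeric vector of RMSF (Angstrom), one entry per residue.
#' @export
perResidueRmsf <- function(trajectory, selection, alignOn = selection,
                           heavyOnly = TRUE,
                           reference = c("mean", "first"),
                           frames = NULL) {
  reference <- match.arg(reference)
  topo <- trajectory@topology
  selIdx <- .atomIndices(topo, selection, heavyOnly)
  alnIdx <- .atomIndices(topo, alignOn, heavyOnly)
  if (is.null(frames)) frames <- seq_len(nFrames(trajectory))
  if (length(frames) < 2L) stop("need at least 2 frames for rmsf")
  atomIdx <- sort(unique(c(selIdx, alnIdx)))
  arr <- .coordArray(trajectory, atomIdx, frames)
  rmsfAtom <- .rmsfEngine(arr, match(alnIdx, atomIdx), reference)
  a <- atomTable(topo)
  keys <- .resKey(a$chain[atomIdx], a$resno[atomIdx])
  selPos <- match(selIdx, atomIdx)
  byRes <- tapply(rmsfAtom[selPos], keys[selPos], mean)
  wantKeys <- if (is.character(selection)) selection else
    residueKeys(selection)
  out <- as.numeric(byRes[wantKeys])
  names(out) <- wantKeys
  out[!is.na(out)]
}

#' Convert crystallographic B-factor to RMSF
#'
#' Uses the isotropic convention `B = 8 pi^2 <u^2> / 3`, i.e.
#' `rmsf = sqrt(3 B / (8 pi^2))` Angstrom.
#'
#' @param b numeric vector of B-factors, Angstrom^2, all >= 0.
#' @return numeric vector of RMSF values, Angstrom.
#' @export
bfactorToRmsf <- function(b) {
  if (any(!is.finite(b)) || any(b < 0))
    stop("B-factors must be finite and >= 0")
  sqrt(3 * b / (8 * pi^2))
}
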