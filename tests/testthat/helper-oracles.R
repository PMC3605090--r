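# Independent oracles and fixture builders shared across tests.

# Brute-force MFPT: dense-trapezoid double sum of
# (1/D) int_0^L e^{F} int_0^x e^{-F}, independent of the adaptive
# quadrature in mfpt().
oracleMfpt <- function(profile, D, n = 10000L, from = "left") {
  x <- seq(0, profile@L, length.out = n + 1L)
  h <- x[2] - x[1]
  ef <- exp(profileEnergy(profile, x))
  em <- exp(-profileEnergy(profile, x))
  cumTrapz <- function(y) c(0, cumsum((y[-1] + y[-length(y)]) / 2 * h))
  inner <- if (from == "left") cumTrapz(em)
           else rev(cumTrapz(rev(em)))
  g <- ef * inner
  sum((g[-1] + g[-length(g)]) / 2 * h) / D
}

# Exhaustive pair-search oracle: max angle change over all unordered
# pairs of rows of two coordinate sets (assumed already idealized).
oracleMaxPair <- function(coordsA, coordsB) {
  n <- nrow(coordsA)
  best <- list(angle = -Inf, pair = c(NA, NA))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    va <- coordsA[j, ] - coordsA[i, ]
    vb <- coordsB[j, ] - coordsB[i, ]
    ca <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
    ang <- acos(min(1, max(-1, ca))) * 180 / pi
    if (ang > best$angle) best <- list(angle = ang, pair = c(i, j))
  }
  best
}

# Random proper rigid transform as a SuperpositionResult-like pair.
randomRigid <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  list(R = R, t = rnorm(3, sd = 5))
}

applyRigid <- function(coords, rig) {
  sweep(coords %*% t(rig$R), 2, rig$t, "+")
}

# Rotation matrix about unit axis u by angle (degrees).
rotMat <- function(u, angleDeg) {
  u <- u / sqrt(sum(u^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Minimal single-chain structure with one P atom per residue, numbered
# 1..n: enough to resolve residue-range selections on a complete chain.
chainFixture <- function(n, chain = "A") {
  new("RiboStructure",
      atoms = data.frame(chain = chain, resno = seq_len(n), resid = "U",
                         elety = "P",
                         x = as.numeric(seq_len(n)), y = 0, z = 0,
                         b = NA_real_, stringsAsFactors = FALSE),
      label = paste0("chain-", n))
}

# Apply a global rigid transform to every frame of a trajectory.
transformTrajectory <- function(traj, rig) {
  xyz <- traj@xyz
  for (f in seq_len(nrow(xyz))) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    xyz[f, ] <- as.vector(t(applyRigid(m, rig)))
  }
  makeTrajectory(traj@topology, xyz, timeStep = timeStep(traj))
}
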