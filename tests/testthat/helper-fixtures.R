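# Scripted-frame fixtures built in code (no data files).

atomRow <- function(name, element, resid, resname, chain = "A", mass = 1) {
  data.frame(name = name, element = element, resid = resid,
             resname = resname, chain = chain, mass = mass,
             stringsAsFactors = FALSE)
}

# donor / hydrogen / acceptor triad; geometry set per frame by the caller
hbondAtoms <- function() {
  rbind(atomRow("OD", "O", 1, "ASP"),
        atomRow("HD", "H", 1, "ASP"),
        atomRow("OA", "O", 2, "SER"))
}

# frames with donor-acceptor at exactly distance d and donor-H-acceptor
# angle exactly ang degrees, all in the xy plane
hbondFrame <- function(d, ang) {
  theta <- ang * pi / 180
  hx <- 0.98                     # donor at origin, H along +x
  donor <- c(0, 0, 0)
  hyd <- c(hx, 0, 0)
  # acceptor at H + L * v with v at angle theta from (donor - H);
  # L solves |acc - donor| = d exactly
  v <- c(-cos(theta), sin(theta), 0)
  L <- hx * cos(theta) + sqrt(hx^2 * cos(theta)^2 - hx^2 + d^2)
  acc <- hyd + L * v
  rbind(donor, hyd, acc)
}

# ideal hexagonal ring (C-C 1.4 A) centred at `center`, in the xy plane
hexRing <- function(center) {
  ang <- seq(0, by = pi / 3, length.out = 6)
  cbind(1.4 * cos(ang) + center[1], 1.4 * sin(ang) + center[2],
        rep(center[3], 6))
}

phenylAtoms <- function(resid) {
  atomRow(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), "C", resid, "PHE")
}

# random rigid motion (rotation + translation) applied to an n x 3 matrix
rigidMotion <- function(xyz, seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(xyz %*% q, 2, runif(3, -5, 5), `+`)
}

# tiny two-helix ensemble used by several suites
smallBundle <- function(nFrames = 200, seed = 1, rho = 0.5) {
  cp <- matrix(rho, 2, 2); diag(cp) <- 0.9
  sampleTrajectory(syntheticSpec(2, 4, bundleSpacing = 6,
                                 ligand = NULL, baseSD = 0.3,
                                 coupling = cp, nFrames = nFrames,
                                 seed = seed))
}
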