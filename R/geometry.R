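## Rigid-body superposition, RMSD, screw-axis decomposition and
## dimer-rotation comparison.

pairCommonResidues <- function(a, b) {
  ## pair rows of two CA coordinate sets on common residue numbers
  common <- intersect(a$resno, b$resno)
  ia <- match(common, a$resno)
  ib <- match(common, b$resno)
  list(a = coordMatrix(a)[ia, , drop = FALSE],
       b = coordMatrix(b)[ib, , drop = FALSE],
       resno = common)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' order-paired coordinate sets.  Reflections are corrected by flipping the
#' sign of the smallest singular vector, so the result is always a proper
#' rotation.
#'
#' @param moving,fixed equal-length, order-paired coordinate sets: either
#'   data.frames from [selectCoords()] or plain n x 3 matrices.
#' @return a [SuperpositionResult]; `rot` and `trans` map `moving` onto
#'   `fixed` as `x %*% t(rot) + trans`.
#' @export
superpose <- function(moving, fixed) {
  M <- if (is.matrix(moving)) moving else coordMatrix(moving)
  F <- if (is.matrix(fixed)) fixed else coordMatrix(fixed)
  if (nrow(M) != nrow(F))
    stop("coordinate sets must be paired (equal length)")
  n <- nrow(M)
  if (n < 3) stop("superposition needs at least 3 paired atoms")
  cm <- colMeans(M); cf <- colMeans(F)
  Mc <- sweep(M, 2, cm); Fc <- sweep(F, 2, cf)
  ## collinearity check: rank of the centered cloud
  sv <- svd(Mc)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate (collinear) coordinate set")
  H <- t(Mc) %*% Fc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  trans <- cf - as.numeric(R %*% cm)
  resid <- Fc - Mc %*% t(R)
  rmsd <- sqrt(sum(resid^2) / n)
  methods::new("SuperpositionResult", rot = R, trans = as.numeric(trans),
               rmsd = rmsd, nPairs = as.integer(n))
}

#' Pairwise RMSD matrix over a set of chains
#'
#' Pairs chains on common residue numbers (CA atoms) and superposes every
#' unordered pair.
#'
#' @param chains list of CA coordinate sets from [selectCoords()].
#' @return `list(matrix, mean)`: symmetric RMSD matrix with zero diagonal,
#'   and the mean over all unordered pairs.
#' @export
averagePairwiseRmsd <- function(chains) {
  n <- length(chains)
  if (n < 2) stop("need at least two chains")
  m <- matrix(0, n, n)
  nm <- names(chains)
  if (is.null(nm)) nm <- as.character(seq_len(n))
  dimnames(m) <- list(nm, nm)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      pr <- pairCommonResidues(chains[[i]], chains[[j]])
      if (length(pr$resno) < 3)
        stop(sprintf("chains %s and %s share fewer than 3 residues", nm[i], nm[j]))
      m[i, j] <- m[j, i] <- superpose(pr$a, pr$b)@rmsd
    }
  }
  list(matrix = m, mean = mean(m[upper.tri(m)]))
}

crossProd3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Decompose a rigid transform into screw parameters
#'
#' The rotation angle comes from the trace (`cos(theta) = (tr(R) - 1)/2`),
#' the axis from the rotation's fixed direction, and the rise is the
#' component of the translation along the axis.  The axis sign is chosen so
#' the rise is non-negative; handedness is `"right"` when the rotation
#' about the advance direction is positive-sense under the right-hand rule
#' and `"left"` otherwise.  A near-zero rotation (below 0.1 degrees) is a
#' pure translation and raises an error.
#'
#' @param rot 3x3 proper orthonormal matrix.
#' @param trans numeric(3) translation (Angstrom).
#' @return a [ScrewParameters].
#' @export
screwDecompose <- function(rot, trans) {
  if (abs(det(rot) - 1) > 1e-6) stop("rot must be a proper rotation")
  tr <- sum(diag(rot))
  cosTheta <- max(-1, min(1, (tr - 1) / 2))
  theta <- acos(cosTheta)
  if (theta * 180 / pi < 0.1)
    stop("pure translation: rotation angle below 0.1 degrees")
  if (pi - theta > 1e-6) {
    axis <- c(rot[3, 2] - rot[2, 3], rot[1, 3] - rot[3, 1], rot[2, 1] - rot[1, 2])
    axis <- axis / (2 * sin(theta))
  } else {
    ## angle ~180 deg: antisymmetric part vanishes; use R + I
    B <- rot + diag(3)
    k <- which.max(colSums(B^2))
    axis <- B[, k] / sqrt(sum(B[, k]^2))
    ## fix sign convention consistently with sin(theta) ~ 0+: any sign is a
    ## valid axis at exactly 180 deg; pick the one giving rise >= 0 below
  }
  axis <- axis / sqrt(sum(axis^2))
  rise <- sum(trans * axis)
  signedTheta <- theta
  if (rise < 0) {
    axis <- -axis
    rise <- -rise
    signedTheta <- -theta
  }
  handed <- if (signedTheta >= 0) "right" else "left"
  if (pi - theta <= 1e-6) handed <- "right"  # 180 deg: sense is undefined
  methods::new("ScrewParameters", angle = theta * 180 / pi, axis = axis,
               rise = rise, handedness = handed)
}

#' Compose a screw transform from its parameters
#'
#' Inverse of [screwDecompose()]: builds the rotation matrix and
#' translation of a screw with the given signed angle about `axis`
#' (right-hand rule) and displacement `rise` along it.
#'
#' @param angle signed rotation, degrees.
#' @param axis 3-vector (normalized internally).
#' @param rise displacement along axis (Angstrom).
#' @param perp optional in-plane translation component to add.
#' @return `list(rot, trans)`.
#' @export
screwCompose <- function(angle, axis, rise, perp = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  list(rot = R, trans = rise * u + perp)
}

circularMeanDeg <- function(deg) {
  rad <- deg * pi / 180
  atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
}

circularSpreadDeg <- function(deg) {
  m <- circularMeanDeg(deg)
  d <- (deg - m + 180) %% 360 - 180
  max(abs(d))
}

## signed twist of a consecutive-subunit transform: the screw angle with the
## sign read off the rotation sense about the advance direction
signedTwist <- function(sp) {
  if (sp@handedness == "left") -sp@angle else sp@angle
}

consecutiveScrews <- function(copies, ids) {
  screws <- vector("list", length(ids) - 1)
  for (k in seq_len(length(ids) - 1)) {
    a <- placedCoords(copies[[ids[k]]])
    b <- placedCoords(copies[[ids[k + 1]]])
    pr <- pairCommonResidues(a, b)
    fit <- superpose(pr$a, pr$b)
    screws[[k]] <- screwDecompose(fit@rot, fit@trans)
  }
  screws
}

helixFromScrews <- function(screws, maxSpread = 15) {
  twists <- vapply(screws, signedTwist, numeric(1))
  rises <- vapply(screws, function(s) s@rise, numeric(1))
  if (circularSpreadDeg(twists) > maxSpread)
    stop(sprintf("not a regular helix: twist spread %.1f deg exceeds %.0f deg",
                 circularSpreadDeg(twists), maxSpread))
  twist <- circularMeanDeg(twists)
  rise <- mean(rises)
  axis <- colMeans(do.call(rbind, lapply(screws, function(s) s@axis)))
  axis <- axis / sqrt(sum(axis^2))
  methods::new("HelixParameters", rise = rise, twist = twist,
               pitch = rise * 360 / abs(twist),
               subunitsPerTurn = 360 / abs(twist),
               handedness = if (twist < 0) "left" else "right",
               nPairsAveraged = length(screws), axis = axis)
}

#' Helical parameters of a protofilament
#'
#' Superposes every consecutive subunit pair (CA atoms, common residues),
#' decomposes each transform into screw parameters, then averages: the
#' twist with circular statistics (angles wrap), the rise arithmetically.
#' Pitch and subunits/turn derive from the averages.  A twist spread above
#' `maxSpread` degrees means the path is not a regular helix and raises an
#' error.
#'
#' @param filament a [FilamentModel], or a plain list of [PlacedCopy]
#'   objects in filament order.
#' @param protofilament index of the protofilament to measure when a
#'   [FilamentModel] is given; defaults to the longest.
#' @param maxSpread tolerated twist spread in degrees.
#' @return a [HelixParameters].
#' @export
helixParameters <- function(filament, protofilament = NULL, maxSpread = 15) {
  if (methods::is(filament, "FilamentModel")) {
    if (!length(filament@protofilaments))
      stop("filament model has no protofilaments")
    if (is.null(protofilament))
      protofilament <- which.max(lengths(filament@protofilaments))
    ids <- filament@protofilaments[[protofilament]]
    copies <- filament@copies
  } else {
    copies <- filament
    ids <- seq_along(copies)
    if (is.null(names(copies))) names(copies) <- as.character(ids)
    ids <- names(copies)
  }
  if (length(ids) < 2) stop("need at least 2 consecutive subunits")
  helixFromScrews(consecutiveScrews(copies, ids), maxSpread)
}

#' Residual rotation between two head-to-tail dimers
#'
#' Anchors the comparison on one subunit of each dimer (by default the
#' tail subunit, the one donating the beta2-beta1-beta5 face), superposes
#' the two dimers on their anchors, and measures the residual rotation
#' that carries the second dimer's other subunit onto the first's.
#'
#' @param dimerA,dimerB `list(tail = , head = )` of CA coordinate sets.
#' @param mapping optional 2-column matrix pairing residue numbers of A
#'   (column 1) with residue numbers of B (column 2), e.g. from
#'   [residuePairing()]; NULL pairs on identical numbering.
#' @param anchor `"tail"` or `"head"`.
#' @return rotation angle in degrees.
#' @export
dimerRotationDifference <- function(dimerA, dimerB, mapping = NULL,
                                    anchor = c("tail", "head")) {
  anchor <- match.arg(anchor)
  other <- if (anchor == "tail") "head" else "tail"
  pairOn <- function(a, b) {
    if (is.null(mapping)) pr <- pairCommonResidues(a, b)
    else {
      ia <- match(mapping[, 1], a$resno)
      ib <- match(mapping[, 2], b$resno)
      ok <- !is.na(ia) & !is.na(ib)
      pr <- list(a = coordMatrix(a)[ia[ok], , drop = FALSE],
                 b = coordMatrix(b)[ib[ok], , drop = FALSE],
                 resno = mapping[ok, 1])
    }
    if (length(pr$resno) < 3) stop("mapping covers fewer than 3 CA pairs")
    pr
  }
  ## superpose B's anchor onto A's anchor
  prAnchor <- pairOn(dimerB[[anchor]], dimerA[[anchor]])
  fit <- superpose(prAnchor$a, prAnchor$b)
  ## transform B's other subunit into A's frame
  prOther <- pairOn(dimerB[[other]], dimerA[[other]])
  bMoved <- prOther$a %*% t(fit@rot) + rep(1, nrow(prOther$a)) %o% fit@trans
  resFit <- superpose(bMoved, prOther$b)
  tr <- sum(diag(resFit@rot))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}
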