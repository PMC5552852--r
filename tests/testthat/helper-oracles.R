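# Independent oracles used to validate the package's numerical core.
# Each deliberately takes a different algorithmic route from the
# implementation it checks.

# Horn's quaternion method for optimal rigid superposition: the optimal
# rotation is the eigenvector of the 4x4 key matrix with the largest
# eigenvalue.  Returns the minimal RMSD.
quaternionRmsd <- function(moving, fixed) {
  M <- sweep(moving, 2, colMeans(moving))
  F <- sweep(fixed, 2, colMeans(fixed))
  S <- t(M) %*% F
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE)$values)
  e <- sum(M^2) + sum(F^2) - 2 * lmax
  sqrt(max(0, e) / nrow(moving))
}

# Screw parameters via numerical eigendecomposition of the rotation
# matrix: the axis is the eigenvector with eigenvalue 1, the angle comes
# from the complex eigenvalue pair.
eigenScrew <- function(rot, trans) {
  ev <- eigen(rot)
  k <- which.min(abs(ev$values - 1))
  axis <- Re(ev$vectors[, k])
  axis <- axis / sqrt(sum(axis^2))
  ang <- max(abs(Arg(ev$values)))  # radians
  rise <- sum(trans * axis)
  if (rise < 0) {
    axis <- -axis
    rise <- -rise
  }
  # rotation sense about the (rise-positive) axis
  p <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- p - sum(p * axis) * axis
  p <- p / sqrt(sum(p^2))
  q <- as.numeric(rot %*% p)
  sgn <- sign(sum(axis * c(p[2] * q[3] - p[3] * q[2],
                           p[3] * q[1] - p[1] * q[3],
                           p[1] * q[2] - p[2] * q[1])))
  list(angle = ang * 180 / pi, axis = axis, rise = rise,
       handedness = if (sgn >= 0) "right" else "left")
}

# Exhaustive global alignment of two short sequences with affine gaps
# (open + extend per gap position, end gaps penalized), enumerating every
# alignment recursively.  Only feasible for sequences of length <= 8.
enumerateAlignScore <- function(a, b, sub, gapOpen = 10, gapExtend = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, score + sub[ca[i], cb[j]], "m")
    if (i <= length(ca))
      rec(i + 1, j, score - gapExtend - if (state != "a") gapOpen else 0, "a")
    if (j <= length(cb))
      rec(i, j + 1, score - gapExtend - if (state != "b") gapOpen else 0, "b")
  }
  rec(1, 1, 0, "m")
  best
}

# Recompute an alignment score directly from the emitted gapped strings.
scoreFromGapped <- function(ga, gb, sub, gapOpen = 10, gapExtend = 0.5) {
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  score <- 0
  inA <- FALSE
  inB <- FALSE
  for (k in seq_along(ca)) {
    if (ca[k] == "-") {
      score <- score - gapExtend - if (!inA) gapOpen else 0
      inA <- TRUE; inB <- FALSE
    } else if (cb[k] == "-") {
      score <- score - gapExtend - if (!inB) gapOpen else 0
      inB <- TRUE; inA <- FALSE
    } else {
      score <- score + sub[ca[k], cb[k]]
      inA <- FALSE; inB <- FALSE
    }
  }
  score
}

# Closed-form accessible area of sphere 1 in a two-sphere system
# (solvent-extended radii R1, R2 at center distance d).
twoSphereExposed <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * max(0, h)
}

# Simple exhaustive double-loop contact scans over toy atom tables,
# mirroring the published chemical criteria.
bruteHBonds <- function(a, b, dMax = 3.5, dMin = 2.2) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (!a$element[i] %in% c("N", "O")) next
    if (!b$element[j] %in% c("N", "O")) next
    d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - c(b$x[j], b$y[j], b$z[j]))^2))
    if (d >= dMin && d <= dMax)
      out <- rbind(out, data.frame(resnoA = a$resno[i], atomA = a$atom[i],
                                   resnoB = b$resno[j], atomB = b$atom[j],
                                   distance = d))
  }
  out
}

bruteSaltBridges <- function(a, b, dMax = 4.0) {
  acid <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  base <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
               HIS = c("ND1", "NE2"))
  isAcid <- function(df, i) !is.null(acid[[df$resid[i]]]) &&
    df$atom[i] %in% acid[[df$resid[i]]]
  isBase <- function(df, i) !is.null(base[[df$resid[i]]]) &&
    df$atom[i] %in% base[[df$resid[i]]]
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    ok <- (isAcid(a, i) && isBase(b, j)) || (isBase(a, i) && isAcid(b, j))
    if (!ok) next
    d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - c(b$x[j], b$y[j], b$z[j]))^2))
    if (d <= dMax)
      out <- rbind(out, data.frame(resnoA = a$resno[i], atomA = a$atom[i],
                                   resnoB = b$resno[j], atomB = b$atom[j],
                                   distance = d))
  }
  out
}

bruteHydrophobicPairs <- function(a, b, dMax = 4.5) {
  mainchain <- c("N", "CA", "C", "O", "OXT")
  pairs <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$element[i] != "C" || a$atom[i] %in% mainchain) next
    if (b$element[j] != "C" || b$atom[j] %in% mainchain) next
    d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - c(b$x[j], b$y[j], b$z[j]))^2))
    if (d <= dMax)
      pairs <- unique(rbind(pairs, data.frame(resnoA = a$resno[i],
                                              resnoB = b$resno[j])))
  }
  pairs
}

# Random toy atom table builder for contact-scan comparisons.
randomToyAtoms <- function(n, seed, spread = 6) {
  set.seed(seed)
  data.frame(chain = "A", resno = seq_len(n),
             resid = sample(c("ALA", "ASP", "GLU", "LYS", "ARG", "HIS",
                              "LEU", "SER"), n, replace = TRUE),
             atom = sample(c("N", "CA", "C", "O", "CB", "CG", "OD1", "NZ",
                             "NH1", "OE1", "NE2", "CD1"), n, replace = TRUE),
             element = NA_character_,
             x = runif(n, 0, spread), y = runif(n, 0, spread),
             z = runif(n, 0, spread), occ = 1, b = 0,
             stringsAsFactors = FALSE) -> df
  df$element <- substr(df$atom, 1, 1)
  df
}

# Random proper rotation matrix.
randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

oneAtom <- function(x = 0, y = 0, z = 0, atom = "CA", element = "C",
                    resno = 1L, resid = "ALA", chain = "A") {
  data.frame(chain = chain, resno = resno, resid = resid, atom = atom,
             element = element, x = x, y = y, z = z, occ = 1, b = 0,
             stringsAsFactors = FALSE)
}

coordMatrixOf <- function(cs) as.matrix(cs[, c("x", "y", "z")])
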