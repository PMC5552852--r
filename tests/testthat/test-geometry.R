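test_that("superposition recovers exact transforms and is symmetric", {
  set.seed(11)
  X <- matrix(rnorm(30, sd = 5), ncol = 3)

  fit0 <- superpose(X, X)
  expect_equal(fit0@rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0@rot, diag(3), tolerance = 1e-9, ignore_attr = TRUE)

  ## 90 degrees about z plus a translation
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  Y <- X %*% t(Rz) + rep(1, nrow(X)) %o% c(3, -2, 7)
  fit <- superpose(X, Y)
  expect_equal(fit@rmsd, 0, tolerance = 1e-9)
  ang <- acos((sum(diag(fit@rot)) - 1) / 2) * 180 / pi
  expect_equal(ang, 90, tolerance = 1e-9)

  ## rmsd is direction-symmetric
  Yn <- Y + matrix(rnorm(30, sd = 0.3), ncol = 3)
  expect_equal(superpose(X, Yn)@rmsd, superpose(Yn, X)@rmsd,
               tolerance = 1e-9)

  ## degenerate input
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(X[1:2, ], X[1:2, ]), "at least 3")
})

test_that("Kabsch rmsd equals the quaternion-method oracle on random clouds", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    X <- matrix(rnorm(30, sd = 4), ncol = 3)
    Y <- X %*% t(randomRotation()) +
      rep(1, 10) %o% rnorm(3, sd = 10) + matrix(rnorm(30, sd = 0.5), ncol = 3)
    worst <- max(worst, abs(superpose(X, Y)@rmsd - quaternionRmsd(X, Y)))
  }
  expect_lt(worst, 1e-9)
})

test_that("screw decomposition inverts construction and matches the eigen oracle", {
  sc <- screwCompose(51.4286, c(0, 0, 1), 11.43)
  sp <- screwDecompose(sc$rot, sc$trans)
  expect_equal(sp@angle, 51.4286, tolerance = 1e-9)
  expect_equal(sp@rise, 11.43, tolerance = 1e-9)
  expect_identical(sp@handedness, "right")
  expect_equal(sp@axis, c(0, 0, 1), tolerance = 1e-9)

  ## a crystallographic 2_1 in an orthogonal frame: 180 deg + c/2
  sc2 <- screwCompose(180, c(0, 0, 1), 62.8)
  sp2 <- screwDecompose(sc2$rot, sc2$trans)
  expect_equal(sp2@angle, 180, tolerance = 1e-9)
  expect_equal(sp2@rise, 62.8, tolerance = 1e-9)

  ## left-handed: negative angle about the advance direction
  sc3 <- screwCompose(-51.4286, c(0, 0, 1), 11.43)
  sp3 <- screwDecompose(sc3$rot, sc3$trans)
  expect_identical(sp3@handedness, "left")
  expect_equal(sp3@angle, 51.4286, tolerance = 1e-9)

  ## random screws: round-trip and independent eigen-based oracle
  set.seed(7)
  for (i in 1:25) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 5, 175)
    rise <- runif(1, 0.5, 25)
    perp <- rnorm(3); perp <- perp - sum(perp * ax) * ax
    sc <- screwCompose(ang, ax, rise, perp = perp)
    sp <- screwDecompose(sc$rot, sc$trans)
    expect_equal(sp@angle, ang, tolerance = 1e-9)
    expect_equal(sp@rise, rise, tolerance = 1e-9)
    orc <- eigenScrew(sc$rot, sc$trans)
    expect_equal(sp@angle, orc$angle, tolerance = 1e-7)
    expect_equal(sp@rise, orc$rise, tolerance = 1e-7)
    expect_equal(abs(sum(sp@axis * orc$axis)), 1, tolerance = 1e-7)
  }

  expect_error(screwDecompose(diag(3), c(0, 0, 5)), "pure translation")
})

test_that("pairwise RMSD matrix matches direct per-pair computation", {
  g <- generateFilament(filamentSpec(nSubunits = 3L))
  ca <- selectCoords(g$structure, "A")

  two <- averagePairwiseRmsd(list(a = ca, b = ca))
  expect_equal(two$mean, 0, tolerance = 1e-12)

  set.seed(3)
  jitter <- function(cs, sd) {
    cs$x <- cs$x + rnorm(nrow(cs), sd = sd)
    cs$y <- cs$y + rnorm(nrow(cs), sd = sd)
    cs$z <- cs$z + rnorm(nrow(cs), sd = sd)
    cs
  }
  chains <- list(a = ca, b = jitter(ca, 0.3), c = jitter(ca, 0.6))
  res <- averagePairwiseRmsd(chains)
  expect_equal(res$matrix, t(res$matrix))
  expect_equal(diag(res$matrix), rep(0, 3), ignore_attr = TRUE)
  direct <- c(superpose(coordMatrixOf(chains$a), coordMatrixOf(chains$b))@rmsd,
              superpose(coordMatrixOf(chains$a), coordMatrixOf(chains$c))@rmsd,
              superpose(coordMatrixOf(chains$b), coordMatrixOf(chains$c))@rmsd)
  expect_equal(res$mean, mean(direct), tolerance = 1e-12)

  short <- ca[1:2, ]
  expect_error(averagePairwiseRmsd(list(a = ca, b = short)), "fewer than 3")
})

test_that("helix parameters are exact on ground truth and reject irregularity", {
  g <- generateFilament(filamentSpec(rise = 11.43, twist = -360 / 7,
                                     nSubunits = 7L))
  copies <- lapply(chainIds(g$structure), function(ch)
    applyOp(g$structure, ch, 1L, c(0L, 0L, 0L)))
  h <- helixParameters(copies)
  expect_equal(h@rise, 11.43, tolerance = 1e-9)
  expect_equal(h@twist, -360 / 7, tolerance = 1e-9)
  expect_equal(h@pitch, 11.43 * 7, tolerance = 1e-6)
  expect_equal(h@subunitsPerTurn, 7, tolerance = 1e-9)
  expect_identical(h@handedness, "left")
  ## the enforced identity pitch = rise * 360 / |twist|
  expect_equal(h@pitch, h@rise * 360 / abs(h@twist), tolerance = 1e-9)

  ## wildly inconsistent consecutive twists are not a regular helix
  g2 <- generateFilament(filamentSpec(rise = 10, twist = 90, nSubunits = 4L))
  copies2 <- lapply(chainIds(g2$structure), function(ch)
    applyOp(g2$structure, ch, 1L, c(0L, 0L, 0L)))
  expect_error(helixParameters(copies2[c(1, 2, 4)]), "not a regular helix")
})

test_that("dimer rotation difference recovers a constructed head rotation", {
  g <- generateFilament(filamentSpec(nSubunits = 3L))
  tailC <- selectCoords(g$structure, "A")
  headC <- selectCoords(g$structure, "B")
  dimer <- list(tail = tailC, head = headC)

  ## acos near trace = 3 is ill-conditioned, so "zero" means < 1e-4 deg
  expect_lt(dimerRotationDifference(dimer, dimer), 1e-4)

  ## rotate the second dimer's head by a known 25 degrees about a random
  ## axis through its centroid
  set.seed(9)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  sc <- screwCompose(25, ax, 0)
  ctr <- colMeans(as.matrix(headC[, c("x", "y", "z")]))
  xyz <- sweep(as.matrix(headC[, c("x", "y", "z")]), 2, ctr) %*% t(sc$rot)
  head2 <- headC
  head2$x <- xyz[, 1] + ctr[1]; head2$y <- xyz[, 2] + ctr[2]
  head2$z <- xyz[, 3] + ctr[3]
  dimer2 <- list(tail = tailC, head = head2)
  expect_equal(dimerRotationDifference(dimer, dimer2, anchor = "tail"), 25,
               tolerance = 1e-6)
  ## a whole-dimer rigid motion must not contribute
  sc2 <- screwCompose(40, c(0, 1, 0), 0)
  move <- function(cs) {
    xyz <- as.matrix(cs[, c("x", "y", "z")]) %*% t(sc2$rot)
    cs$x <- xyz[, 1] + 5; cs$y <- xyz[, 2] - 3; cs$z <- xyz[, 3] + 2
    cs
  }
  dimer3 <- list(tail = move(tailC), head = move(head2))
  expect_equal(dimerRotationDifference(dimer, dimer3, anchor = "tail"), 25,
               tolerance = 1e-6)
})
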