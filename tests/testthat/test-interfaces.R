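test_that("SASA reproduces analytic sphere areas", {
  a1 <- oneAtom()
  s <- sasa(a1, nPoints = 960)
  exact <- 4 * pi * (1.70 + 1.4)^2
  expect_lt(abs(sum(s) - exact) / exact, 0.01)

  ## two fully overlapping identical atoms expose one sphere in total
  a2 <- rbind(a1, a1)
  expect_lt(abs(sum(sasa(a2, nPoints = 960)) - exact) / exact, 0.01)

  ## partial overlap against the spherical-cap closed form
  for (d in c(1.5, 3.0, 5.0)) {
    pair <- rbind(a1, oneAtom(x = d, resno = 2L))
    got <- sasa(pair, nPoints = 960)
    want <- twoSphereExposed(3.1, 3.1, d)
    expect_lt(abs(got[1] - want) / want, 0.02)
    expect_lt(abs(got[2] - want) / want, 0.02)
  }

  expect_error(sasa(a1, nPoints = 50), "nPoints")
  expect_warning(sasa(oneAtom(element = "XX")), "fallback")
})

test_that("SASA is invariant under rotation and translation", {
  set.seed(5)
  n <- 60
  cl <- data.frame(chain = "A", resno = seq_len(n), resid = "ALA",
                   atom = "CA", element = sample(c("C", "N", "O", "S"), n, TRUE),
                   x = rnorm(n, sd = 4), y = rnorm(n, sd = 4),
                   z = rnorm(n, sd = 4), occ = 1, b = 0)
  s0 <- sasa(cl)
  R <- randomRotation()
  xyz <- as.matrix(cl[, c("x", "y", "z")]) %*% t(R)
  cl2 <- cl
  cl2$x <- xyz[, 1] + 12.3; cl2$y <- xyz[, 2] - 4.5; cl2$z <- xyz[, 3] + 0.7
  s1 <- sasa(cl2)
  expect_lt(max(abs(s1 - s0) / pmax(s0, 1e-6)), 1e-9)
})

test_that("doubling the point count barely moves a domain-sized total", {
  sub <- dixpol:::placeBody(
    dixpol:::engineerTemplate(makeToySubunit(2L, 150L),
                              filamentSpec(nRes = 150L)),
    filamentSpec(nRes = 150L), FALSE)
  t960 <- sum(sasa(sub, nPoints = 960))
  t1920 <- sum(sasa(sub, nPoints = 1920))
  expect_lt(abs(t1920 - t960) / t960, 0.005)
})

test_that("buried surface area behaves like an interface measure", {
  g <- generateFilament(filamentSpec(nSubunits = 3L))
  a <- applyOp(g$structure, "A", 1L, c(0L, 0L, 0L))
  b <- applyOp(g$structure, "B", 1L, c(0L, 0L, 0L))
  bsa <- buriedSurfaceArea(a, b, nPoints = 480)
  expect_gt(bsa$bsaTotal, 0)
  expect_true(all(bsa$bsaPerSide >= 0))
  expect_equal(bsa$bsaTotal, sum(bsa$bsaPerSide))

  ## fully separated parts bury exactly zero area
  far <- atomTable(b)
  far$x <- far$x + 200
  bsa0 <- buriedSurfaceArea(atomTable(a), far, nPoints = 480)
  expect_identical(bsa0$bsaTotal, 0)

  expect_error(buriedSurfaceArea(atomTable(a), atomTable(a)), "both parts")
})

test_that("contact detectors match exhaustive scans on random toys", {
  for (seed in 1:6) {
    a <- randomToyAtoms(12, seed)
    b <- randomToyAtoms(12, seed + 100, spread = 8)
    hb <- findHBonds(a, b)
    oracle <- bruteHBonds(a, b)
    expect_identical(nrow(hb), if (is.null(oracle)) 0L else nrow(oracle))
    if (nrow(hb)) {
      key <- function(d) sort(paste(d$resnoA, d$atomA, d$resnoB, d$atomB))
      expect_identical(key(hb), key(oracle))
    }
    sb <- findSaltBridges(a, b)
    osb <- bruteSaltBridges(a, b)
    expect_identical(nrow(sb), if (is.null(osb)) 0L else nrow(osb))
    hp <- findHydrophobic(a, b)
    ohp <- bruteHydrophobicPairs(a, b)
    expect_identical(nrow(hp), if (is.null(ohp)) 0L else nrow(ohp))
  }
})

test_that("hydrogen-bond records carry the main-chain flag and distances", {
  a <- oneAtom(atom = "N", element = "N")
  b <- oneAtom(x = 3.2, atom = "O", element = "O", resno = 5L, chain = "B")
  hb <- findHBonds(a, b)
  expect_identical(nrow(hb), 1L)
  expect_identical(hb$kind, "mainchain_hbond")
  expect_equal(hb$distance, 3.2)

  ## side-chain pair: plain hbond
  sc <- findHBonds(oneAtom(atom = "ND1", element = "N", resid = "HIS"),
                   oneAtom(x = 3.0, atom = "OD1", element = "O",
                           resid = "ASP", chain = "B"))
  expect_identical(sc$kind, "hbond")

  ## beyond cutoff or inside the clash floor: nothing
  expect_identical(nrow(findHBonds(a, oneAtom(x = 3.8, atom = "O",
                                              element = "O", chain = "B"))), 0L)
  expect_identical(nrow(findHBonds(a, oneAtom(x = 1.0, atom = "O",
                                              element = "O", chain = "B"))), 0L)
})

test_that("salt bridges pair acidic oxygens with basic nitrogens", {
  asp <- oneAtom(atom = "OD1", element = "O", resid = "ASP")
  lys <- oneAtom(x = 3.0, atom = "NZ", element = "N", resid = "LYS",
                 chain = "B")
  sb <- findSaltBridges(asp, lys)
  expect_identical(nrow(sb), 1L)
  expect_equal(sb$distance, 3.0)
  ## orientation-independent
  expect_identical(nrow(findSaltBridges(lys, asp)), 1L)
  ## backbone N does not qualify
  expect_identical(nrow(findSaltBridges(asp, oneAtom(x = 3, atom = "N",
                                                     element = "N",
                                                     resid = "LYS",
                                                     chain = "B"))), 0L)
})

test_that("water-mediated detection finds single and chained bridges", {
  a <- oneAtom(atom = "O", element = "O")
  b <- oneAtom(x = 6.0, atom = "O", element = "O", chain = "B", resno = 2L)
  w1 <- oneAtom(x = 3.0, atom = "O", element = "O", resid = "HOH",
                resno = 101L, chain = "w")
  wm <- findWaterMediated(a, b, w1)
  expect_identical(nrow(wm), 1L)
  expect_identical(wm$kind, "water_mediated")

  ## two-water chain requires depth 2
  b2 <- oneAtom(x = 9.0, atom = "O", element = "O", chain = "B", resno = 2L)
  w2 <- oneAtom(x = 6.0, atom = "O", element = "O", resid = "HOH",
                resno = 102L, chain = "w")
  ws <- rbind(w1, w2)
  expect_identical(nrow(findWaterMediated(a, b2, ws, depth = 1)), 0L)
  wm2 <- findWaterMediated(a, b2, ws, depth = 2)
  expect_identical(nrow(wm2), 1L)
})

test_that("planted bridging waters are recovered from a fixture", {
  g <- generateFilament(filamentSpec(nSubunits = 4L, waters = TRUE))
  a <- applyOp(g$structure, "A", 1L, c(0L, 0L, 0L))
  b <- applyOp(g$structure, "B", 1L, c(0L, 0L, 0L))
  wm <- findWaterMediated(a, b, waters(g$structure))
  expect_gt(nrow(wm), 0)
})

test_that("interface fingerprints recover the planted inventory", {
  sdefs <- defaultStrandDefs("toy")
  g <- generateFilament(filamentSpec(secondStrand = TRUE))

  ## head-to-tail pair: three main-chain bridges in the beta4:beta2 zipper
  a <- applyOp(g$structure, "A", 1L, c(0L, 0L, 0L))
  b <- applyOp(g$structure, "B", 1L, c(0L, 0L, 0L))
  rep1 <- interfaceFingerprint(a, b, sdefs, nPoints = 480)
  mc <- contacts(rep1)[contacts(rep1)$kind == "mainchain_hbond", ]
  expect_identical(nrow(mc), 3L)
  expect_equal(mc$distance, rep(2.9, 3), tolerance = 1e-9)
  expect_true(all(mc$site == "site1"))
  expect_gt(bsaTotal(rep1), 0)

  ## inter-filament pair of the double helix: planted type II salt bridge
  n <- g$truth@spec@nSubunits
  s2 <- applyOp(g$structure, chainIds(g$structure)[n + 1], 1L, c(0L, 0L, 0L))
  rep2 <- interfaceFingerprint(applyOp(g$structure, "B", 1L, c(0L, 0L, 0L)),
                               s2, sdefs, nPoints = 480)
  sb <- contacts(rep2)[contacts(rep2)$kind == "salt_bridge", ]
  expect_identical(nrow(sb), 1L)
  expect_equal(sb$distance, 3.0, tolerance = 1e-9)
  expect_identical(sb$site, "typeII")

  ## distant pair: empty report
  farB <- atomTable(b)
  farB$x <- farB$x + 150
  rep0 <- interfaceFingerprint(atomTable(a), farB, sdefs)
  expect_identical(nrow(contacts(rep0)), 0L)
  expect_identical(bsaTotal(rep0), 0)
})
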