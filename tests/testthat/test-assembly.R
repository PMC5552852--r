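# The synthetic generator supplies assemblies with known architecture and
# edge structure; expansion radius 30 A with +/-1 lattice shifts keeps the
# neighborhoods small.

expandSmall <- function(structure, radius = 30) {
  expandNeighborhood(structure, radius = radius, maxShift = 1L)
}

test_that("neighborhood expansion matches brute-force enumeration in P1", {
  g <- generateFilament(filamentSpec(nSubunits = 3L, cellPadding = 8))
  s <- g$structure
  radius <- 25
  copies <- expandNeighborhood(s, radius = radius, maxShift = 1L)
  expect_true(all(c("A:1:+0,+0,+0", "B:1:+0,+0,+0", "C:1:+0,+0,+0") %in%
                    names(copies)))

  ## brute force: every chain x every shift in a 3x3x3 block, kept when
  ## the bounding spheres come within the radius
  bounds <- lapply(chainIds(s), function(ch)
    dixpol:::chainBounds(atomTable(s)[atomTable(s)$chain == ch, ]))
  names(bounds) <- chainIds(s)
  O <- dixpol:::orthoMatrix(s@cell)
  count <- 0L
  for (ch in chainIds(s)) for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    ctr <- bounds[[ch]]$center + as.numeric(O %*% c(i, j, k))
    near <- any(vapply(bounds, function(ref)
      sqrt(sum((ctr - ref$center)^2)) - bounds[[ch]]$radius - ref$radius <=
        radius, logical(1)))
    if (near) count <- count + 1L
  }
  expect_identical(length(copies), count)
})

test_that("expansion extends a commensurate filament across the c boundary", {
  g <- generateFilament(filamentSpec(rise = 11.43, twist = -360 / 7,
                                     nSubunits = 7L))
  copies <- expandSmall(g$structure)
  edges <- detectHeadToTail(copies, defaultStrandDefs("toy"))
  ## the last chain of the cell bonds the +c image of the first chain
  expect_true(any(edges$from == "G:1:+0,+0,+0" & edges$to == "A:1:+0,+0,+1"))
  fm <- buildFilaments(copies, edges, defaultStrandDefs("toy"))
  expect_gt(max(lengths(protofilaments(fm))), 7)
})

test_that("head-to-tail detection sees consecutive subunits only", {
  g <- generateFilament(filamentSpec(nSubunits = 5L))
  copies <- lapply(chainIds(g$structure), function(ch)
    applyOp(g$structure, ch, 1L, c(0L, 0L, 0L)))
  names(copies) <- vapply(copies, copyId, character(1))
  edges <- detectHeadToTail(copies, defaultStrandDefs("toy"))
  expect_identical(nrow(edges), 4L)
  expect_true(all(edges$n_mainchain_hbonds == 3L))
  ord <- match(edges$from, names(copies))
  expect_identical(match(edges$to, names(copies)), ord + 1L)

  ## two isolated copies far apart: no edge
  far <- copies[c(1, 4)]
  expect_identical(nrow(detectHeadToTail(far, defaultStrandDefs("toy"))), 0L)

  expect_error(detectHeadToTail(copies, list(b1 = c(1, 3))), "strandDefs")
})

test_that("filament building extracts paths and rejects branching", {
  g <- generateFilament(filamentSpec(nSubunits = 3L))
  copies <- lapply(chainIds(g$structure), function(ch)
    applyOp(g$structure, ch, 1L, c(0L, 0L, 0L)))
  names(copies) <- c("A", "B", "C")
  edges <- data.frame(from = c("A", "B"), to = c("B", "C"),
                      n_mainchain_hbonds = 3L, stringsAsFactors = FALSE)
  fm <- buildFilaments(copies, edges, defaultStrandDefs("toy"))
  expect_identical(protofilaments(fm), list(c("A", "B", "C")))

  bad <- rbind(edges, data.frame(from = "A", to = "C",
                                 n_mainchain_hbonds = 2L))
  expect_error(buildFilaments(copies, bad, defaultStrandDefs("toy")),
               "non-filamentous")
})

test_that("architecture classification matches the generator ground truth", {
  sdefs <- defaultStrandDefs("toy")
  for (case in list(list(second = NULL, want = "single"),
                    list(second = TRUE, want = "double"))) {
    g <- generateFilament(filamentSpec(secondStrand = case$second))
    copies <- expandSmall(g$structure)
    fm <- buildFilaments(copies, detectHeadToTail(copies, sdefs), sdefs)
    expect_identical(architecture(fm), case$want)
    expect_identical(architecture(fm), g$truth@architecture)
    if (case$want == "single")
      expect_identical(nrow(fm@interfilamentEdges), 0L)
  }
})

test_that("interfilament neighbors: interior subunits see two typed partners", {
  sdefs <- defaultStrandDefs("toy")
  g <- generateFilament(filamentSpec(secondStrand = TRUE))
  copies <- expandSmall(g$structure)
  fm <- buildFilaments(copies, detectHeadToTail(copies, sdefs), sdefs)
  main <- protofilaments(fm)[[which.max(lengths(protofilaments(fm)))]]
  mid <- main[ceiling(length(main) / 2)]
  nb <- countInterfilamentNeighbors(fm, mid)
  expect_identical(nb$n, 2L)
  expect_setequal(unname(nb$kinds),
                  c("interfilament_typeI", "interfilament_typeII"))

  ## a terminal subunit of the filament touches fewer partners than an
  ## interior one
  ends <- c(main[1], main[length(main)])
  nEnd <- min(vapply(ends, function(id)
    countInterfilamentNeighbors(fm, id)$n, integer(1)))
  expect_lt(nEnd, 2L)

  ## neighbor counting is only defined for double architectures
  g1 <- generateFilament(filamentSpec())
  copies1 <- expandSmall(g1$structure)
  fm1 <- buildFilaments(copies1, detectHeadToTail(copies1, sdefs), sdefs)
  expect_error(countInterfilamentNeighbors(fm1, protofilaments(fm1)[[1]][1]),
               "double")
})

test_that("expansion is invariant under whole-lattice translation", {
  sdefs <- defaultStrandDefs("toy")
  g <- generateFilament(filamentSpec(nSubunits = 7L))
  s <- g$structure
  O <- dixpol:::orthoMatrix(s@cell)
  sh <- as.numeric(O %*% c(1, 0, 0))
  at2 <- atomTable(s)
  at2$x <- at2$x + sh[1]; at2$y <- at2$y + sh[2]; at2$z <- at2$z + sh[3]
  s2 <- dixpol:::newCrystalStructure(at2, waters(s), s@cell, spaceGroup(s))

  build <- function(st) {
    copies <- expandSmall(st)
    buildFilaments(copies, detectHeadToTail(copies, sdefs), sdefs)
  }
  fmA <- build(s); fmB <- build(s2)
  expect_identical(architecture(fmA), architecture(fmB))
  expect_identical(sort(lengths(protofilaments(fmA))),
                   sort(lengths(protofilaments(fmB))))
  expect_identical(nrow(fmA@edges), nrow(fmB@edges))
})

test_that("every consecutive head-to-tail pair carries the same screw step", {
  sdefs <- defaultStrandDefs("toy")
  g <- generateFilament(filamentSpec(rise = 11.43, twist = -360 / 7,
                                     nSubunits = 7L))
  copies <- expandSmall(g$structure)
  fm <- buildFilaments(copies, detectHeadToTail(copies, sdefs), sdefs)
  main <- protofilaments(fm)[[which.max(lengths(protofilaments(fm)))]]
  screws <- dixpol:::consecutiveScrews(fm@copies, main)
  rises <- vapply(screws, function(s) s@rise, numeric(1))
  angles <- vapply(screws, function(s) s@angle, numeric(1))
  expect_lt(diff(range(rises)), 1e-8)
  expect_lt(diff(range(angles)), 1e-8)
})
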