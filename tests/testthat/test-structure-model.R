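test_that("synthetic fixtures round-trip through PDB and mmCIF", {
  g <- generateFilament(filamentSpec(nSubunits = 3L, waters = TRUE))
  dir <- withr::local_tempdir()
  paths <- writeFixture(g$structure, g$truth, dir, "rt")
  for (p in paths[c("pdb", "cif")]) {
    s2 <- readStructure(p)
    expect_identical(nrow(atomTable(s2)), nrow(atomTable(g$structure)))
    expect_identical(nrow(waters(s2)), nrow(waters(g$structure)))
    expect_identical(chainIds(s2), chainIds(g$structure))
    expect_equal(as.matrix(atomTable(s2)[, c("x", "y", "z")]),
                 as.matrix(atomTable(g$structure)[, c("x", "y", "z")]),
                 tolerance = 2e-3, ignore_attr = TRUE)
    expect_equal(unname(unitCell(s2)), g$structure@cell, tolerance = 1e-3)
    expect_identical(spaceGroup(s2), "P 1")
  }
})

test_that("missing cell or space-group records are hard errors", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), tmp)
  expect_error(readStructure(tmp), "CRYST1")
  tmp2 <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_x", "_cell.length_a 10"), tmp2)
  expect_error(readStructure(tmp2), "_cell")
})

test_that("unknown space groups are rejected with the supported list", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 32 2 1      6",
    "ATOM      1  CA  ALA A   1       1.000   1.000   1.000  1.00  0.00           C",
    "END"), tmp)
  expect_error(readStructure(tmp), "supported groups")
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.70  0.00           C",
    "ATOM      3  N  AALA A   1       3.000   0.000   0.000  0.50  0.00           N",
    "ATOM      4  N  BALA A   1       4.000   0.000   0.000  0.50  0.00           N",
    "END"), tmp)
  s <- readStructure(tmp)
  at <- atomTable(s)
  expect_identical(nrow(at), 2L)
  expect_equal(at$x[at$atom == "CA"], 2.0)  # higher occupancy wins
  expect_equal(at$x[at$atom == "N"], 3.0)   # tie: altloc label order
})

test_that("symmetry operators close under composition for every group", {
  for (sg in c("P 1", "P 21 21 21", "P 61")) {
    ops <- spaceGroupOps(sg)
    expect_true(max(abs(ops[[1]]$rot - diag(3))) < 1e-12)
    for (a in ops) for (b in ops) {
      rot <- a$rot %*% b$rot
      trans <- as.numeric(a$rot %*% b$trans) + a$trans
      found <- any(vapply(ops, function(o) {
        dt <- (trans - o$trans) %% 1
        max(abs(o$rot - rot)) < 1e-9 && max(pmin(dt, 1 - dt)) < 1e-9
      }, logical(1)))
      expect_true(found, info = sg)
    }
    for (o in ops) expect_equal(det(o$rot), 1)
  }
})

test_that("applyOp realizes screw operators and preserves rigidity", {
  g <- generateFilament(filamentSpec(nSubunits = 3L))
  s <- g$structure

  idc <- applyOp(s, "A", 1L, c(0L, 0L, 0L))
  expect_lt(max(abs(as.matrix(atomTable(idc)[, c("x", "y", "z")]) -
                    as.matrix(selectCoords(s, "A", atomFilter = "all")[, c("x", "y", "z")]))),
            1e-9)

  ## rigid transform: all intra-chain distances preserved
  sh <- applyOp(s, "A", 1L, c(1L, -1L, 0L))
  d0 <- dist(selectCoords(s, "A", atomFilter = "all")[, c("x", "y", "z")])
  d1 <- dist(atomTable(sh)[, c("x", "y", "z")])
  expect_lt(max(abs(d0 - d1)), 1e-6)

  ## a 2_1 screw applied twice is a pure lattice translation (+c for the
  ## operator with translation (1/2, 0, 1/2))
  cs <- newP212121Cell()
  c1 <- applyOp(cs, "A", 2L, c(0L, 0L, 0L))
  s2 <- applyOp(structureFromCopy(cs, c1), "A", 2L, c(0L, 0L, 0L))
  O <- dixpol:::orthoMatrix(cs@cell)
  moved <- as.matrix(atomTable(s2)[, c("x", "y", "z")])
  orig <- as.matrix(atomTable(cs)[, c("x", "y", "z")])
  shift <- sweep(moved, 2, as.numeric(O %*% c(0, 0, 1)))
  expect_lt(max(abs(shift - orig)), 1e-9)

  ## the 6_1 generator (60 deg + c/6) applied six times translates by
  ## exactly one c repeat
  hexCell <- c(40, 40, 60, 90, 90, 120)
  hx <- dixpol:::newCrystalStructure(atomTable(cs), dixpol:::emptyAtomTable(),
                                     hexCell, "P 61")
  ops <- spaceGroupOps("P 61")
  gen <- which(vapply(ops, function(o) abs(o$trans[3] - 1 / 6) < 1e-9,
                      logical(1)))
  cur <- hx
  for (i in 1:6) {
    cp <- applyOp(cur, "A", gen, c(0L, 0L, 0L))
    cur <- structureFromCopy(hx, cp)
  }
  Oh <- dixpol:::orthoMatrix(hexCell)
  d <- as.matrix(atomTable(cur)[, c("x", "y", "z")]) -
    as.matrix(atomTable(hx)[, c("x", "y", "z")])
  expect_lt(max(abs(sweep(d, 2, as.numeric(Oh %*% c(0, 0, 1))))), 1e-9)
})

test_that("selectCoords filters, orders and reports gaps", {
  g <- generateFilament(filamentSpec(nSubunits = 3L))
  s <- g$structure
  ca <- selectCoords(s, "A")
  expect_identical(nrow(ca), 24L)
  expect_true(all(ca$atom == "CA"))
  expect_true(!is.unsorted(ca$resno))

  bb <- selectCoords(s, "A", residueRange = c(2, 2), atomFilter = "backbone")
  expect_identical(nrow(bb), 4L)
  expect_setequal(bb$atom, c("N", "CA", "C", "O"))

  gap <- selectCoords(s, "A", residueRange = c(20, 30))
  expect_identical(attr(gap, "missing"), 25:30)
  expect_identical(nrow(gap), 5L)

  expect_error(selectCoords(s, "Q"), "chain")
  expect_error(selectCoords(s, "A", residueRange = c(500, 600)), "empty")
})
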