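## Solvent-accessible surface area, buried interface area, and typed
## contact detection (hydrogen bonds, salt bridges, hydrophobic and
## water-mediated contacts).  All criteria are heavy-atom based: the
## crystal structures this package targets carry no hydrogens, so
## donor/acceptor roles follow atom identity and distance only.

#' Van der Waals radii table
#'
#' Standard heavy-atom radii with a 1.4 Angstrom water probe.  Elements
#' without an entry fall back to the carbon radius with a warning.
#'
#' @param probe probe radius, Angstrom.
#' @return `list(radii, probe, fallback)`.
#' @export
radiiTable <- function(probe = 1.4) {
  list(radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90, P = 1.80),
       probe = probe, fallback = 1.70)
}

atomRadii <- function(elements, radii = radiiTable()) {
  r <- radii$radii[elements]
  if (anyNA(r)) {
    warning(sprintf("unknown element(s) %s: using fallback radius %.2f",
                    paste(unique(elements[is.na(r)]), collapse = ", "),
                    radii$fallback))
    r[is.na(r)] <- radii$fallback
  }
  as.numeric(r)
}

## Deterministic near-uniform sphere directions (golden-spiral lattice).
goldenSpiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

## Rotation-invariant canonical frame: principal axes of the coordinate
## cloud with signs fixed by the third moment along each axis (falls back
## to the identity for degenerate/symmetric clouds).
canonicalFrame <- function(xyz) {
  n <- nrow(xyz)
  ctr <- colMeans(xyz)
  if (n < 3) return(list(center = ctr, rot = diag(3)))
  X <- sweep(xyz, 2, ctr)
  C <- crossprod(X) / n
  if (max(abs(C)) < 1e-12) return(list(center = ctr, rot = diag(3)))
  ev <- eigen(C, symmetric = TRUE)
  V <- ev$vectors
  for (k in 1:2) {
    sk <- sum((X %*% V[, k])^3)
    if (abs(sk) > 1e-9 && sk < 0) V[, k] <- -V[, k]
  }
  V[, 3] <- crossProd3(V[, 1], V[, 2])
  list(center = ctr, rot = t(V))
}

sasaCore <- function(xyz, rad, probe, nPoints) {
  n <- nrow(xyz)
  pts <- goldenSpiral(nPoints)
  R <- rad + probe
  areas <- numeric(n)
  ## neighbor lists by extended-radius overlap
  for (i in seq_len(n)) {
    di <- sweep(xyz, 2, xyz[i, ])
    d2 <- rowSums(di^2)
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      pj <- sweep(p, 2, xyz[j, ])
      d2 <- rowSums(pj^2)
      ## points exactly on a neighbor surface (coincident or tangent
      ## spheres) belong to the earlier atom, so duplicates are not
      ## double-counted
      buried <- d2 < R[j]^2 - 1e-9 | (d2 < R[j]^2 + 1e-9 & j < i)
      acc <- acc & !buried
      if (!any(acc)) break
    }
    areas[i] <- 4 * pi * R[i]^2 * sum(acc) / nPoints
  }
  areas
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples each atom's solvent-extended sphere with a deterministic
#' golden-spiral point lattice and counts the points not buried inside any
#' neighbor sphere.  Coordinates are first taken to a canonical principal
#' axis frame, so the result is invariant under rotation and translation
#' of the input.
#'
#' @param atoms atom data.frame (needs element, x, y, z), or an n x 3
#'   matrix with `elements` supplied separately.
#' @param radii a [radiiTable()].
#' @param nPoints sphere sample points per atom (>= 100).
#' @param elements element vector when `atoms` is a bare matrix.
#' @param canonical transform to the canonical frame first (default TRUE).
#' @return numeric vector of per-atom accessible areas (Angstrom^2).
#' @export
sasa <- function(atoms, radii = radiiTable(), nPoints = 960, elements = NULL,
                 canonical = TRUE) {
  if (nPoints < 100) stop("nPoints must be >= 100")
  if (is.matrix(atoms)) {
    xyz <- atoms
    if (is.null(elements)) stop("elements required with a coordinate matrix")
  } else {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    elements <- atoms$element
  }
  rad <- atomRadii(elements, radii)
  if (canonical && nrow(xyz) > 1) {
    fr <- canonicalFrame(xyz)
    xyz <- sweep(xyz, 2, fr$center) %*% t(fr$rot)
  }
  sasaCore(xyz, rad, radii$probe, nPoints)
}

#' Buried solvent-accessible surface area of an interface
#'
#' Computes per-side buried area as SASA(part alone) - SASA(part in
#' complex) and the total as the sum over both sides.  All three SASA
#' evaluations share one canonical frame (derived from the complex), so
#' fully separated parts bury exactly zero area.  Waters must be excluded
#' by the caller.
#'
#' @param partA,partB atom data.frames; an atom may not appear in both.
#' @param radii a [radiiTable()].
#' @param nPoints sphere sample points per atom.
#' @return `list(bsaTotal, bsaPerSide)`.
#' @export
buriedSurfaceArea <- function(partA, partB, radii = radiiTable(),
                              nPoints = 960) {
  a <- if (methods::is(partA, "PlacedCopy")) partA@atoms else partA
  b <- if (methods::is(partB, "PlacedCopy")) partB@atoms else partB
  keyA <- paste(a$x, a$y, a$z)
  keyB <- paste(b$x, b$y, b$z)
  if (any(keyA %in% keyB))
    stop("identical atom present in both parts")
  xyzA <- as.matrix(a[, c("x", "y", "z")])
  xyzB <- as.matrix(b[, c("x", "y", "z")])
  all <- rbind(xyzA, xyzB)
  fr <- canonicalFrame(all)
  tf <- function(m) sweep(m, 2, fr$center) %*% t(fr$rot)
  radA <- atomRadii(a$element, radii)
  radB <- atomRadii(b$element, radii)
  sA <- sasaCore(tf(xyzA), radA, radii$probe, nPoints)
  sB <- sasaCore(tf(xyzB), radB, radii$probe, nPoints)
  sAB <- sasaCore(tf(all), c(radA, radB), radii$probe, nPoints)
  nA <- nrow(a)
  per <- c(A = sum(sA) - sum(sAB[seq_len(nA)]),
           B = sum(sB) - sum(sAB[-seq_len(nA)]))
  list(bsaTotal = sum(per), bsaPerSide = per)
}

.MAINCHAIN <- c("N", "CA", "C", "O", "OXT")
.SC_ACID_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.SC_BASE_N <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                   HIS = c("ND1", "NE2"))

asContactTable <- function(x, label) {
  df <- if (methods::is(x, "PlacedCopy")) x@atoms else x
  df$copy <- label
  df
}

crossDistances <- function(a, b) {
  ## all-pairs distance matrix between two atom tables
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

contactRecord <- function(a, ia, b, ib, kind, dist, site = "unassigned") {
  data.frame(kind = kind,
             copyA = a$copy[ia], resnoA = a$resno[ia], residA = a$resid[ia],
             atomA = a$atom[ia],
             copyB = b$copy[ib], resnoB = b$resno[ib], residB = b$resid[ib],
             atomB = b$atom[ib],
             distance = dist, site = site, stringsAsFactors = FALSE)
}

emptyContacts <- function() {
  data.frame(kind = character(), copyA = character(), resnoA = integer(),
             residA = character(), atomA = character(), copyB = character(),
             resnoB = integer(), residB = character(), atomB = character(),
             distance = numeric(), site = character(), stringsAsFactors = FALSE)
}

#' Hydrogen bonds across an interface
#'
#' Records every nitrogen/oxygen pair across the two parts within `dMax`
#' (and above a 2.2 Angstrom clash floor).  Pairs of main-chain N and
#' main-chain O are flagged `mainchain_hbond`; all others are `hbond`.
#'
#' @param a,b atom tables or [PlacedCopy] objects (different molecules).
#' @param dMax distance cutoff, Angstrom.
#' @param dMin clash floor, Angstrom.
#' @return contact data.frame.
#' @export
findHBonds <- function(a, b, dMax = 3.5, dMin = 2.2) {
  A <- asContactTable(a, "A"); B <- asContactTable(b, "B")
  A <- A[A$element %in% c("N", "O"), , drop = FALSE]
  B <- B[B$element %in% c("N", "O"), , drop = FALSE]
  if (!nrow(A) || !nrow(B)) return(emptyContacts())
  D <- crossDistances(A, B)
  hit <- which(D <= dMax & D >= dMin, arr.ind = TRUE)
  if (!nrow(hit)) return(emptyContacts())
  ## at least one side must be able to donate and the other to accept;
  ## with N and O both dual-role at heavy-atom resolution, any N/O pair
  ## qualifies except O-O pairs where neither is a hydroxyl-like oxygen
  ia <- hit[, 1]; ib <- hit[, 2]
  mc <- A$element[ia] == "N" & A$atom[ia] %in% .MAINCHAIN &
        B$element[ib] == "O" & B$atom[ib] %in% .MAINCHAIN |
        A$element[ia] == "O" & A$atom[ia] %in% .MAINCHAIN &
        B$element[ib] == "N" & B$atom[ib] %in% .MAINCHAIN
  kind <- ifelse(mc, "mainchain_hbond", "hbond")
  out <- contactRecord(A, ia, B, ib, kind, D[hit])
  out[order(out$distance), , drop = FALSE]
}

#' Salt bridges across an interface
#'
#' Asp/Glu side-chain oxygen within `dMax` of Lys/Arg/His side-chain
#' nitrogen, in either orientation.
#'
#' @inheritParams findHBonds
#' @export
findSaltBridges <- function(a, b, dMax = 4.0) {
  A <- asContactTable(a, "A"); B <- asContactTable(b, "B")
  pick <- function(df, table) {
    keep <- rep(FALSE, nrow(df))
    for (res in names(table))
      keep <- keep | (df$resid == res & df$atom %in% table[[res]])
    df[keep, , drop = FALSE]
  }
  one <- function(acidTab, baseTab, flip) {
    ac <- pick(acidTab, .SC_ACID_O)
    ba <- pick(baseTab, .SC_BASE_N)
    if (!nrow(ac) || !nrow(ba)) return(emptyContacts())
    D <- crossDistances(ac, ba)
    hit <- which(D <= dMax, arr.ind = TRUE)
    if (!nrow(hit)) return(emptyContacts())
    if (flip) contactRecord(ba, hit[, 2], ac, hit[, 1], "salt_bridge", D[hit])
    else contactRecord(ac, hit[, 1], ba, hit[, 2], "salt_bridge", D[hit])
  }
  out <- rbind(one(A, B, flip = FALSE), one(B, A, flip = TRUE))
  ## flip = TRUE swapped the tables so copy labels follow the acid; restore
  if (nrow(out)) {
    swap <- out$copyA == "B"
    if (any(swap)) {
      tmp <- out[swap, c("copyB", "resnoB", "residB", "atomB")]
      out[swap, c("copyB", "resnoB", "residB", "atomB")] <-
        out[swap, c("copyA", "resnoA", "residA", "atomA")]
      out[swap, c("copyA", "resnoA", "residA", "atomA")] <- tmp
    }
  }
  out[order(out$distance), , drop = FALSE]
}

#' Hydrophobic contacts across an interface
#'
#' Side-chain carbon/carbon contacts within `dMax`, aggregated per residue
#' pair (closest distance and atom pair reported).
#'
#' @inheritParams findHBonds
#' @export
findHydrophobic <- function(a, b, dMax = 4.5) {
  A <- asContactTable(a, "A"); B <- asContactTable(b, "B")
  A <- A[A$element == "C" & !A$atom %in% .MAINCHAIN, , drop = FALSE]
  B <- B[B$element == "C" & !B$atom %in% .MAINCHAIN, , drop = FALSE]
  if (!nrow(A) || !nrow(B)) return(emptyContacts())
  D <- crossDistances(A, B)
  hit <- which(D <= dMax, arr.ind = TRUE)
  if (!nrow(hit)) return(emptyContacts())
  rec <- contactRecord(A, hit[, 1], B, hit[, 2], "hydrophobic", D[hit])
  key <- paste(rec$resnoA, rec$resnoB)
  rec <- rec[order(key, rec$distance), , drop = FALSE]
  out <- rec[!duplicated(paste(rec$resnoA, rec$resnoB)), , drop = FALSE]
  out[order(out$distance), , drop = FALSE]
}

#' Water-mediated hydrogen bonds across an interface
#'
#' Finds water oxygens bridging hydrogen-bond-capable atoms (N/O) of the
#' two parts: at depth 1 a single water within `dMax` of both sides; at
#' depth 2 additionally chains of two waters within `dMax` of each other,
#' one anchored on each side.
#'
#' @inheritParams findHBonds
#' @param waterAtoms data.frame of water oxygen records.
#' @param depth 1 (single bridging water) or 2 (two-water chains allowed).
#' @export
findWaterMediated <- function(a, b, waterAtoms, dMax = 3.5, depth = 1) {
  A <- asContactTable(a, "A"); B <- asContactTable(b, "B")
  A <- A[A$element %in% c("N", "O"), , drop = FALSE]
  B <- B[B$element %in% c("N", "O"), , drop = FALSE]
  W <- waterAtoms[waterAtoms$element == "O", , drop = FALSE]
  if (!nrow(A) || !nrow(B) || !nrow(W)) return(emptyContacts())
  W$copy <- "W"
  DA <- crossDistances(A, W)
  DB <- crossDistances(W, B)
  out <- emptyContacts()
  for (w in seq_len(nrow(W))) {
    ia <- which(DA[, w] <= dMax)
    ib <- which(DB[w, ] <= dMax)
    if (length(ia) && length(ib)) {
      for (i in ia) for (j in ib) {
        rec <- contactRecord(A, i, B, j, "water_mediated",
                             max(DA[i, w], DB[w, j]))
        rec$water <- paste0(W$resno[w])
        out <- rbind(out, rec)
      }
    }
  }
  if (depth >= 2 && nrow(W) > 1) {
    DW <- crossDistances(W, W)
    for (w1 in seq_len(nrow(W))) for (w2 in seq_len(nrow(W))) {
      if (w1 == w2 || DW[w1, w2] > dMax) next
      ia <- which(DA[, w1] <= dMax)
      ib <- which(DB[w2, ] <= dMax)
      if (length(ia) && length(ib)) {
        for (i in ia) for (j in ib) {
          rec <- contactRecord(A, i, B, j, "water_mediated",
                               max(DA[i, w1], DW[w1, w2], DB[w2, j]))
          rec$water <- paste(W$resno[w1], W$resno[w2])
          out <- rbind(out, rec)
        }
      }
    }
  }
  if (!nrow(out)) return(out)
  out <- out[!duplicated(out[, c("resnoA", "atomA", "resnoB", "atomB")]), ,
             drop = FALSE]
  out[order(out$distance), , drop = FALSE]
}

residueRegion <- function(resno, strandDefs) {
  out <- rep("unassigned", length(resno))
  for (region in names(strandDefs)) {
    rg <- strandDefs[[region]]
    out[resno >= rg[1] & resno <= rg[2]] <- region
  }
  out
}

assignSites <- function(contacts, strandDefs, interfaceKind) {
  if (!nrow(contacts)) return(contacts)
  ra <- residueRegion(contacts$resnoA, strandDefs)
  rb <- residueRegion(contacts$resnoB, strandDefs)
  sheet <- c("b1", "b5", "b3", "b4")
  site <- rep("unassigned", nrow(contacts))
  if (interfaceKind == "head_to_tail") {
    ## Site 2: the beta4/beta3 face against loop beta1-beta2 of the partner;
    ## Site 1: the beta3/loop/beta4 head face against the beta2-beta1-beta5 sheet
    s2 <- (ra == "loop12" & rb %in% c("b3", "b4")) |
          (rb == "loop12" & ra %in% c("b3", "b4"))
    s1 <- (ra %in% c("b3", "loop34", "b4") & rb %in% c("b1", "b2", "b5")) |
          (rb %in% c("b3", "loop34", "b4") & ra %in% c("b1", "b2", "b5"))
    site[s1] <- "site1"
    site[s2] <- "site2"
  } else {
    t1 <- (ra == "loop12" & rb == "loop34") | (rb == "loop12" & ra == "loop34")
    t2 <- (ra == "loop12" & rb %in% sheet) | (rb == "loop12" & ra %in% sheet)
    site[t2] <- "typeII"
    site[t1] <- "typeI"
  }
  contacts$site <- site
  contacts
}

#' Full typed-contact and buried-area fingerprint of an interface
#'
#' Runs every contact detector, computes the buried surface area, and
#' assigns each contact to a site (site1/site2 for head-to-tail
#' interfaces, typeI/typeII for inter-filament contacts) from the
#' beta-strand residue ranges.  The interface kind is detected from the
#' main-chain beta-bridge (>= 2 main-chain H-bonds between the beta4 and
#' beta2 strand ranges) unless given explicitly.
#'
#' @param a,b atom tables or [PlacedCopy] objects.
#' @param strandDefs named list of residue ranges (`b1`, `loop12`, `b2`,
#'   `b3`, `loop34`, `b4`, `b5`), e.g. [defaultStrandDefs()].
#' @param waterAtoms optional water records for water-mediated contacts.
#' @param kind `"auto"`, `"head_to_tail"` or `"interfilament"`.
#' @param nPoints SASA sample points.
#' @param waterDepth chaining depth for water-mediated contacts.
#' @return an [InterfaceReport].
#' @export
interfaceFingerprint <- function(a, b, strandDefs, waterAtoms = NULL,
                                 kind = c("auto", "head_to_tail",
                                          "interfilament"),
                                 nPoints = 960, waterDepth = 1) {
  kind <- match.arg(kind)
  hb <- findHBonds(a, b)
  if (kind == "auto") {
    atabA <- asContactTable(a, "A"); atabB <- asContactTable(b, "B")
    regA <- residueRegion(hb$resnoA, strandDefs)
    regB <- residueRegion(hb$resnoB, strandDefs)
    bridge <- sum(hb$kind == "mainchain_hbond" &
                    ((regA == "b4" & regB == "b2") |
                     (regA == "b2" & regB == "b4")))
    kind <- if (bridge >= 2) "head_to_tail" else "interfilament"
  }
  cts <- rbind(hb, findSaltBridges(a, b), findHydrophobic(a, b))
  if (!is.null(waterAtoms) && nrow(waterAtoms)) {
    wm <- findWaterMediated(a, b, waterAtoms, depth = waterDepth)
    if (nrow(wm)) cts <- rbind(cts, wm[, names(cts), drop = FALSE])
  }
  cts <- assignSites(cts, strandDefs, kind)
  bsa <- if (nrow(cts)) buriedSurfaceArea(a, b, nPoints = nPoints)
         else list(bsaTotal = 0, bsaPerSide = c(A = 0, B = 0))
  methods::new("InterfaceReport", bsaTotal = bsa$bsaTotal,
               bsaPerSide = bsa$bsaPerSide, contacts = cts)
}
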