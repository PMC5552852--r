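## Polymer reconstruction from crystal symmetry: neighborhood expansion,
## head-to-tail edge detection, protofilament assembly and architecture
## classification.

#' Beta-strand residue ranges for supported proteins
#'
#' Named residue ranges (`b1`, `loop12`, `b2`, `b3`, `loop34`, `b4`, `b5`)
#' in author numbering for the mouse and zebrafish Ccd1 DIX domains, and
#' for the synthetic toy subunit.  The Ccd1 ranges follow the
#' secondary-structure annotation of the domain (ubiquitin-like fold:
#' five beta strands, one alpha helix); the beta3-beta4 connection is a
#' five-residue type I beta-turn (mCcd1 439-443, zCcd1 407-411).
#'
#' @param protein `"mCcd1"`, `"zCcd1"` or `"toy"`.
#' @return named list of `c(lo, hi)` integer ranges.
#' @export
defaultStrandDefs <- function(protein = c("toy", "mCcd1", "zCcd1")) {
  protein <- match.arg(protein)
  switch(protein,
    toy = list(b1 = c(1, 3), loop12 = c(4, 6), b2 = c(7, 10),
               b3 = c(11, 14), loop34 = c(15, 16), b4 = c(17, 20),
               b5 = c(21, 24)),
    mCcd1 = list(b1 = c(391, 397), loop12 = c(398, 404), b2 = c(405, 410),
                 b3 = c(430, 438), loop34 = c(439, 443), b4 = c(444, 449),
                 b5 = c(460, 468)),
    zCcd1 = list(b1 = c(359, 365), loop12 = c(366, 372), b2 = c(373, 378),
                 b3 = c(398, 406), loop34 = c(407, 411), b4 = c(412, 417),
                 b5 = c(428, 436)))
}

chainBounds <- function(df) {
  ctr <- c(mean(df$x), mean(df$y), mean(df$z))
  rad <- sqrt(max((df$x - ctr[1])^2 + (df$y - ctr[2])^2 + (df$z - ctr[3])^2))
  list(center = ctr, radius = rad)
}

#' Expand the crystallographic neighborhood of the asymmetric unit
#'
#' Generates every symmetry/lattice copy of every chain whose bounding
#' sphere comes within `radius` of the bounding sphere of any
#' asymmetric-unit chain.  Copies are deduplicated by generator id; the
#' identity copies (the asymmetric-unit chains themselves) are always
#' present.
#'
#' @param structure a [CrystalStructure].
#' @param radius neighborhood radius, Angstrom.
#' @param maxShift lattice search range in each direction.
#' @return named list of [PlacedCopy] (names are generator ids).
#' @export
expandNeighborhood <- function(structure, radius = 60, maxShift = 2L) {
  if (radius <= 0) stop("radius must be positive")
  chains <- chainIds(structure)
  asu <- lapply(chains, function(ch)
    chainBounds(structure@atoms[structure@atoms$chain == ch, , drop = FALSE]))
  shifts <- expand.grid(s1 = -maxShift:maxShift, s2 = -maxShift:maxShift,
                        s3 = -maxShift:maxShift)
  out <- list()
  for (ch in chains) {
    df <- structure@atoms[structure@atoms$chain == ch, , drop = FALSE]
    bb <- chainBounds(df)
    for (op in seq_along(structure@symops)) {
      tr <- opOrthogonal(structure, op, c(0, 0, 0))
      ctr0 <- as.numeric(tr$rot %*% bb$center + tr$trans)
      O <- orthoMatrix(structure@cell)
      for (s in seq_len(nrow(shifts))) {
        sh <- as.integer(shifts[s, ])
        ctr <- ctr0 + as.numeric(O %*% sh)
        near <- any(vapply(asu, function(ref)
          sqrt(sum((ctr - ref$center)^2)) - bb$radius - ref$radius <= radius,
          logical(1)))
        if (!near) next
        copy <- applyOp(structure, ch, op, sh)
        out[[copyId(copy)]] <- copy
      }
    }
  }
  ## deterministic order: source chain, op, shift
  ord <- order(vapply(out, function(p) p@sourceChain, character(1)),
               vapply(out, function(p) p@opIndex, integer(1)),
               vapply(out, function(p) p@shift[1], integer(1)),
               vapply(out, function(p) p@shift[2], integer(1)),
               vapply(out, function(p) p@shift[3], integer(1)))
  out[ord]
}

strandAtoms <- function(copy, range, mainchainOnly = TRUE) {
  df <- copy@atoms
  df <- df[df$resno >= range[1] & df$resno <= range[2], , drop = FALSE]
  if (mainchainOnly) df <- df[df$atom %in% c("N", "O", "C", "CA"), , drop = FALSE]
  df
}

strandDirection <- function(copy, range) {
  ca <- strandAtoms(copy, range)
  ca <- ca[ca$atom == "N" | ca$atom == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  if (nrow(ca) < 2) return(NULL)
  v <- c(ca$x[nrow(ca)] - ca$x[1], ca$y[nrow(ca)] - ca$y[1],
         ca$z[nrow(ca)] - ca$z[1])
  v / sqrt(sum(v^2))
}

#' Detect head-to-tail beta-bridge edges between placed copies
#'
#' A directed edge is emitted from copy `i` to copy `j` when the beta4
#' strand main chain of `i` forms at least `minHbonds` main-chain N...O
#' hydrogen bonds with the beta2 strand main chain of `j`, with parallel
#' strand directionality (positive dot product of the strand direction
#' vectors).  The edge runs tail-end to head-end of the growing filament:
#' `from` engages its beta4 (head face), `to` engages its beta2 (tail
#' face), so a path `A -> B -> C` leaves A's beta2 free (the filament's
#' tail end) and C's beta4 free (the head end).
#'
#' @param copies named list of [PlacedCopy] from [expandNeighborhood()].
#' @param strandDefs residue ranges, see [defaultStrandDefs()].
#' @param dMax hydrogen-bond distance cutoff, Angstrom.
#' @param minHbonds minimum main-chain H-bond count for an edge.
#' @param screen centroid pre-screen distance, Angstrom.
#' @return data.frame with columns from, to, n_mainchain_hbonds.
#' @export
detectHeadToTail <- function(copies, strandDefs, dMax = 3.5, minHbonds = 2L,
                             screen = 80) {
  if (is.null(strandDefs) || is.null(strandDefs$b2) || is.null(strandDefs$b4))
    stop("strandDefs with b2 and b4 ranges required")
  if (is.null(names(copies)))
    names(copies) <- vapply(copies, copyId, character(1))
  ids <- names(copies)
  ctrs <- t(vapply(copies, function(p)
    c(mean(p@atoms$x), mean(p@atoms$y), mean(p@atoms$z)), numeric(3)))
  edges <- data.frame(from = character(), to = character(),
                      n_mainchain_hbonds = integer(), stringsAsFactors = FALSE)
  n <- length(copies)
  for (i in seq_len(n)) {
    b4i <- strandAtoms(copies[[i]], strandDefs$b4)
    diri <- strandDirection(copies[[i]], strandDefs$b4)
    for (j in seq_len(n)) {
      if (i == j) next
      if (sqrt(sum((ctrs[i, ] - ctrs[j, ])^2)) > screen) next
      b2j <- strandAtoms(copies[[j]], strandDefs$b2)
      ## count main-chain N...O bridges between the two strands
      Ni <- b4i[b4i$atom == "N", , drop = FALSE]
      Oi <- b4i[b4i$atom == "O", , drop = FALSE]
      Nj <- b2j[b2j$atom == "N", , drop = FALSE]
      Oj <- b2j[b2j$atom == "O", , drop = FALSE]
      ## no lower distance floor here: a compressed N...O still evidences
      ## the beta bridge
      cnt <- 0L
      if (nrow(Ni) && nrow(Oj)) cnt <- cnt + sum(crossDistances(Ni, Oj) <= dMax)
      if (nrow(Oi) && nrow(Nj)) cnt <- cnt + sum(crossDistances(Oi, Nj) <= dMax)
      if (cnt < minHbonds) next
      dirj <- strandDirection(copies[[j]], strandDefs$b2)
      if (is.null(diri) || is.null(dirj) || sum(diri * dirj) <= 0) next
      edges <- rbind(edges, data.frame(from = ids[i], to = ids[j],
                                       n_mainchain_hbonds = cnt,
                                       stringsAsFactors = FALSE))
    }
  }
  edges
}

minInteratomicDistance <- function(a, b) {
  min(crossDistances(if (methods::is(a, "PlacedCopy")) a@atoms else a,
                     if (methods::is(b, "PlacedCopy")) b@atoms else b))
}

classifyInterfilamentKind <- function(copyA, copyB, strandDefs, cutoff = 4.5) {
  dfA <- copyA@atoms; dfB <- copyB@atoms
  D <- crossDistances(dfA, dfB)
  hit <- which(D <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return("other")
  ra <- residueRegion(dfA$resno[hit[, 1]], strandDefs)
  rb <- residueRegion(dfB$resno[hit[, 2]], strandDefs)
  sheet <- c("b1", "b5", "b3", "b4")
  t1 <- sum((ra == "loop12" & rb == "loop34") | (rb == "loop12" & ra == "loop34"))
  t2 <- sum((ra == "loop12" & rb %in% sheet) | (rb == "loop12" & ra %in% sheet))
  if (t1 == 0 && t2 == 0) return("other")
  if (t1 >= t2) "interfilament_typeI" else "interfilament_typeII"
}

#' Assemble protofilaments from head-to-tail edges
#'
#' Extracts maximal simple paths from the head-to-tail graph (each copy at
#' most one predecessor and one successor; branching is an error), orders
#' them tail to head, then finds inter-filament contacts: copy pairs from
#' distinct protofilaments with any heavy-atom distance within
#' `contactCutoff`, typed as typeI (loop beta1-beta2 against loop
#' beta3-beta4) or typeII (loop beta1-beta2 against the
#' beta1-beta5-beta3-beta4 sheet) by the dominant contact regions.
#' Finally classifies the architecture (see [classifyArchitecture()]).
#'
#' @param copies named list of [PlacedCopy].
#' @param edges head-to-tail edge data.frame from [detectHeadToTail()].
#' @param strandDefs residue ranges for contact typing.
#' @param contactCutoff heavy-atom contact distance, Angstrom.
#' @return a [FilamentModel].
#' @export
buildFilaments <- function(copies, edges, strandDefs = defaultStrandDefs("toy"),
                           contactCutoff = 4.5) {
  if (is.null(names(copies)))
    names(copies) <- vapply(copies, copyId, character(1))
  if (anyDuplicated(edges$from) || anyDuplicated(edges$to)) {
    bad <- c(edges$from[duplicated(edges$from)], edges$to[duplicated(edges$to)])
    stop(sprintf("non-filamentous packing: copy %s has multiple head-to-tail partners",
                 bad[1]))
  }
  nxt <- stats::setNames(edges$to, edges$from)
  protos <- list()
  used <- character()
  starts <- setdiff(edges$from, edges$to)
  walk <- function(s) {
    path <- s
    while (!is.na(nxt[path[length(path)]]) &&
           !(nxt[[path[length(path)]]] %in% path)) {
      path <- c(path, nxt[[path[length(path)]]])
    }
    path
  }
  for (s in sort(starts)) {
    p <- walk(s)
    protos[[length(protos) + 1L]] <- p
    used <- c(used, p)
  }
  ## cycles (closed rings in a finite expansion): break at the smallest id
  remaining <- setdiff(unique(c(edges$from, edges$to)), used)
  while (length(remaining)) {
    s <- sort(remaining)[1]
    p <- walk(s)
    warning("head-to-tail graph contains a cycle; broken at ", s)
    protos[[length(protos) + 1L]] <- p
    used <- c(used, p)
    remaining <- setdiff(remaining, p)
  }
  protos <- mergeBrokenPaths(protos, copies)
  protos <- protos[lengths(protos) >= 2]

  ife <- data.frame(a = character(), b = character(), kind = character(),
                    protoA = integer(), protoB = integer(),
                    stringsAsFactors = FALSE)
  if (length(protos) >= 2) {
    ctrs <- lapply(copies, function(p)
      chainBounds(p@atoms))
    for (pa in seq_len(length(protos) - 1)) {
      for (pb in seq.int(pa + 1, length(protos))) {
        for (ida in protos[[pa]]) for (idb in protos[[pb]]) {
          ba <- ctrs[[ida]]; bb <- ctrs[[idb]]
          if (sqrt(sum((ba$center - bb$center)^2)) - ba$radius - bb$radius >
              contactCutoff) next
          if (minInteratomicDistance(copies[[ida]], copies[[idb]]) >
              contactCutoff) next
          kind <- classifyInterfilamentKind(copies[[ida]], copies[[idb]],
                                            strandDefs, contactCutoff)
          ife <- rbind(ife, data.frame(a = ida, b = idb, kind = kind,
                                       protoA = pa, protoB = pb,
                                       stringsAsFactors = FALSE))
        }
      }
    }
  }
  fm <- methods::new("FilamentModel", copies = copies, protofilaments = protos,
                     edges = edges, interfilamentEdges = ife,
                     architecture = "irregular")
  fm@architecture <- classifyArchitecture(fm)
  fm
}

## Rejoin protofilament fragments split by a single sub-threshold beta
## bridge (a real imperfection mode in noisy or marginally ordered
## lattices): two paths are merged when the head end of one sits in
## contact with the tail end of the other and the junction transform
## matches the filament's own screw step (angle within 10 deg, rise
## within 1.5 A).  Parallel but non-continuing filaments (e.g. lattice
## translates) fail both the contact and the step test.
mergeBrokenPaths <- function(protos, copies, angleTol = 10, riseTol = 1.5,
                             contact = 5) {
  stepOf <- function(idA, idB) {
    pr <- pairCommonResidues(placedCoords(copies[[idA]]),
                             placedCoords(copies[[idB]]))
    fit <- superpose(pr$a, pr$b)
    tryCatch(screwDecompose(fit@rot, fit@trans), error = function(e) NULL)
  }
  touching <- function(idA, idB) {
    ba <- chainBounds(copies[[idA]]@atoms)
    bb <- chainBounds(copies[[idB]]@atoms)
    if (sqrt(sum((ba$center - bb$center)^2)) - ba$radius - bb$radius >
        contact) return(FALSE)
    minInteratomicDistance(copies[[idA]], copies[[idB]]) <= contact
  }
  repeat {
    ## cheap pre-screen: any head end in contact with another path's tail?
    cand <- FALSE
    for (i in seq_along(protos)) {
      for (j in seq_along(protos)) {
        if (i == j) next
        if (touching(protos[[i]][length(protos[[i]])], protos[[j]][1])) {
          cand <- TRUE
          break
        }
      }
      if (cand) break
    }
    if (!cand) return(protos)
    ## reference step: median over all consecutive pairs of current paths
    refs <- list()
    for (p in protos) if (length(p) >= 2)
      for (k in seq_len(length(p) - 1)) {
        s <- stepOf(p[k], p[k + 1])
        if (!is.null(s)) refs[[length(refs) + 1L]] <- s
      }
    if (!length(refs)) return(protos)
    refAngle <- stats::median(vapply(refs, function(s) s@angle, numeric(1)))
    refRise <- stats::median(vapply(refs, function(s) s@rise, numeric(1)))
    merged <- FALSE
    for (i in seq_along(protos)) {
      for (j in seq_along(protos)) {
        if (i == j) next
        u <- protos[[i]][length(protos[[i]])]
        v <- protos[[j]][1]
        if (!touching(u, v)) next
        s <- stepOf(u, v)
        if (is.null(s)) next
        if (abs(s@angle - refAngle) > angleTol ||
            abs(s@rise - refRise) > riseTol) next
        protos[[i]] <- c(protos[[i]], protos[[j]])
        protos[[j]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) return(protos)
  }
}

protoAxis <- function(fm, k) {
  helixParameters(fm, protofilament = k)@axis
}

#' Classify filament architecture
#'
#' Works on the connected component containing the longest protofilament
#' (a crystal lattice may hold several translation-equivalent images of
#' the same filament that never touch).  The component is `"double"` when
#' it holds exactly two protofilaments whose helix axes lie within
#' `axisTol` degrees of parallel and which share at least two
#' inter-filament contact edges per helical turn; `"single"` when the
#' component is one protofilament with no inter-filament partner; anything
#' else is `"irregular"`.
#'
#' @param fm a [FilamentModel].
#' @param axisTol axis parallelism tolerance, degrees.
#' @return `"single"`, `"double"` or `"irregular"`.
#' @export
classifyArchitecture <- function(fm, axisTol = 10) {
  protos <- fm@protofilaments
  if (!length(protos)) return("irregular")
  if (max(lengths(protos)) < 3) return("irregular")
  main <- which.max(lengths(protos))
  ## connected component over the interfilament-edge graph
  comp <- main
  repeat {
    touching <- unique(c(fm@interfilamentEdges$protoB[fm@interfilamentEdges$protoA %in% comp],
                         fm@interfilamentEdges$protoA[fm@interfilamentEdges$protoB %in% comp]))
    grow <- setdiff(touching, comp)
    if (!length(grow)) break
    comp <- c(comp, grow)
  }
  if (length(comp) == 1) return("single")
  if (length(comp) != 2) return("irregular")
  hp <- try(helixParameters(fm, protofilament = main), silent = TRUE)
  if (inherits(hp, "try-error")) return("irregular")
  other <- setdiff(comp, main)
  axA <- hp@axis
  axB <- try(protoAxis(fm, other), silent = TRUE)
  if (inherits(axB, "try-error")) return("irregular")
  ang <- acos(min(1, abs(sum(axA * axB)))) * 180 / pi
  if (ang > axisTol) return("irregular")
  nEdges <- sum((fm@interfilamentEdges$protoA %in% comp) &
                  (fm@interfilamentEdges$protoB %in% comp))
  turns <- max(1e-9, length(protos[[main]]) / hp@subunitsPerTurn)
  if (nEdges / turns >= 2) "double" else "irregular"
}

#' Inter-filament neighbors of one subunit
#'
#' Counts the distinct subunits of the other protofilament within contact
#' distance of `subunitId` and reports each contact's type.
#'
#' @param fm a [FilamentModel] with `"double"` architecture.
#' @param subunitId copy id of the query subunit.
#' @return `list(n, kinds)`: neighbor count and a named character vector
#'   of contact kinds per neighbor id.
#' @export
countInterfilamentNeighbors <- function(fm, subunitId) {
  if (fm@architecture != "double")
    stop("subunit is not part of a double filament")
  e <- fm@interfilamentEdges
  hit <- e$a == subunitId | e$b == subunitId
  if (!any(hit)) return(list(n = 0L, kinds = character()))
  partner <- ifelse(e$a[hit] == subunitId, e$b[hit], e$a[hit])
  kinds <- stats::setNames(e$kind[hit], partner)
  kinds <- kinds[!duplicated(partner)]
  list(n = length(kinds), kinds = kinds)
}
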