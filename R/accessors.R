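## Accessors and show methods.

#' @describeIn chainIds chain labels of a CrystalStructure
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' Chain labels
#'
#' @param x a [CrystalStructure].
#' @return character vector of chain ids in file order.
#' @export
setMethod("chainIds", "CrystalStructure", function(x) unique(x@atoms$chain))

#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' Atom records as a data.frame
#'
#' @param x a [CrystalStructure] or [PlacedCopy].
#' @return data.frame with columns chain, resno, resid, atom, element,
#'   x, y, z, occ, b.
#' @rdname atomTable
#' @export
setMethod("atomTable", "CrystalStructure", function(x) x@atoms)

#' @rdname atomTable
#' @export
setMethod("atomTable", "PlacedCopy", function(x) x@atoms)

#' @export
setGeneric("waters", function(x) standardGeneric("waters"))

#' Water atoms of a structure
#' @param x a [CrystalStructure].
#' @rdname waters
#' @export
setMethod("waters", "CrystalStructure", function(x) x@waters)

#' @export
setGeneric("unitCell", function(x) standardGeneric("unitCell"))

#' Unit-cell parameters (a, b, c, alpha, beta, gamma)
#' @param x a [CrystalStructure].
#' @rdname unitCell
#' @export
setMethod("unitCell", "CrystalStructure", function(x) {
  stats::setNames(x@cell, c("a", "b", "c", "alpha", "beta", "gamma"))
})

#' @export
setGeneric("spaceGroup", function(x) standardGeneric("spaceGroup"))

#' Space-group name
#' @param x a [CrystalStructure].
#' @rdname spaceGroup
#' @export
setMethod("spaceGroup", "CrystalStructure", function(x) x@spaceGroup)

#' @export
setGeneric("symOps", function(x) standardGeneric("symOps"))

#' Symmetry operators (fractional rot/trans pairs)
#' @param x a [CrystalStructure].
#' @rdname symOps
#' @export
setMethod("symOps", "CrystalStructure", function(x) x@symops)

#' @export
setGeneric("copyId", function(x) standardGeneric("copyId"))

#' Generator id of a placed copy
#'
#' The id encodes the generator: source chain, operator index and lattice
#' shift, e.g. `"A:2:+1,0,0"`.
#' @param x a [PlacedCopy].
#' @rdname copyId
#' @export
setMethod("copyId", "PlacedCopy", function(x) {
  sprintf("%s:%d:%+d,%+d,%+d", x@sourceChain, x@opIndex,
          x@shift[1], x@shift[2], x@shift[3])
})

#' @export
setGeneric("architecture", function(x) standardGeneric("architecture"))

#' Architecture label of a filament model
#' @param x a [FilamentModel].
#' @return `"single"`, `"double"` or `"irregular"`.
#' @rdname architecture
#' @export
setMethod("architecture", "FilamentModel", function(x) x@architecture)

#' @export
setGeneric("protofilaments", function(x) standardGeneric("protofilaments"))

#' Protofilaments (ordered copy-id vectors)
#' @param x a [FilamentModel].
#' @rdname protofilaments
#' @export
setMethod("protofilaments", "FilamentModel", function(x) x@protofilaments)

#' @export
setGeneric("filamentCopies", function(x) standardGeneric("filamentCopies"))

#' Placed copies of a filament model
#' @param x a [FilamentModel].
#' @rdname filamentCopies
#' @export
setMethod("filamentCopies", "FilamentModel", function(x) x@copies)

#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))

#' Typed contact records of an interface report
#' @param x an [InterfaceReport].
#' @rdname contacts
#' @export
setMethod("contacts", "InterfaceReport", function(x) x@contacts)

#' @export
setGeneric("bsaTotal", function(x) standardGeneric("bsaTotal"))

#' Total buried surface area (both partners summed)
#' @param x an [InterfaceReport].
#' @rdname bsaTotal
#' @export
setMethod("bsaTotal", "InterfaceReport", function(x) x@bsaTotal)

#' @export
setGeneric("bsaPerSide", function(x) standardGeneric("bsaPerSide"))

#' Buried surface area on each partner
#' @param x an [InterfaceReport].
#' @rdname bsaPerSide
#' @export
setMethod("bsaPerSide", "InterfaceReport", function(x) x@bsaPerSide)

#' @export
setGeneric("percentIdentityOf", function(x) standardGeneric("percentIdentityOf"))

#' Percent identity stored in an aligned pair
#' @param x an [AlignedPair].
#' @rdname percentIdentityOf
#' @export
setMethod("percentIdentityOf", "AlignedPair", function(x) x@identity)

setMethod("show", "CrystalStructure", function(object) {
  at <- object@atoms
  ch <- chainIds(object)
  cat(sprintf("CrystalStructure: %d chain(s), %d atoms, %d waters\n",
              length(ch), nrow(at), nrow(object@waters)))
  cat(sprintf("  space group %s; cell %.2f %.2f %.2f  %.1f %.1f %.1f\n",
              object@spaceGroup, object@cell[1], object@cell[2],
              object@cell[3], object@cell[4], object@cell[5], object@cell[6]))
  for (c1 in ch) {
    r <- range(at$resno[at$chain == c1])
    cat(sprintf("  chain %s: residues %d-%d\n", c1, r[1], r[2]))
  }
  invisible(object)
})

setMethod("show", "PlacedCopy", function(object) {
  cat(sprintf("PlacedCopy %s (%d atoms)\n", copyId(object), nrow(object@atoms)))
  invisible(object)
})

setMethod("show", "HelixParameters", function(object) {
  cat(sprintf(paste0("HelixParameters: rise %.3f A, twist %.3f deg (%s-handed),\n",
                     "  pitch %.2f A, %.3f subunits/turn (%d pairs averaged)\n"),
              object@rise, object@twist, object@handedness, object@pitch,
              object@subunitsPerTurn, object@nPairsAveraged))
  invisible(object)
})

setMethod("show", "ScrewParameters", function(object) {
  cat(sprintf("ScrewParameters: %.4f deg about (%.3f, %.3f, %.3f), rise %.4f A, %s-handed\n",
              object@angle, object@axis[1], object@axis[2], object@axis[3],
              object@rise, object@handedness))
  invisible(object)
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd %.4f A over %d pairs\n",
              object@rmsd, object@nPairs))
  invisible(object)
})

setMethod("show", "FilamentModel", function(object) {
  cat(sprintf("FilamentModel: %s architecture; %d protofilament(s); %d copies\n",
              object@architecture, length(object@protofilaments),
              length(object@copies)))
  if (length(object@protofilaments))
    cat(sprintf("  protofilament sizes: %s\n",
                paste(lengths(object@protofilaments), collapse = ", ")))
  cat(sprintf("  %d head-to-tail edge(s), %d inter-filament edge(s)\n",
              nrow(object@edges), nrow(object@interfilamentEdges)))
  invisible(object)
})

setMethod("show", "InterfaceReport", function(object) {
  cat(sprintf("InterfaceReport: BSA %.1f A^2 total (%.1f + %.1f); %d contact(s)\n",
              object@bsaTotal, object@bsaPerSide[1], object@bsaPerSide[2],
              nrow(object@contacts)))
  if (nrow(object@contacts)) {
    tab <- table(object@contacts$kind)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(object)
})

setMethod("show", "AlignedPair", function(object) {
  cat(sprintf("AlignedPair: %d x %d residues, score %.1f, identity %.1f%%\n",
              nchar(object@seqA), nchar(object@seqB), object@score,
              object@identity))
  invisible(object)
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %s architecture\n", object@architecture))
  show(object@helix)
  invisible(object)
})
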