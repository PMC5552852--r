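## Central S4 containers.
##
## Atom records are kept as a flat data.frame throughout (one row per atom,
## columns chain/resno/resid/atom/element/x/y/z/occ/b), the representation
## used by bio3d and by most structural toolkits.  The classes below wrap
## that table with the crystallographic context (cell, space group,
## symmetry operators) or with derived results.

ATOM_COLS <- c("chain", "resno", "resid", "atom", "element",
               "x", "y", "z", "occ", "b")

emptyAtomTable <- function() {
  data.frame(chain = character(), resno = integer(), resid = character(),
             atom = character(), element = character(),
             x = numeric(), y = numeric(), z = numeric(),
             occ = numeric(), b = numeric(), stringsAsFactors = FALSE)
}

checkAtomTable <- function(df, what = "atoms") {
  if (!is.data.frame(df)) return(sprintf("%s must be a data.frame", what))
  miss <- setdiff(ATOM_COLS, names(df))
  if (length(miss))
    return(sprintf("%s is missing columns: %s", what, paste(miss, collapse = ", ")))
  if (nrow(df)) {
    if (!all(is.finite(df$x)) || !all(is.finite(df$y)) || !all(is.finite(df$z)))
      return(sprintf("%s contains non-finite coordinates", what))
    if (any(df$occ < 0 | df$occ > 1, na.rm = TRUE))
      return(sprintf("%s has occupancies outside [0,1]", what))
    if (any(!nzchar(df$element)))
      return(sprintf("%s has empty element symbols", what))
  }
  TRUE
}

#' CrystalStructure: an asymmetric unit with crystallographic context
#'
#' Holds the polymer atoms of the asymmetric unit, the water oxygens, the
#' unit cell (a, b, c in Angstrom; alpha, beta, gamma in degrees), the
#' space-group name and its symmetry operators in fractional coordinates.
#'
#' @slot atoms data.frame of polymer atom records.
#' @slot waters data.frame of water atom records (same schema).
#' @slot cell numeric(6): a, b, c, alpha, beta, gamma.
#' @slot spaceGroup character scalar, e.g. `"P 21 21 21"`.
#' @slot symops list of `list(rot = 3x3 matrix, trans = numeric(3))`,
#'   fractional-space operators; the first is always the identity.
#' @exportClass CrystalStructure
setClass("CrystalStructure",
  representation(atoms = "data.frame", waters = "data.frame",
                 cell = "numeric", spaceGroup = "character",
                 symops = "list"),
  validity = function(object) {
    msg <- character()
    ok <- checkAtomTable(object@atoms, "atoms")
    if (!isTRUE(ok)) msg <- c(msg, ok)
    ok <- checkAtomTable(object@waters, "waters")
    if (!isTRUE(ok)) msg <- c(msg, ok)
    if (length(object@cell) != 6L || any(!is.finite(object@cell)))
      msg <- c(msg, "cell must be numeric(6)")
    else {
      if (any(object@cell[1:3] <= 0)) msg <- c(msg, "cell edges must be positive")
      if (any(object@cell[4:6] <= 0 | object@cell[4:6] >= 180))
        msg <- c(msg, "cell angles must lie in (0, 180)")
    }
    if (!length(object@symops)) msg <- c(msg, "symops must be non-empty")
    else {
      id <- object@symops[[1L]]
      if (max(abs(id$rot - diag(3))) > 1e-9 || max(abs(id$trans)) > 1e-9)
        msg <- c(msg, "first symop must be the identity")
      for (op in object@symops) {
        if (abs(det(op$rot) - 1) > 1e-6)
          msg <- c(msg, "symop rotations must have det +1")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' PlacedCopy: a symmetry-generated chain instance
#'
#' A chain of the asymmetric unit transformed by a symmetry operator plus an
#' integer lattice shift.  The generator (source chain, operator index,
#' shift) identifies the copy uniquely within an expansion.
#'
#' @slot sourceChain chain label in the asymmetric unit.
#' @slot opIndex 1-based index into the structure's symop list.
#' @slot shift integer(3) lattice translation (unit-cell multiples).
#' @slot atoms transformed atom table.
#' @exportClass PlacedCopy
setClass("PlacedCopy",
  representation(sourceChain = "character", opIndex = "integer",
                 shift = "integer", atoms = "data.frame"),
  validity = function(object) {
    if (length(object@shift) != 3L) return("shift must be integer(3)")
    ok <- checkAtomTable(object@atoms)
    if (!isTRUE(ok)) return(ok)
    TRUE
  })

#' SuperpositionResult: optimal rigid-body fit of paired coordinates
#'
#' @slot rot 3x3 proper rotation applied to the moving set.
#' @slot trans translation (Angstrom) applied after rotation.
#' @slot rmsd root-mean-square deviation after fitting (Angstrom).
#' @slot nPairs number of paired atoms.
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
  representation(rot = "matrix", trans = "numeric", rmsd = "numeric",
                 nPairs = "integer"),
  validity = function(object) {
    if (abs(det(object@rot) - 1) > 1e-9) return("rotation must be proper (det +1)")
    if (object@rmsd < -1e-12) return("rmsd must be non-negative")
    TRUE
  })

#' ScrewParameters: rotation + translation along a common axis
#'
#' Decomposition of a rigid transform into a rotation by `angle` degrees
#' about `axis` combined with a displacement `rise` along it.  The axis sign
#' is chosen so the rise is non-negative; `handedness` is `"right"` when the
#' rotation about that axis (right-hand rule) is positive-sense and
#' `"left"` otherwise.
#'
#' @slot angle rotation magnitude, degrees in (0, 180].
#' @slot axis unit 3-vector.
#' @slot rise displacement along axis, Angstrom (>= 0).
#' @slot handedness `"left"` or `"right"`.
#' @exportClass ScrewParameters
setClass("ScrewParameters",
  representation(angle = "numeric", axis = "numeric", rise = "numeric",
                 handedness = "character"),
  validity = function(object) {
    if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-9) return("axis must be unit-norm")
    if (!object@handedness %in% c("left", "right"))
      return("handedness must be 'left' or 'right'")
    TRUE
  })

#' HelixParameters: per-subunit helical geometry of a protofilament
#'
#' @slot rise mean axial translation per subunit (Angstrom).
#' @slot twist signed mean rotation per subunit (degrees; negative =
#'   left-handed under the right-hand rule about the advance direction).
#' @slot pitch axial length of one full turn, `rise * 360 / |twist|`.
#' @slot subunitsPerTurn `360 / |twist|`.
#' @slot handedness `"left"` or `"right"`.
#' @slot nPairsAveraged number of consecutive-subunit transforms averaged.
#' @slot axis mean helix axis direction (unit vector, orthogonal frame).
#' @exportClass HelixParameters
setClass("HelixParameters",
  representation(rise = "numeric", twist = "numeric", pitch = "numeric",
                 subunitsPerTurn = "numeric", handedness = "character",
                 nPairsAveraged = "integer", axis = "numeric"),
  validity = function(object) {
    if (abs(object@pitch - object@rise * 360 / abs(object@twist)) >
        1e-6 * max(1, abs(object@pitch)))
      return("pitch must equal rise * 360 / |twist|")
    if (abs(object@subunitsPerTurn - 360 / abs(object@twist)) > 1e-9 *
        max(1, object@subunitsPerTurn))
      return("subunitsPerTurn must equal 360 / |twist|")
    TRUE
  })

#' FilamentModel: protofilaments plus inter-filament contacts
#'
#' The result of building head-to-tail filaments from an expanded
#' neighborhood.  Protofilaments are maximal simple paths in the
#' head-to-tail graph, ordered from the free-tail end (exposed beta2 face)
#' to the free-head end (exposed beta4 face).
#'
#' @slot copies named list of [PlacedCopy] objects keyed by copy id.
#' @slot protofilaments list of character vectors of copy ids (>= 2
#'   subunits each), ordered tail to head.
#' @slot edges data.frame of head-to-tail edges (`from` presents beta4,
#'   `to` presents beta2; `n_mainchain_hbonds` records the bridge count).
#' @slot interfilamentEdges data.frame of contacts between distinct
#'   protofilaments with a `kind` column (`interfilament_typeI`,
#'   `interfilament_typeII` or `other`).
#' @slot architecture `"single"`, `"double"` or `"irregular"`.
#' @exportClass FilamentModel
setClass("FilamentModel",
  representation(copies = "list", protofilaments = "list",
                 edges = "data.frame", interfilamentEdges = "data.frame",
                 architecture = "character"))

#' InterfaceReport: buried area and typed contacts for one interface
#'
#' @slot bsaTotal buried solvent-accessible area summed over both partners
#'   (Angstrom^2).
#' @slot bsaPerSide named numeric(2), area buried on each partner.
#' @slot contacts data.frame of typed contact records with a `site` column
#'   assigning each contact to site1/site2 (head-to-tail interfaces) or
#'   typeI/typeII (inter-filament interfaces).
#' @exportClass InterfaceReport
setClass("InterfaceReport",
  representation(bsaTotal = "numeric", bsaPerSide = "numeric",
                 contacts = "data.frame"),
  validity = function(object) {
    if (length(object@bsaPerSide) != 2L) return("bsaPerSide must have length 2")
    if (abs(object@bsaTotal - sum(object@bsaPerSide)) >
        1e-6 * max(1, abs(object@bsaTotal)))
      return("bsaTotal must equal sum(bsaPerSide)")
    TRUE
  })

#' AlignedPair: pairwise global alignment of two amino-acid sequences
#'
#' @slot seqA,seqB the input sequences.
#' @slot alignedA,alignedB gapped strings of equal length.
#' @slot score alignment score (substitution matrix minus affine gap costs).
#' @slot identity percent identity over aligned (gap-free) columns.
#' @slot pairs integer matrix (n x 2) of 1-based residue indices paired at
#'   gap-free columns.
#' @exportClass AlignedPair
setClass("AlignedPair",
  representation(seqA = "character", seqB = "character",
                 alignedA = "character", alignedB = "character",
                 score = "numeric", identity = "numeric", pairs = "matrix"),
  validity = function(object) {
    if (nchar(object@alignedA) != nchar(object@alignedB))
      return("gapped strings must have equal length")
    if (object@identity < 0 || object@identity > 100)
      return("identity must lie in [0, 100]")
    TRUE
  })

#' FilamentSpec: parameters of a synthetic helical assembly
#'
#' See [filamentSpec()] for construction and defaults.
#'
#' @slot rise,twist per-subunit screw step (Angstrom, signed degrees).
#' @slot nSubunits subunits per protofilament in the asymmetric unit.
#' @slot secondStrand numeric(2) `(phase degrees, axial offset Angstrom)`
#'   of an intertwined second protofilament, or length 0 for single.
#' @slot noiseSigma isotropic Gaussian coordinate noise (Angstrom).
#' @slot seed integer seed controlling the subunit template and the noise.
#' @slot cellPadding padding added around the assembly in a and b (Angstrom).
#' @slot nRes residues in the toy subunit template.
#' @slot waters logical, plant bridging waters at head-to-tail interfaces.
#' @exportClass FilamentSpec
setClass("FilamentSpec",
  representation(rise = "numeric", twist = "numeric", nSubunits = "integer",
                 secondStrand = "numeric", noiseSigma = "numeric",
                 seed = "integer", cellPadding = "numeric", nRes = "integer",
                 waters = "logical"),
  validity = function(object) {
    if (object@twist == 0) return("twist must be non-zero")
    if (object@nSubunits < 3L) return("nSubunits must be >= 3")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    if (!length(object@secondStrand) %in% c(0L, 2L))
      return("secondStrand must be numeric(0) or numeric(2)")
    TRUE
  })

#' GroundTruth: exact generating parameters of a synthetic assembly
#'
#' @slot helix noise-free [HelixParameters] of the generated filament.
#' @slot architecture `"single"` or `"double"`.
#' @slot plantedContacts data.frame describing the engineered interface
#'   contacts (kind, residues, atoms, exact distance).
#' @slot spec the generating [FilamentSpec].
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(helix = "HelixParameters", architecture = "character",
                 plantedContacts = "data.frame", spec = "FilamentSpec"))
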