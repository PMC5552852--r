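## Reading and writing crystal structures, coordinate selection, and
## symmetry transforms.

## Supported space groups, operators transcribed from International Tables
## conventions (rotations in fractional space, translations in cell
## fractions).  P1 covers synthetic fixtures; P 21 21 21 and P 61 cover the
## orthorhombic and hexagonal crystal forms of the Ccd1 DIX domains.
.SG_OPS <- list(
  "P 1" = list(
    list(rot = diag(3), trans = c(0, 0, 0))
  ),
  "P 21 21 21" = list(
    list(rot = diag(3), trans = c(0, 0, 0)),
    list(rot = diag(c(-1, -1, 1)), trans = c(1/2, 0, 1/2)),
    list(rot = diag(c(-1, 1, -1)), trans = c(0, 1/2, 1/2)),
    list(rot = diag(c(1, -1, -1)), trans = c(1/2, 1/2, 0))
  ),
  "P 61" = list(
    list(rot = diag(3), trans = c(0, 0, 0)),
    list(rot = matrix(c(0, 1, 0, -1, -1, 0, 0, 0, 1), 3, 3), trans = c(0, 0, 1/3)),
    list(rot = matrix(c(-1, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3), trans = c(0, 0, 2/3)),
    list(rot = matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3), trans = c(0, 0, 1/2)),
    list(rot = matrix(c(0, -1, 0, 1, 1, 0, 0, 0, 1), 3, 3), trans = c(0, 0, 5/6)),
    list(rot = matrix(c(1, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3), trans = c(0, 0, 1/6))
  )
)

normalizeSpaceGroup <- function(name) {
  key <- toupper(gsub("[[:space:]_]", "", name))
  hit <- match(key, gsub("[[:space:]]", "", names(.SG_OPS)))
  if (is.na(hit))
    stop(sprintf("unsupported space group '%s'; supported groups: %s",
                 name, paste(names(.SG_OPS), collapse = ", ")))
  names(.SG_OPS)[hit]
}

#' Symmetry operators of a supported space group
#'
#' Operators are given in fractional coordinates as `list(rot, trans)`
#' pairs; the first is always the identity.  Supported groups are
#' `P 1`, `P 21 21 21` and `P 61`.
#'
#' @param name space-group symbol (spacing and underscores ignored).
#' @return list of operators.
#' @export
spaceGroupOps <- function(name) .SG_OPS[[normalizeSpaceGroup(name)]]

## PDB convention orthogonalization matrix: a along x, b in the xy plane.
orthoMatrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c * cos(be),
           0, b * sin(ga), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, c * v / sin(ga)),
         nrow = 3, byrow = TRUE)
}

.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

elementFromName <- function(atom, resid) {
  ## strip digits/primes, take the leading letters; two-letter elements in
  ## protein/water context are rare (SE in selenomethionine)
  nm <- toupper(gsub("[^A-Za-z]", "", atom))
  el <- substr(nm, 1, 1)
  el[nm %in% c("SE", "SED") | substr(nm, 1, 2) == "SE" & resid == "MSE"] <- "SE"
  el
}

resolveAltloc <- function(df, alt, what = "atoms") {
  if (is.null(alt)) return(df)
  alt[is.na(alt)] <- ""
  if (!any(nzchar(alt))) return(df)
  ## keep highest-occupancy conformer; ties broken by altloc label order
  key <- paste(df$chain, df$resno, df$atom, sep = "\r")
  ord <- order(key, -df$occ, alt)
  df2 <- df[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  df2[keep, , drop = FALSE][order(which(keep)), , drop = FALSE]
}

readPdbStructure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl))
    stop(sprintf("'%s' has no CRYST1 record (unit cell and space group required)",
                 path))
  cl <- cl[1]
  cell <- as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33),
                       substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54)))
  sg <- trimws(substr(cl, 56, 66))
  if (!nzchar(sg)) stop(sprintf("'%s' CRYST1 record has no space-group symbol", path))
  p <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  a <- p$atom
  df <- data.frame(chain = as.character(a$chain), resno = as.integer(a$resno),
                   resid = as.character(a$resid), atom = as.character(a$elety),
                   element = ifelse(is.na(a$elesy) | !nzchar(a$elesy),
                                    NA_character_, toupper(as.character(a$elesy))),
                   x = a$x, y = a$y, z = a$z,
                   occ = ifelse(is.na(a$o), 1, a$o),
                   b = ifelse(is.na(a$b), 0, a$b),
                   stringsAsFactors = FALSE)
  bad <- is.na(df$element)
  df$element[bad] <- elementFromName(df$atom[bad], df$resid[bad])
  df <- resolveAltloc(df, a$alt)
  isw <- df$resid %in% .WATER_NAMES
  newCrystalStructure(df[!isw, , drop = FALSE], df[isw, , drop = FALSE], cell, sg)
}

## Minimal mmCIF reader for the atom_site/cell/symmetry categories this
## package writes and that deposited entries share.  bio3d's CIF reader
## does not expose the cell or the space group, which the expansion needs.
readCifStructure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getItem <- function(tag) {
    hit <- grep(paste0("^", tag, "[[:space:]]"), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    val <- trimws(sub(paste0("^", tag), "", hit[1]))
    gsub("^['\"]|['\"]$", "", val)
  }
  cell <- as.numeric(c(getItem("_cell.length_a"), getItem("_cell.length_b"),
                       getItem("_cell.length_c"), getItem("_cell.angle_alpha"),
                       getItem("_cell.angle_beta"), getItem("_cell.angle_gamma")))
  if (any(is.na(cell)))
    stop(sprintf("'%s' lacks complete _cell records", path))
  sg <- getItem("_symmetry.space_group_name_H-M")
  if (is.na(sg)) sg <- getItem("_space_group.name_H-M_alt")
  if (is.na(sg)) stop(sprintf("'%s' lacks a space-group record", path))

  ## locate the atom_site loop
  starts <- grep("^loop_", lines)
  atomLoop <- NULL
  for (s in starts) {
    j <- s + 1
    fields <- character()
    while (j <= length(lines) && grepl("^_", lines[j])) {
      fields <- c(fields, trimws(lines[j])); j <- j + 1
    }
    if (any(grepl("^_atom_site\\.", fields))) {
      k <- j
      while (k <= length(lines) && !grepl("^(loop_|_|#)", lines[k]) &&
             nzchar(trimws(lines[k]))) k <- k + 1
      atomLoop <- list(fields = fields, rows = lines[j:(k - 1)])
      break
    }
  }
  if (is.null(atomLoop)) stop(sprintf("'%s' has no _atom_site loop", path))
  f <- sub("^_atom_site\\.", "", atomLoop$fields)
  mat <- do.call(rbind, strsplit(trimws(atomLoop$rows), "[[:space:]]+"))
  col <- function(name, alt = NULL) {
    i <- match(name, f)
    if (is.na(i) && !is.null(alt)) i <- match(alt, f)
    if (is.na(i)) return(NULL)
    v <- mat[, i]
    v[v %in% c(".", "?")] <- NA
    v
  }
  grp <- col("group_PDB")
  df <- data.frame(
    chain = as.character(col("auth_asym_id", "label_asym_id")),
    resno = as.integer(col("auth_seq_id", "label_seq_id")),
    resid = as.character(col("auth_comp_id", "label_comp_id")),
    atom = gsub('"', "", as.character(col("auth_atom_id", "label_atom_id"))),
    element = toupper(as.character(col("type_symbol"))),
    x = as.numeric(col("Cartn_x")), y = as.numeric(col("Cartn_y")),
    z = as.numeric(col("Cartn_z")),
    occ = as.numeric(col("occupancy")), b = as.numeric(col("B_iso_or_equiv")),
    stringsAsFactors = FALSE)
  df$occ[is.na(df$occ)] <- 1
  df$b[is.na(df$b)] <- 0
  bad <- is.na(df$element) | !nzchar(df$element)
  df$element[bad] <- elementFromName(df$atom[bad], df$resid[bad])
  df <- resolveAltloc(df, col("label_alt_id"))
  isw <- df$resid %in% .WATER_NAMES
  newCrystalStructure(df[!isw, , drop = FALSE], df[isw, , drop = FALSE], cell, sg)
}

newCrystalStructure <- function(atoms, waters, cell, spaceGroup) {
  sg <- normalizeSpaceGroup(spaceGroup)
  methods::new("CrystalStructure", atoms = atoms, waters = waters,
               cell = as.numeric(cell), spaceGroup = sg,
               symops = .SG_OPS[[sg]])
}

#' Read a crystal structure with crystallographic context
#'
#' Parses a PDB or mmCIF file into a [CrystalStructure].  Water molecules
#' are separated from the polymer chains; alternate locations are resolved
#' to the highest-occupancy conformer (ties broken by altloc label order).
#' Missing unit-cell or space-group records are a hard error, as is an
#' unsupported space group.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return a [CrystalStructure].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (format == "pdb") readPdbStructure(path) else readCifStructure(path)
}

formatPdbAtomName <- function(atom, element) {
  ## single-letter elements are right-justified into column 14
  ifelse(nchar(atom) >= 4, substr(atom, 1, 4),
         ifelse(nchar(element) == 1, sprintf(" %-3s", atom),
                sprintf("%-4s", atom)))
}

writePdbStructure <- function(structure, path) {
  cell <- structure@cell
  out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                 cell[1], cell[2], cell[3], cell[4], cell[5], cell[6],
                 structure@spaceGroup, length(structure@symops))
  fmtAtoms <- function(df, record, serial0) {
    if (!nrow(df)) return(character())
    sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, (serial0 + seq_len(nrow(df)) - 1) %% 100000,
            formatPdbAtomName(df$atom, df$element), "",
            df$resid, df$chain, df$resno, "",
            df$x, df$y, df$z, df$occ, df$b, df$element)
  }
  out <- c(out, fmtAtoms(structure@atoms, "ATOM", 1L),
           fmtAtoms(structure@waters, "HETATM", nrow(structure@atoms) + 1L),
           "END")
  writeLines(out, path)
  invisible(path)
}

writeCifStructure <- function(structure, path) {
  cell <- structure@cell
  hdr <- c("data_dixpol",
           "#",
           sprintf("_cell.length_a    %.4f", cell[1]),
           sprintf("_cell.length_b    %.4f", cell[2]),
           sprintf("_cell.length_c    %.4f", cell[3]),
           sprintf("_cell.angle_alpha %.4f", cell[4]),
           sprintf("_cell.angle_beta  %.4f", cell[5]),
           sprintf("_cell.angle_gamma %.4f", cell[6]),
           sprintf("_symmetry.space_group_name_H-M '%s'", structure@spaceGroup),
           "#",
           "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "auth_atom_id",
                    "auth_comp_id", "auth_asym_id", "auth_seq_id",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv")))
  rows <- function(df, record, serial0) {
    if (!nrow(df)) return(character())
    sprintf("%-6s %d %s %s %s %s %d %.3f %.3f %.3f %.2f %.2f",
            record, serial0 + seq_len(nrow(df)) - 1, df$element, df$atom,
            df$resid, df$chain, df$resno, df$x, df$y, df$z, df$occ, df$b)
  }
  writeLines(c(hdr, rows(structure@atoms, "ATOM", 1L),
               rows(structure@waters, "HETATM", nrow(structure@atoms) + 1L),
               "#"), path)
  invisible(path)
}

#' Write a crystal structure to PDB or mmCIF
#'
#' @param structure a [CrystalStructure].
#' @param path output path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @export
writeStructure <- function(structure, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  if (format == "pdb") writePdbStructure(structure, path)
  else writeCifStructure(structure, path)
}

#' Select ordered coordinates from one chain
#'
#' Returns an ordered coordinate set for superposition and geometry:
#' a data.frame with columns `resno`, `atom`, `element`, `x`, `y`, `z`,
#' ordered by residue number.  Residues requested but absent from the model
#' are skipped and reported in the `"missing"` attribute.
#'
#' @param structure a [CrystalStructure] or [PlacedCopy].
#' @param chainId chain label (ignored for a [PlacedCopy]).
#' @param residueRange inclusive `c(lo, hi)` in author numbering, or NULL
#'   for the whole chain.
#' @param atomFilter `"CA"` (alpha carbons), `"backbone"` (N, CA, C, O) or
#'   `"all"`.
#' @return coordinate data.frame; attribute `"missing"` lists skipped
#'   residue numbers.
#' @export
selectCoords <- function(structure, chainId = NULL, residueRange = NULL,
                         atomFilter = c("CA", "backbone", "all")) {
  atomFilter <- match.arg(atomFilter)
  df <- atomTable(structure)
  if (!is.null(chainId)) {
    if (!chainId %in% df$chain)
      stop(sprintf("chain '%s' not present", chainId))
    df <- df[df$chain == chainId, , drop = FALSE]
  }
  missing <- integer()
  if (!is.null(residueRange)) {
    wanted <- seq.int(residueRange[1], residueRange[2])
    missing <- setdiff(wanted, unique(df$resno))
    df <- df[df$resno %in% wanted, , drop = FALSE]
  }
  df <- switch(atomFilter,
               CA = df[df$atom == "CA", , drop = FALSE],
               backbone = df[df$atom %in% c("N", "CA", "C", "O"), , drop = FALSE],
               all = df)
  if (!nrow(df)) stop("empty coordinate selection")
  df <- df[order(df$resno, match(df$atom, c("N", "CA", "C", "O"))), , drop = FALSE]
  out <- df[, c("resno", "atom", "element", "x", "y", "z")]
  rownames(out) <- NULL
  attr(out, "missing") <- missing
  out
}

coordMatrix <- function(cs) as.matrix(cs[, c("x", "y", "z")])

transformAtoms <- function(df, rotOrth, transOrth) {
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rotOrth)
  df$x <- xyz[, 1] + transOrth[1]
  df$y <- xyz[, 2] + transOrth[2]
  df$z <- xyz[, 3] + transOrth[3]
  df
}

## orthogonal-frame rotation/translation realizing symop + lattice shift
opOrthogonal <- function(structure, opIndex, latticeShift) {
  op <- structure@symops[[opIndex]]
  O <- orthoMatrix(structure@cell)
  Oi <- solve(O)
  rot <- O %*% op$rot %*% Oi
  trans <- as.numeric(O %*% (op$trans + latticeShift))
  list(rot = rot, trans = trans)
}

#' Apply a symmetry operator plus lattice shift to one chain
#'
#' Coordinates are taken to fractional space, transformed by the operator
#' and the integer lattice shift, and returned to the orthogonal frame.
#' The returned copy records its generator.
#'
#' @param structure a [CrystalStructure].
#' @param chainId chain label.
#' @param opIndex 1-based index into `symOps(structure)`.
#' @param latticeShift integer(3) unit-cell translation.
#' @return a [PlacedCopy].
#' @export
applyOp <- function(structure, chainId, opIndex, latticeShift = c(0L, 0L, 0L)) {
  if (opIndex < 1L || opIndex > length(structure@symops))
    stop(sprintf("opIndex %d out of range (structure has %d operators)",
                 opIndex, length(structure@symops)))
  if (!chainId %in% structure@atoms$chain)
    stop(sprintf("chain '%s' not present", chainId))
  df <- structure@atoms[structure@atoms$chain == chainId, , drop = FALSE]
  tr <- opOrthogonal(structure, opIndex, latticeShift)
  methods::new("PlacedCopy", sourceChain = chainId, opIndex = as.integer(opIndex),
               shift = as.integer(latticeShift),
               atoms = transformAtoms(df, tr$rot, tr$trans))
}

placedCoords <- function(copy, atomFilter = "CA") {
  selectCoords(copy, atomFilter = atomFilter)
}
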