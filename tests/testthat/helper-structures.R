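# Small structure fixtures built in code.

# A handful of atoms in a P 21 21 21 cell.
newP212121Cell <- function() {
  at <- data.frame(chain = "A", resno = 1:3, resid = "ALA",
                   atom = "CA", element = "C",
                   x = c(3, 6, 5), y = c(2, 4, 8), z = c(1, 3, 6),
                   occ = 1, b = 0, stringsAsFactors = FALSE)
  dixpol:::newCrystalStructure(at, dixpol:::emptyAtomTable(),
                               c(30, 35, 40, 90, 90, 90), "P 21 21 21")
}

# Rebuild a structure whose chain A coordinates come from a placed copy
# (keeps the original cell and symmetry).
structureFromCopy <- function(structure, copy) {
  at <- atomTable(copy)
  at$chain <- "A"
  dixpol:::newCrystalStructure(at, structure@waters, structure@cell,
                               structure@spaceGroup)
}
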