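## Pairwise global alignment, percent identity and residue-pairing maps
## for cross-species superposition.  The dynamic-programming engine is
## Biostrings::pairwiseAlignment (Needleman-Wunsch with affine gaps and a
## BLOSUM62 substitution matrix); this module owns the identity
## bookkeeping and the author-numbering pairing maps built on top of it.

.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

checkSequence <- function(s, what) {
  ch <- strsplit(toupper(s), "")[[1]]
  if (!length(ch)) stop(sprintf("%s is empty", what))
  bad <- setdiff(ch, .AA_ALPHABET)
  if (length(bad))
    stop(sprintf("%s contains invalid characters: %s", what,
                 paste(unique(bad), collapse = ", ")))
  paste(ch, collapse = "")
}

#' Global pairwise alignment of two amino-acid sequences
#'
#' Optimal Needleman-Wunsch alignment with affine gap penalties
#' (BLOSUM62 scores, gap open 10, gap extend 0.5 by default, both charged
#' as positive costs).
#'
#' @param a,b amino-acid strings (standard 20-letter alphabet).
#' @param gapOpen,gapExtend affine gap costs (positive).
#' @param substitutionMatrix scoring matrix name understood by Biostrings
#'   (default `"BLOSUM62"`).
#' @return an [AlignedPair].
#' @export
globalAlign <- function(a, b, gapOpen = 10, gapExtend = 0.5,
                        substitutionMatrix = "BLOSUM62") {
  a <- checkSequence(a, "sequence a")
  b <- checkSequence(b, "sequence b")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpen, gapExtension = gapExtend, type = "global")
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  nongap <- ca != "-" & cb != "-"
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  pairs <- cbind(a = ia[nongap], b = ib[nongap])
  ident <- if (any(nongap)) 100 * mean(ca[nongap] == cb[nongap]) else 0
  methods::new("AlignedPair", seqA = a, seqB = b, alignedA = ga,
               alignedB = gb, score = Biostrings::score(pa),
               identity = ident, pairs = pairs)
}

#' Percent identity of an aligned pair under a chosen denominator
#'
#' @param pair an [AlignedPair].
#' @param denominator `"aligned_columns"` (gap-free columns),
#'   `"shorter_seq"` or `"alignment_length"`.
#' @return percent identity in `[0, 100]`.
#' @export
percentIdentity <- function(pair,
                            denominator = c("aligned_columns", "shorter_seq",
                                            "alignment_length")) {
  denominator <- match.arg(denominator)
  ca <- strsplit(pair@alignedA, "")[[1]]
  cb <- strsplit(pair@alignedB, "")[[1]]
  nongap <- ca != "-" & cb != "-"
  nid <- sum(ca[nongap] == cb[nongap])
  den <- switch(denominator,
                aligned_columns = sum(nongap),
                shorter_seq = min(nchar(pair@seqA), nchar(pair@seqB)),
                alignment_length = length(ca))
  if (den == 0) return(0)
  100 * nid / den
}

#' Author-numbered residue pairing from an alignment
#'
#' Maps the gap-free alignment columns onto author residue numbers for CA
#' superposition across species.
#'
#' @param pair an [AlignedPair].
#' @param numberingA,numberingB author residue numbers, one per residue of
#'   the respective sequence.
#' @return integer matrix (n x 2) of paired author numbers; attribute
#'   `"n"` carries the pair count.
#' @export
residuePairing <- function(pair, numberingA, numberingB) {
  if (length(numberingA) != nchar(pair@seqA))
    stop("numberingA length does not match sequence a")
  if (length(numberingB) != nchar(pair@seqB))
    stop("numberingB length does not match sequence b")
  out <- cbind(a = numberingA[pair@pairs[, "a"]],
               b = numberingB[pair@pairs[, "b"]])
  attr(out, "n") <- nrow(out)
  out
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFastaSequences <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(s), names(s))
}
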