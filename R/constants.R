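# Shared sequence alphabets, the frozen BLOSUM62 table, and codon helpers.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter residue codes. `X` is accepted everywhere as
#' the ambiguity code; non-standard residues (B, Z, U, O) are mapped to `X`
#' on input.
#' @export
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# hydrophobic set used by the signal-peptide heuristic
AA_HYDROPHOBIC <- c("A", "I", "L", "M", "F", "V", "W", "C")

# the four canonical prohormone-convertase dibasic dyads
DYADS <- c("KR", "RK", "RR", "KK")

#' BLOSUM62 substitution matrix
#'
#' Frozen copy of the standard BLOSUM62 log-odds matrix over the 20 standard
#' residues plus `X`. Used by the affine-gap aligner.
#' @format integer matrix, 21 x 21, dimnames are residue letters.
#' @export
BLOSUM62 <- local({
  letters21 <- c("A","R","N","D","C","Q","E","G","H","I","L",
                 "K","M","F","P","S","T","W","Y","V","X")
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,-1,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,-1,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-2,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,-1,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,-1,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,-1,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-1,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,-1,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2, 0,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-2,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-1,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-1,
     0,-1,-1,-1,-2,-1,-1,-1,-1,-1,-1,-1,-1,-1,-2, 0, 0,-2,-1,-1,-1)
  m <- matrix(as.integer(v), nrow = 21, byrow = TRUE,
              dimnames = list(letters21, letters21))
  m
})

# standard genetic code as a named character vector codon -> residue
# (taken from Biostrings at load time; '*' marks stop)
.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# residue -> character vector of synonymous codons
.codon_table <- function() {
  gc <- .genetic_code()
  split(names(gc), unname(gc))
}

#' Translate a coding sequence
#'
#' Translates a nucleotide string with the standard genetic code. Codons
#' containing characters outside ACGT translate to `X`; stop codons
#' translate to `*`.
#'
#' @param cds nucleotide string, length a multiple of 3.
#' @return amino-acid string.
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("cds length (", n, ") is not a multiple of 3")
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  gc <- .genetic_code()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

# split an aa string into single characters
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# split a cds into codon triplets
.codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}
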