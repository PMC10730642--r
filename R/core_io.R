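# Reading/writing FASTA and annotation tables; the precursor record model.

TAXONOMY_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' Construct a table of precursor records
#'
#' The unit of analysis is one candidate neuropeptide precursor: an
#' identifier, its amino-acid sequence, an optional coding sequence, and
#' optional source metadata (species, claimed family). Records are held as a
#' data.frame of class `precursor_records`.
#'
#' @param record_id character vector of unique identifiers.
#' @param aa_seq amino-acid sequences (20 standard letters plus `X`).
#' @param cds_seq optional coding sequences (`NA` where absent). When
#'   present, the length must be a multiple of 3 and the translation must
#'   equal `aa_seq` (a trailing stop codon is allowed).
#' @param species,family_claim optional metadata (`NA` where absent).
#' @return a `precursor_records` data.frame.
#' @export
precursor_records <- function(record_id, aa_seq, cds_seq = NA_character_,
                              species = NA_character_,
                              family_claim = NA_character_) {
  record_id <- as.character(record_id)
  aa_seq <- toupper(as.character(aa_seq))
  n <- length(record_id)
  stopifnot(length(aa_seq) == n)
  cds_seq <- rep_len(toupper(as.character(cds_seq)), n)
  species <- rep_len(as.character(species), n)
  family_claim <- rep_len(as.character(family_claim), n)

  dup <- record_id[duplicated(record_id)]
  if (length(dup))
    stop("duplicate record_id: ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(aa_seq)))
    stop("empty aa_seq for record(s): ",
         paste(record_id[!nzchar(aa_seq)], collapse = ", "))

  bad <- vapply(aa_seq, function(s)
    any(!.chars(s) %in% c(AA_STANDARD, "X")), logical(1))
  if (any(bad))
    stop("non-standard residues in record(s): ",
         paste(record_id[bad], collapse = ", "),
         " (map with normalize_residues() first)")

  for (i in seq_len(n)) {
    if (!is.na(cds_seq[i])) {
      tr <- translate_cds(cds_seq[i])
      tr_nostop <- sub("\\*$", "", tr)
      if (!identical(tr, aa_seq[i]) && !identical(tr_nostop, aa_seq[i]))
        stop("cds_seq of record '", record_id[i],
             "' does not translate to its aa_seq")
    }
  }

  out <- data.frame(record_id = record_id, aa_seq = aa_seq,
                    cds_seq = cds_seq, species = species,
                    family_claim = family_claim,
                    stringsAsFactors = FALSE)
  class(out) <- c("precursor_records", "data.frame")
  out
}

#' Map non-standard residues to X
#'
#' Replaces B, Z, U, O (and any other non-standard letter) with `X`,
#' warning once per call. Motif rules downstream are defined only on the
#' standard alphabet.
#'
#' @param aa_seq character vector of amino-acid strings.
#' @return character vector with only standard letters plus `X`.
#' @export
normalize_residues <- function(aa_seq) {
  aa_seq <- toupper(aa_seq)
  out <- vapply(aa_seq, function(s) {
    ch <- .chars(s)
    bad <- !(ch %in% c(AA_STANDARD, "X"))
    if (any(bad)) ch[bad] <- "X"
    paste0(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  if (any(out != aa_seq))
    warning("non-standard residues mapped to X in ",
            sum(out != aa_seq), " sequence(s)")
  out
}

#' Read amino-acid FASTA into precursor records
#'
#' The header token before the first whitespace becomes `record_id`.
#' Sequences are uppercased, a trailing `*` (stop) is stripped, and
#' non-standard residues are mapped to `X` with a warning.
#'
#' @param path path to a FASTA file.
#' @return a `precursor_records` data.frame (zero rows for an empty file).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(precursor_records(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate record_id in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  seqs <- normalize_residues(seqs)
  precursor_records(ids, seqs)
}

#' Write precursor records to FASTA
#'
#' Sequences are wrapped at 60 columns. `read_fasta(write_fasta(x))`
#' round-trips on (id, sequence).
#'
#' @param records a `precursor_records` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (nrow(records) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(setNames(records$aa_seq, records$record_id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write named nucleotide/aa sequences to FASTA
#' @param seqs named character vector of sequences (gaps allowed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_strings <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a taxonomy/annotation table
#'
#' Tab-separated with a header; must contain `record_id`. Rank columns
#' (`phylum`, `class`, `order`, `family`, `genus`, `species`) and
#' `family_claim` are optional; absent ranks are filled with empty strings
#' so every table exposes the full ordered lineage.
#'
#' @param path path to a TSV file.
#' @return data.frame with `record_id`, the six rank columns, `family_claim`.
#' @export
read_annotation_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  if (!"record_id" %in% names(tab))
    stop("annotation table ", path, " lacks a 'record_id' column")
  dup <- tab$record_id[duplicated(tab$record_id)]
  if (length(dup))
    stop("duplicate record_id in annotation table: ",
         paste(unique(dup), collapse = ", "))
  for (r in TAXONOMY_RANKS)
    if (!r %in% names(tab)) tab[[r]] <- ""
  if (!"family_claim" %in% names(tab)) tab$family_claim <- ""
  tab[is.na(tab)] <- ""
  tab[, c("record_id", TAXONOMY_RANKS, "family_claim")]
}

#' Write an annotation table
#' @param tab data.frame as returned by [read_annotation_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.precursor_records <- function(x, ...) {
  cat("precursor_records: ", nrow(x), " record(s)\n", sep = "")
  NextMethod()
}
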