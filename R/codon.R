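# Codon-level view of a protein alignment, conserved-codon-block detection,
# and fusion of blocks into virtual precursors (NPPs) as postulated by the
# DNA loss model.

#' Back-map a protein alignment onto codons
#'
#' Each aligned amino-acid column becomes one codon column; protein gaps
#' become codon gaps (`---`). Stripping gaps from any row reproduces its
#' coding sequence.
#'
#' @param aa_alignment named character vector of gapped amino-acid rows
#'   (as returned by [progressive_align()]).
#' @param cds_map named character vector / list mapping row ids to coding
#'   sequences; each cds must be exactly 3x the ungapped protein length
#'   (an additional trailing stop codon is allowed and dropped).
#' @return object of class `codon_alignment`: list with `rows` (ids),
#'   `codons` (character matrix rows x columns, `---` for gaps) and
#'   `provenance` (per-cell cds offset matrix, `NA` at gaps).
#' @export
codon_backmap <- function(aa_alignment, cds_map) {
  ids <- names(aa_alignment)
  stopifnot(!is.null(ids), all(ids %in% names(cds_map)))
  ncol <- unique(nchar(aa_alignment))
  if (length(ncol) != 1L) stop("rows have unequal alignment length")
  codons <- matrix("---", length(ids), ncol, dimnames = list(ids, NULL))
  offset <- matrix(NA_integer_, length(ids), ncol, dimnames = list(ids, NULL))
  for (r in ids) {
    aa <- .chars(aa_alignment[[r]])
    cds <- toupper(cds_map[[r]])
    naa <- sum(aa != "-")
    ncds <- nchar(cds)
    if (ncds == 3L * (naa + 1L)) {
      tr <- translate_cds(cds)
      if (endsWith(tr, "*")) { cds <- substr(cds, 1L, ncds - 3L); ncds <- ncds - 3L }
    }
    if (ncds != 3L * naa)
      stop("row '", r, "': cds length ", ncds,
           " does not match 3 x ", naa, " aligned residues")
    cdn <- .codons(cds)
    idx <- which(aa != "-")
    codons[r, idx] <- cdn
    offset[r, idx] <- 3L * (seq_along(idx) - 1L)
  }
  structure(list(rows = ids, codons = codons, provenance = offset),
            class = "codon_alignment")
}

# mean pairwise nucleotide identity of one codon column (gaps excluded);
# NA when fewer than two rows carry a codon
.column_identity <- function(col) {
  col <- col[col != "---"]
  if (length(col) < 2L) return(NA_real_)
  pairs <- utils::combn(length(col), 2L)
  idents <- apply(pairs, 2L, function(p) {
    a <- .chars(col[p[1L]]); b <- .chars(col[p[2L]])
    mean(a == b)
  })
  mean(idents)
}

#' Find conserved codon blocks
#'
#' Greedy left-to-right maximal extension: runs of consecutive columns
#' whose mean pairwise nucleotide identity (gaps excluded) is at least
#' `min_ident`, kept when at least `min_len` columns long. Columns carried
#' by fewer than two rows never qualify.
#'
#' @param codon_aln a `codon_alignment` from [codon_backmap()].
#' @param min_len minimum block length in codon columns (default 4, the
#'   four-codon conserved runs the DNA loss model describes).
#' @param min_ident minimum mean column identity in \[0, 1\] (default 0.8).
#' @return data.frame of class `conserved_blocks` with `start`, `end`
#'   (0-based half-open column interval), `mean_identity`, `consensus`
#'   (consensus codons, comma-free string).
#' @export
find_conserved_blocks <- function(codon_aln, min_len = 4L, min_ident = 0.8) {
  stopifnot(inherits(codon_aln, "codon_alignment"))
  nc <- ncol(codon_aln$codons)
  ident <- vapply(seq_len(nc), function(j)
    .column_identity(codon_aln$codons[, j]), numeric(1))
  ok <- !is.na(ident) & ident >= min_ident
  out <- data.frame(start = integer(0), end = integer(0),
                    mean_identity = numeric(0), consensus = character(0),
                    stringsAsFactors = FALSE)
  if (nc == 0L || !any(ok)) { class(out) <- c("conserved_blocks", "data.frame"); return(out) }
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths >= min_len)) {
    cols <- starts[k]:ends[k]
    cons <- vapply(cols, function(j)
      .consensus_codon(codon_aln$codons[, j]), character(1))
    out <- rbind(out, data.frame(
      start = starts[k] - 1L, end = ends[k],
      mean_identity = mean(ident[cols]),
      consensus = paste0(cons, collapse = ""),
      stringsAsFactors = FALSE))
  }
  class(out) <- c("conserved_blocks", "data.frame")
  out
}

# column-wise plurality codon with deterministic lexicographic tie-break
.consensus_codon <- function(col) {
  col <- col[col != "---"]
  if (!length(col)) return("---")
  tab <- table(col)
  cand <- names(tab)[tab == max(tab)]
  sort(cand)[1L]
}

#' Fuse conserved codon blocks into a virtual precursor (NPP)
#'
#' Concatenates the consensus codons of each block in template-row
#' coordinate order (blocks sorted by alignment column), translates the
#' fused coding sequence, and records per-block provenance. This is the
#' DNA-loss-model construction: a "Neuropeptide Precursor Predictive"
#' virtual precursor assembled from the conserved codon regions of related
#' precursor families.
#'
#' @param blocks a `conserved_blocks` data.frame with at least one block.
#' @param codon_aln the `codon_alignment` the blocks came from.
#' @param template row id whose coordinates order the blocks (must be a
#'   row of the alignment).
#' @return object of class `npp`: list with `cds`, `aa`, `provenance`
#'   (data.frame block -> fused-cds interval and source columns) and
#'   `layout` (copy counts per family from [validate_npp_layout()]).
#' @export
fuse_blocks <- function(blocks, codon_aln, template = codon_aln$rows[1L]) {
  if (nrow(blocks) == 0L) stop("no blocks to fuse")
  stopifnot(template %in% codon_aln$rows)
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  cds <- paste0(blocks$consensus, collapse = "")
  aa <- translate_cds(cds)
  len <- nchar(blocks$consensus)
  ends <- cumsum(len)
  prov <- data.frame(block = seq_len(nrow(blocks)),
                     fused_start = ends - len, fused_end = ends,
                     col_start = blocks$start, col_end = blocks$end,
                     template = template, stringsAsFactors = FALSE)
  structure(list(cds = cds, aa = aa, provenance = prov,
                 layout = validate_npp_layout(aa)),
            class = "npp")
}

#' Count active-peptide copies per family in a precursor
#'
#' Runs the purge annotation (signal peptide, cleavage sites) and the
#' family classifier on a single amino-acid sequence and tabulates the
#' copy count of each called family. Used to check that a fused virtual
#' precursor has the layout the DNA loss model predicts (e.g. three
#' APGWamide copies plus one AKH-type peptide for the rotifer-style
#' precursor).
#'
#' @param precursor_aa amino-acid string.
#' @param lineage optional named character vector of taxonomy ranks.
#' @return named integer vector family -> copy count (zero-length when no
#'   productive sites exist).
#' @export
validate_npp_layout <- function(precursor_aa, lineage = NULL) {
  rec <- precursor_records("npp_query", precursor_aa)
  ann <- structural_screen(rec)
  peps <- ann$peptides
  if (is.null(peps) || nrow(peps) == 0L)
    return(setNames(integer(0), character(0)))
  fams <- vapply(seq_len(nrow(peps)), function(i)
    classify_family(peps$seq[i], peps$amidated[i], lineage)$family,
    character(1))
  fams <- fams[fams != "unclassified"]
  if (!length(fams)) return(setNames(integer(0), character(0)))
  tab <- table(fams)
  setNames(as.integer(tab), names(tab))
}

#' Find open reading frames in a cDNA
#'
#' Scans all three forward frames for ATG..stop ORFs. Used to check the
#' structure of deposited cDNAs (e.g. a 306-bp ORF inside an ACP cDNA).
#'
#' @param cdna nucleotide string.
#' @return data.frame with `start` (0-based), `end` (half-open, includes
#'   the stop codon), `length_bp`, `aa` (translation without stop), sorted
#'   by decreasing length.
#' @export
find_orfs <- function(cdna) {
  cdna <- toupper(cdna)
  n <- nchar(cdna)
  out <- data.frame(start = integer(0), end = integer(0),
                    length_bp = integer(0), aa = character(0),
                    stringsAsFactors = FALSE)
  gc <- .genetic_code()
  for (frame in 0:2) {
    starts <- seq(frame + 1L, n - 2L, by = 3L)
    if (!length(starts)) next
    codons <- substring(cdna, starts, starts + 2L)
    aa <- gc[codons]; aa[is.na(aa)] <- "X"
    i <- 1L
    while (i <= length(aa)) {
      if (aa[i] == "M") {
        stop_at <- which(aa[-seq_len(i - 1L)] == "*")
        if (length(stop_at)) {
          j <- i + stop_at[1L] - 1L
          out <- rbind(out, data.frame(
            start = starts[i] - 1L, end = starts[j] + 2L,
            length_bp = (j - i + 1L) * 3L,
            aa = paste0(aa[i:(j - 1L)], collapse = ""),
            stringsAsFactors = FALSE))
          i <- j + 1L
          next
        }
      }
      i <- i + 1L
    }
  }
  out[order(-out$length_bp), , drop = FALSE]
}

#' @export
print.npp <- function(x, ...) {
  cat("npp virtual precursor: ", nchar(x$cds), " bp / ",
      nchar(x$aa), " aa, ", nrow(x$provenance), " block(s)\n", sep = "")
  if (length(x$layout))
    cat("  layout: ",
        paste(names(x$layout), x$layout, sep = " x ", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
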