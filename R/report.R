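# Bookkeeping arithmetic and summaries: retention rate, database totals,
# taxonomy breadth.

#' Retention rate of the purge, truncated to 2 decimals
#'
#' `100 * n_final / n_input`, truncated (not rounded) at the second
#' decimal. Truncation matters: 719 of 13,778 gives 5.218..., reported as
#' 5.21.
#'
#' @param n_final,n_input non-negative counts, `n_final <= n_input`,
#'   `n_input > 0`.
#' @return percentage with two decimals.
#' @export
retention_rate <- function(n_final, n_input) {
  if (n_input <= 0) stop("n_input must be positive")
  if (n_final < 0 || n_final > n_input)
    stop("need 0 <= n_final <= n_input")
  floor(100 * n_final / n_input * 100 + 1e-9) / 100
}

#' Render a purge summary from pipeline counts
#'
#' Validates the `pipeline_counts` invariants (monotone stage counts,
#' non-negative additions), recomputes the final total
#' `n_convertase + sum(additions)` and returns a printable stage table.
#'
#' @param counts a `pipeline_counts` object (see [pipeline_counts()]).
#' @return list with `table` (data.frame of stages and survivors),
#'   `additions`, and `n_final`.
#' @export
summarize_pipeline <- function(counts) {
  stopifnot(inherits(counts, "pipeline_counts"))
  # re-validate (objects may have been edited)
  counts <- pipeline_counts(counts$n_input, counts$n_structural,
                            counts$n_dibasic, counts$n_convertase,
                            counts$additions)
  tab <- data.frame(
    stage = c("input", "structural", "dibasic", "convertase", "final"),
    n = c(counts$n_input, counts$n_structural, counts$n_dibasic,
          counts$n_convertase, counts$n_final),
    stringsAsFactors = FALSE)
  list(table = tab, additions = counts$additions, n_final = counts$n_final)
}

#' Taxonomy breadth of an annotation table
#'
#' Counts distinct non-empty names at each rank (phylum, class, order,
#' family, genus, species).
#'
#' @param tab annotation data.frame as from [read_annotation_table()].
#' @return named integer vector of class `taxonomy_summary`.
#' @export
summarize_taxonomy <- function(tab) {
  out <- vapply(TAXONOMY_RANKS, function(r) {
    v <- if (r %in% names(tab)) tab[[r]] else character(0)
    v <- v[!is.na(v) & nzchar(v)]
    length(unique(v))
  }, integer(1))
  class(out) <- "taxonomy_summary"
  out
}

#' @export
print.taxonomy_summary <- function(x, ...) {
  cat("taxonomy breadth:",
      paste(unclass(x), names(x), collapse = ", "), "\n")
  invisible(x)
}
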