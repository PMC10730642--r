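# End-to-end orchestration: synth/input -> purge -> classify -> align under
# both parameter regimes -> NJ trees -> Robinson-Foulds report -> summary.

#' Run configuration for the end-to-end pipeline
#'
#' Either a synthetic batch is generated (`synth` is a
#' [synthetic_config()]) or `fasta`/`annotation` paths are read. The two
#' alignment regimes to contrast default to `"dnalm"` and `"default"`.
#'
#' @param out_dir output directory; must not already exist (one run
#'   directory per invocation, never overwritten).
#' @param synth optional [synthetic_config()].
#' @param fasta,annotation optional input paths (used when `synth` is
#'   `NULL`).
#' @param presets character vector of two preset names to contrast.
#' @param max_align_seqs cap on the number of retained sequences entering
#'   the alignment/tree stage (smallest record ids kept first).
#' @param seed integer seed recorded in the manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, synth = NULL, fasta = NULL,
                       annotation = NULL, presets = c("dnalm", "default"),
                       max_align_seqs = 50L, seed = 1L) {
  stopifnot(length(presets) == 2L,
            all(presets %in% c("dnalm", "default")))
  if (is.null(synth) && is.null(fasta))
    stop("run_config needs either a synthetic_config or a fasta path")
  if (!is.null(synth)) stopifnot(inherits(synth, "synthetic_config"))
  structure(list(out_dir = out_dir, synth = synth, fasta = fasta,
                 annotation = annotation, presets = presets,
                 max_align_seqs = as.integer(max_align_seqs),
                 seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes purge, classification, the two alignment regimes,
#' neighbor-joining trees, the Robinson-Foulds contrast, and the summary
#' report, writing every artifact plus a manifest (parameters, seed, file
#' hashes) into a fresh run directory.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the run directory path, the purge
#'   result, the classification table, the per-regime trees, and the RF
#'   report.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir_out <- config$out_dir
  if (dir.exists(dir_out)) stop("run directory already exists: ", dir_out)
  dir.create(dir_out, recursive = TRUE)

  # ---- inputs
  truth <- NULL
  if (!is.null(config$synth)) {
    gen <- .stage("synth", generate_precursors(config$synth))
    records <- gen$records
    annot <- gen$annotation
    truth <- gen$truth
    write_fasta(records, file.path(dir_out, "input.fasta"))
    write_annotation_table(annot, file.path(dir_out, "input_annotation.tsv"))
    write.table(truth, file.path(dir_out, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    records <- .stage("input", read_fasta(config$fasta))
    annot <- if (!is.null(config$annotation))
      .stage("input", read_annotation_table(config$annotation)) else NULL
  }

  # ---- purge
  purge <- .stage("purge", run_purge(records))
  purge_tab <- data.frame(
    record_id = names(purge$annotations),
    passed_structural = vapply(purge$annotations, `[[`, logical(1),
                               "passed_structural"),
    passed_dibasic = vapply(purge$annotations, `[[`, logical(1),
                            "passed_dibasic"),
    passed_convertase = vapply(purge$annotations, `[[`, logical(1),
                               "passed_convertase"),
    sites = vapply(purge$annotations, function(a)
      paste(sprintf("%d:%s:%.2f", a$sites$pos, a$sites$motif,
                    a$sites$score), collapse = ";"), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  write.table(purge_tab, file.path(dir_out, "purge.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(purge$counts),
                       file.path(dir_out, "counts.json"),
                       auto_unbox = TRUE, digits = NA)

  # ---- classification of retained records
  cls <- .stage("classify", {
    rows <- lapply(purge$retained, function(id) {
      ann <- purge$annotations[[id]]
      peps <- ann$peptides
      if (is.null(peps) || nrow(peps) == 0L) return(NULL)
      lin <- NULL
      if (!is.null(annot)) {
        r <- annot[annot$record_id == id, , drop = FALSE]
        if (nrow(r) == 1L)
          lin <- unlist(r[1L, TAXONOMY_RANKS, drop = TRUE])
      }
      data.frame(record_id = id, copy_index = peps$copy_index,
                 peptide = peps$seq, amidated = peps$amidated,
                 family = vapply(seq_len(nrow(peps)), function(i)
                   classify_family(peps$seq[i], peps$amidated[i],
                                   lin)$family, character(1)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  if (is.null(cls))
    cls <- data.frame(record_id = character(0), copy_index = integer(0),
                      peptide = character(0), amidated = logical(0),
                      family = character(0))
  write.table(cls, file.path(dir_out, "classification.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # ---- alignments + trees under both regimes
  keep <- head(sort(purge$retained), config$max_align_seqs)
  trees <- list(); alns <- list()
  rf_report <- NULL
  if (length(keep) >= 3L) {
    seqs <- setNames(records$aa_seq[match(keep, records$record_id)], keep)
    for (p in config$presets) {
      aln <- .stage(paste0("align_", p),
                    progressive_align(seqs, align_params(p)))
      alns[[p]] <- aln
      write_fasta_strings(aln, file.path(dir_out,
                                         paste0("alignment_", p, ".fasta")))
      tr <- .stage(paste0("tree_", p), nj_tree(p_distance(aln)))
      trees[[p]] <- tr
      write_newick(tr, file.path(dir_out, paste0("tree_", p, ".nwk")))
    }
    rf_report <- list(
      presets = config$presets,
      n_leaves = length(keep),
      rf = robinson_foulds(trees[[1L]], trees[[2L]]),
      normalized_rf = normalized_rf(trees[[1L]], trees[[2L]]))
    jsonlite::write_json(rf_report, file.path(dir_out, "rf_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # ---- summary
  summary <- list(
    counts = unclass(purge$counts),
    retention_pct = if (purge$counts$n_input > 0)
      retention_rate(purge$counts$n_final, purge$counts$n_input) else NA,
    taxonomy = if (!is.null(annot)) unclass(summarize_taxonomy(annot)),
    families = as.list(table(cls$family)))
  jsonlite::write_json(summary, file.path(dir_out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  # ---- manifest (hashes of all artifacts; no timestamps)
  files <- sort(setdiff(list.files(dir_out), "manifest.json"))
  manifest <- list(
    package = "nppcur",
    version = as.character(utils::packageVersion("nppcur")),
    seed = config$seed,
    presets = config$presets,
    hashes = as.list(tools::md5sum(file.path(dir_out, files))))
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, file.path(dir_out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(dir = dir_out, purge = purge, classification = cls,
                 trees = trees, alignments = alns, rf = rf_report,
                 truth = truth))
}
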