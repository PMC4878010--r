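#' Default run configuration
#'
#' Flat list of pipeline parameters; all fields are serializable and a
#' run's configuration is echoed into its output directory so a run can
#' be reproduced byte-identically.
#'
#' @param ... Overrides for any default field.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    schema_version = "1.0",
    mode = "strict",
    window = 19L, threshold = 1.6, min_helix_len = 15L, min_gap = 3L,
    max_loop = 80L, max_span = 300L, max_candidates = 100L,
    strict_arg = FALSE, template_file = NULL,
    substitution = "BLOSUM62", gap_open = -10, gap_extend = -1,
    build_tree = FALSE,
    out_dir = NULL, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = c("run_config", "list"))
}

# stage-level candidate calling for one record
call_candidates <- function(record, cfg) {
  hits <- scan_motif(record$sequence, cfg$mode)
  helices <- tm_helices(record$sequence, cfg$window, cfg$threshold,
                        cfg$min_helix_len, cfg$min_gap)
  assemble_vsd(record, helices, hits, cfg$max_candidates, cfg$max_loop,
               cfg$max_span)
}

#' Run the VSD discovery pipeline on a FASTA file or record collection
#'
#' Executes motif scan, transmembrane-helix prediction, S1-S4 assembly
#' and S4 family classification (and optionally a neighbor-joining tree
#' of the candidate VSD spans). When `cfg$out_dir` is set, TSV/JSON
#' reports, the Newick tree and an echo of the configuration are
#' written there; stage counts are logged to stderr.
#'
#' @param input Path to a protein FASTA file, or a [protein_records]
#'   data frame.
#' @param cfg A [default_run_config()] list.
#' @return Invisibly, a list with `records`, `hits`, `helices` (per
#'   record), `candidates`, `classifications` and optionally `tree`.
#' @export
run_pipeline <- function(input, cfg = default_run_config()) {
  records <- if (is.character(input)) read_fasta(input) else input
  templates <- if (!is.null(cfg$template_file)) {
    c(builtin_s4_templates(cfg$strict_arg),
      read_s4_templates(cfg$template_file))
  } else {
    builtin_s4_templates(cfg$strict_arg)
  }
  hits <- scan_records(records, cfg$mode)
  cands <- lapply(seq_len(nrow(records)), function(k) {
    call_candidates(records[k, ], cfg)
  })
  candidates <- do.call(rbind, c(cands, list(make.row.names = FALSE)))
  if (is.null(candidates) || nrow(records) == 0L) {
    candidates <- assemble_vsd(list(id = "x", sequence = "A"),
                               data.frame(start = integer(0),
                                          end = integer(0)),
                               scan_motif("AAAAAAAA", cfg$mode))
  }
  classifications <- if (nrow(candidates) > 0L) {
    calls <- lapply(candidates$s4_sequence, classify_s4, templates)
    data.frame(
      record_id = candidates$record_id,
      anchor_pos = candidates$anchor_pos,
      label = vapply(calls, function(x) x$label, character(1)),
      match_offset = vapply(calls, function(x)
        as.integer(x$match_offset), integer(1)),
      basic_count = vapply(candidates$s4_sequence, function(s)
        fingerprint_s4(s)$basic_count, integer(1), USE.NAMES = FALSE),
      spacing_vector = vapply(candidates$s4_sequence, function(s)
        paste(fingerprint_s4(s)$spacing_vector, collapse = ","),
        character(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
  } else {
    data.frame(record_id = character(0), anchor_pos = integer(0),
               label = character(0), match_offset = integer(0),
               basic_count = integer(0), spacing_vector = character(0),
               stringsAsFactors = FALSE)
  }
  tree <- NULL
  if (isTRUE(cfg$build_tree) && nrow(candidates) >= 3L) {
    vsd_records <- protein_records(
      id = paste0(candidates$record_id, "/", candidates$anchor_pos),
      sequence = substring(
        records$sequence[match(candidates$record_id, records$id)],
        candidates$vsd_start, candidates$vsd_end))
    tree <- nj_tree(vsd_records, cfg$substitution, cfg$gap_open,
                    cfg$gap_extend)
  }
  message(sprintf(
    "[vsdscout] records=%d hits=%d candidates=%d classified=%d",
    nrow(records), nrow(hits), nrow(candidates),
    sum(classifications$label != "unclassified")))
  result <- list(records = records, hits = hits,
                 candidates = candidates,
                 classifications = classifications, tree = tree,
                 config = cfg)
  if (!is.null(cfg$out_dir)) write_reports(result, cfg$out_dir)
  invisible(result)
}

# write TSV/JSON reports plus the config echo
write_reports <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(result$hits, "hits.tsv")
  tsv(result$classifications, "classifications.tsv")
  jsonlite::write_json(
    list(schema_version = result$config$schema_version,
         candidates = result$candidates),
    file.path(out_dir, "candidates.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- result$config
  cfg[vapply(cfg, is.null, logical(1))] <- NULL
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(result$tree)) {
    write_newick(result$tree, file.path(out_dir, "tree.nwk"))
  }
  invisible(out_dir)
}

#' Score pipeline calls against planted ground truth
#'
#' For each protein of a planted proteome, checks whether some
#' candidate recovers the planted S1-S4 architecture (each called
#' helix overlaps its planted counterpart and the called anchor equals
#' the planted anchor), how much of the planted S4 core the called S4
#' span covers, and whether the family label is correct.
#'
#' @param proteome A list as returned by
#'   [generate_planted_proteome()].
#' @param cfg A [default_run_config()] list.
#' @return A data frame per protein: `id`, `family`, `recovered`,
#'   `s4_core_coverage`, `label`, `label_correct`.
#' @export
evaluate_recovery <- function(proteome, cfg = default_run_config()) {
  records <- proteome$records
  truth <- proteome$truth
  templates <- builtin_s4_templates(cfg$strict_arg)
  overlaps <- function(a1, a2, b1, b2) a1 <= b2 && b1 <= a2
  out <- lapply(seq_len(nrow(records)), function(k) {
    tr <- truth[truth$id == records$id[k], ]
    cand <- call_candidates(records[k, ], cfg)
    recovered <- FALSE
    coverage <- 0
    label <- NA_character_
    if (nrow(cand) > 0L && !is.na(tr$motif_anchor)) {
      for (r in seq_len(nrow(cand))) {
        ok <- cand$anchor_pos[r] == tr$motif_anchor &&
          overlaps(cand$s1_start[r], cand$s1_end[r], tr$s1_start,
                   tr$s1_end) &&
          overlaps(cand$s2_start[r], cand$s2_end[r], tr$s2_start,
                   tr$s2_end) &&
          overlaps(cand$s3_start[r], cand$s3_end[r], tr$s3_start,
                   tr$s3_end) &&
          overlaps(cand$s4_start[r], cand$s4_end[r], tr$s4_start,
                   tr$s4_end)
        if (!ok) next
        core_len <- tr$s4_core_end - tr$s4_core_start + 1L
        cov <- (min(cand$s4_end[r], tr$s4_core_end) -
                  max(cand$s4_start[r], tr$s4_core_start) + 1L) /
          core_len
        cov <- max(0, cov)
        if (cov > coverage || !recovered) {
          coverage <- cov
          label <- classify_s4(cand$s4_sequence[r], templates)$label
        }
        recovered <- TRUE
      }
    }
    data.frame(id = records$id[k], family = tr$family,
               recovered = recovered, s4_core_coverage = coverage,
               label = label,
               label_correct = !is.na(label) && label == tr$family,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
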