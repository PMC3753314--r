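#' Final validation: collate per-sample flags against the replication design
#'
#' Counts valid, invalid and ambiguous observations for every sequence and
#' retains those that are provisionally valid (cross-sample pass) and whose
#' valid observations satisfy the replication design: at least
#' `min_valid_obs` valid samples, or -- when blocks are defined -- a valid
#' observation in every sample of at least one block. Ambiguous
#' observations (single in-sample reads) never count as valid, and
#' invalid observations are not vetoes: only valid observations are
#' counted.
#'
#' @param flags per-(sequence, sample) flags from [validate_all_samples()].
#' @param prelim preliminary-validation results from [prelim_validate()].
#' @param design a [replication_design()]; any sample it references must
#'   exist in the flags' sample set.
#' @param table the filtered `abundance_table` (for sequences and counts in
#'   the ledger).
#' @return data.frame ledger: `sequence_id`, `sequence`, `total_reads`,
#'   `n_valid`, `n_invalid`, `n_ambiguous`, `prelim_status`,
#'   `final_status` ("valid"/"rejected"). Rejected sequences stay in the
#'   ledger; nothing is silently discarded.
#' @export
finalize <- function(flags, prelim, design, table) {
  stopifnot(inherits(design, "replication_design"),
            inherits(table, "abundance_table"))
  samples <- table_samples(table)
  if (!is.null(design$blocks)) {
    unknown <- setdiff(unlist(design$blocks), samples)
    if (length(unknown) > 0)
      stop("replication design references unknown samples: ",
           paste(unknown, collapse = ", "))
  }
  ids <- table$sequence_id
  tally <- function(st) {
    f <- flags[flags$status == st, , drop = FALSE]
    v <- table(factor(f$sequence_id, levels = ids))
    as.integer(v)
  }
  n_valid <- tally("valid")
  n_invalid <- tally("invalid")
  n_ambiguous <- tally("ambiguous")

  prelim_ok <- ids %in% prelim$sequence_id[prelim$status == "provisional"]

  if (!is.null(design$blocks)) {
    vf <- flags[flags$status == "valid", , drop = FALSE]
    design_ok <- vapply(ids, function(id) {
      vs <- vf$sample[vf$sequence_id == id]
      any(vapply(design$blocks, function(b) all(b %in% vs), logical(1)))
    }, logical(1))
  } else {
    design_ok <- n_valid >= design$min_valid_obs
  }

  data.frame(sequence_id = ids,
             sequence = table$sequence,
             total_reads = table$total_reads,
             n_valid = n_valid, n_invalid = n_invalid,
             n_ambiguous = n_ambiguous,
             prelim_status = ifelse(prelim_ok, "provisional", "rejected"),
             final_status = ifelse(prelim_ok & design_ok,
                                   "valid", "rejected"),
             stringsAsFactors = FALSE)
}

#' Run the full denoising pipeline
#'
#' Executes the four validation steps in order: (1) demultiplex, trim and
#' filter raw reads into a unique-sequence abundance table; (2) group
#' sequences and validate them preliminarily from their cross-sample
#' abundance distribution; (3) validate within samples by explicit
#' per-error-type abundance thresholds; (4) collate valid observations
#' against the replication design. No read is ever edited, merged or
#' mapped onto another sequence -- the output is a subset of the observed
#' unique sequences.
#'
#' @param reads named character vector of raw reads, or path to a FASTA
#'   file.
#' @param spec a [primer_spec()].
#' @param design a [replication_design()].
#' @param params an [error_params()].
#' @param grouping "precluster" (default, reference-free) or a named
#'   best-hit vector / hit-table TSV path for accession grouping.
#' @param radius precluster radius when `grouping = "precluster"`.
#' @param max_parents passed to [validate_all_samples()].
#' @param out_dir optional directory; when given, all result files are
#'   exported there via [export_results()].
#' @return object of class `apdp_result`: list with `accepted`,
#'   `rejected_reads`, `table_raw`, `table`, `removed`, `groups`,
#'   `dropped`, `prelim`, `flags`, `ledger` and `stage_counts` (raw reads,
#'   accepted reads, unique sequences, filtered, preliminary-validated,
#'   final-validated).
#' @export
run_pipeline <- function(reads, spec, design, params = error_params(),
                         grouping = "precluster", radius = 0.02,
                         max_parents = Inf, out_dir = NULL) {
  stopifnot(inherits(spec, "primer_spec"),
            inherits(design, "replication_design"))
  dm <- demultiplex(reads, spec)
  n_raw <- nrow(dm$accepted) + nrow(dm$rejected)
  table_raw <- build_abundance_table(dm$accepted,
                                     samples = sort(unique(spec$mid_map$sample)))
  pf <- prefilter(table_raw, spec)
  table <- pf$table

  if (identical(grouping, "precluster")) {
    gr <- group_by_precluster(table, radius = radius)
  } else {
    hits <- if (is.character(grouping) && length(grouping) == 1 &&
                file.exists(grouping)) read_hit_table(grouping) else grouping
    gr <- group_by_besthit(table, hits)
  }
  # sequences dropped as non-target leave all downstream validation
  if (length(gr$dropped) > 0) {
    keep <- !(table$sequence_id %in% gr$dropped)
    table <- table[keep, , drop = FALSE]
    rownames(table) <- NULL
    class(table) <- c("abundance_table", "data.frame")
  }

  prelim <- prelim_validate(gr$groups, table, params, mode = design$mode)
  flags <- validate_all_samples(table, params, max_parents = max_parents)
  ledger <- finalize(flags, prelim, design, table)

  # structural guarantee of the detection floor
  fl <- detection_floor(design)
  val <- ledger[ledger$final_status == "valid", , drop = FALSE]
  stopifnot(all(val$total_reads >= fl["min_dataset_reads"]))

  stage_counts <- data.frame(
    stage = c("raw_reads", "accepted_reads", "unique_sequences",
              "filtered_sequences", "prelim_validated", "final_validated"),
    count = c(n_raw, nrow(dm$accepted), nrow(table_raw), nrow(pf$table),
              sum(prelim$status == "provisional"),
              sum(ledger$final_status == "valid"))
  )

  res <- structure(list(accepted = dm$accepted,
                        rejected_reads = dm$rejected,
                        table_raw = table_raw, table = table,
                        removed = pf$removed,
                        groups = gr$groups, dropped = gr$dropped,
                        prelim = prelim, flags = flags, ledger = ledger,
                        stage_counts = stage_counts,
                        spec = spec, design = design, params = params),
                   class = "apdp_result")
  if (!is.null(out_dir)) export_results(res, out_dir)
  res
}

#' @export
print.apdp_result <- function(x, ...) {
  cat("amplicon denoising result\n")
  print(x$stage_counts, row.names = FALSE)
  invisible(x)
}

#' Validated sequences of a pipeline result
#' @param result an `apdp_result`.
#' @return character vector of validated sequences, named by sequence id.
#' @export
validated_sequences <- function(result) {
  led <- result$ledger
  v <- led[led$final_status == "valid", , drop = FALSE]
  setNames(v$sequence, v$sequence_id)
}

#' Export all pipeline results to a directory
#'
#' Writes the abundance table, grouping, per-step validation tables and
#' the final ledger as TSV; validated and rejected sequences as FASTA
#' (headers carry dataset and per-sample read counts); and a validated
#' sequence-by-sample count matrix TSV usable as a downstream OTU/feature
#' table.
#'
#' @param result an `apdp_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_results <- function(result, dir) {
  stopifnot(inherits(result, "apdp_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_abundance_table(result$table, p("abundance_table.tsv"))
  write_tsv(result$rejected_reads, p("read_rejections.tsv"))
  write_tsv(result$removed, p("filtered_out_sequences.tsv"))
  write_tsv(result$groups, p("groups.tsv"))
  write_tsv(result$prelim, p("preliminary_validation.tsv"))
  write_tsv(result$flags, p("sample_flags.tsv"))
  write_tsv(result$ledger, p("validation_ledger.tsv"))
  write_tsv(result$stage_counts, p("stage_counts.tsv"))

  led <- result$ledger
  tab <- result$table
  samples <- table_samples(tab)
  header_of <- function(ids) {
    i <- match(ids, tab$sequence_id)
    counts <- apply(tab[i, samples, drop = FALSE], 1, function(r)
      paste(sprintf("%s=%d", samples, as.integer(r)), collapse = ";"))
    sprintf("%s;total_reads=%d;%s", ids, tab$total_reads[i], counts)
  }
  vids <- led$sequence_id[led$final_status == "valid"]
  rids <- led$sequence_id[led$final_status != "valid"]
  vset <- Biostrings::DNAStringSet(setNames(
    tab$sequence[match(vids, tab$sequence_id)], header_of(vids)))
  Biostrings::writeXStringSet(vset, p("validated.fasta"))
  if (length(rids) > 0) {
    rset <- Biostrings::DNAStringSet(setNames(
      tab$sequence[match(rids, tab$sequence_id)], header_of(rids)))
    Biostrings::writeXStringSet(rset, p("rejected.fasta"))
  }
  feat <- tab[match(vids, tab$sequence_id),
              c("sequence_id", "sequence", "total_reads", samples),
              drop = FALSE]
  write_tsv(feat, p("feature_table.tsv"))
  invisible(list.files(dir, full.names = TRUE))
}
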