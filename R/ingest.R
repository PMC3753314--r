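#' Primer/MID demultiplexing specification
#'
#' Describes the expected read layout: `forward_mid + forward_primer +
#' amplicon + revcomp(reverse_primer) + revcomp(reverse_mid)`. Matching is
#' exact; no fuzzy primer search is performed.
#'
#' @param forward_primer,reverse_primer primer sequences (5'->3' on their
#'   respective strands), non-empty.
#' @param mid_map data.frame with columns `sample`, `forward_mid`,
#'   `reverse_mid`: one row per sample, MID pairs unique.
#' @param min_length reads shorter than this after trimming are rejected.
#'   Default 1 (reject empty amplicons only).
#' @param truncate_at optional positive integer enabling long-amplicon
#'   mode: the reverse primer/MID are not searched for and the read is cut
#'   at `truncate_at` bases after forward trimming. In this mode samples
#'   must be resolvable from the forward MID alone.
#' @return object of class `primer_spec`.
#' @examples
#' mids <- data.frame(sample = c("S1", "S2"),
#'                    forward_mid = c("ACGAGTGCGT", "ACGCTCGACA"),
#'                    reverse_mid = c("TACTCTCGTG", "TACTCTCGTG"))
#' primer_spec("TGGTGCATGG", "CATCTAAGGG", mids, min_length = 50)
#' @export
primer_spec <- function(forward_primer, reverse_primer, mid_map,
                        min_length = 1L, truncate_at = NULL) {
  forward_primer <- clean_bases(forward_primer)
  reverse_primer <- clean_bases(reverse_primer)
  stopifnot(nzchar(forward_primer), nzchar(reverse_primer),
            is.data.frame(mid_map),
            all(c("sample", "forward_mid", "reverse_mid") %in% names(mid_map)))
  mid_map$forward_mid <- clean_bases(mid_map$forward_mid)
  mid_map$reverse_mid <- clean_bases(mid_map$reverse_mid)
  key <- paste(mid_map$forward_mid, mid_map$reverse_mid)
  if (anyDuplicated(key)) stop("MID pairs must be unique")
  if (!is.null(truncate_at)) {
    stopifnot(truncate_at >= 1)
    if (anyDuplicated(mid_map$forward_mid))
      stop("truncation mode requires samples resolvable by forward MID alone")
  }
  structure(list(forward_primer = forward_primer,
                 reverse_primer = reverse_primer,
                 mid_map = mid_map,
                 min_length = as.integer(min_length),
                 truncate_at = if (is.null(truncate_at)) NULL
                               else as.integer(truncate_at)),
            class = "primer_spec")
}

#' Accept and trim a single raw read
#'
#' Applies the exact-match acceptance rule: the read must start with a
#' known forward MID followed by the forward primer, and (unless the spec
#' is in truncation mode) contain the reverse-complemented reverse primer
#' towards its 3' end followed by a known reverse MID. Accepted reads are
#' stripped of MIDs and primers and assigned to their sample.
#'
#' @param bases nucleotide string of the read.
#' @param spec a [primer_spec()].
#' @return list with `accepted` (logical); on acceptance `sample` and
#'   `sequence`; on rejection `reason`, one of `no_forward_primer`,
#'   `no_reverse_primer`, `unknown_mid`, `too_short`.
#' @export
accept_and_trim <- function(bases, spec) {
  stopifnot(inherits(spec, "primer_spec"))
  res <- demultiplex(setNames(clean_bases(bases), "r"), spec)
  if (nrow(res$accepted) == 1) {
    list(accepted = TRUE, sample = res$accepted$sample,
         sequence = res$accepted$sequence)
  } else {
    list(accepted = FALSE, reason = res$rejected$reason)
  }
}

#' Demultiplex a set of raw reads
#'
#' Vectorised driver of the acceptance rule in [accept_and_trim()].
#'
#' @param reads named character vector of reads (names are read ids,
#'   unique) or a path to a FASTA file, read via
#'   [Biostrings::readDNAStringSet()].
#' @param spec a [primer_spec()].
#' @return list with `accepted` (data.frame `read_id`, `sample`,
#'   `sequence`) and `rejected` (data.frame `read_id`, `reason`). Every
#'   input read appears in exactly one of the two.
#' @export
demultiplex <- function(reads, spec) {
  stopifnot(inherits(spec, "primer_spec"))
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    ss <- Biostrings::readDNAStringSet(reads)
    reads <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  if (length(reads) == 0) {
    return(list(accepted = data.frame(read_id = character(),
                                      sample = character(),
                                      sequence = character(),
                                      stringsAsFactors = FALSE),
                rejected = data.frame(read_id = character(),
                                      reason = character(),
                                      stringsAsFactors = FALSE)))
  }
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    stop("reads must be named by read id")
  if (anyDuplicated(names(reads))) stop("read ids must be unique")
  reads <- clean_bases(reads)
  n <- length(reads)
  sample_out <- character(n)
  seq_out <- character(n)
  reason <- character(n)  # "" = accepted

  mm <- spec$mid_map
  fwd <- spec$forward_primer
  # forward MID + primer anchored at position 0
  fmids <- unique(mm$forward_mid)
  fhit <- rep(NA_character_, n)
  for (fm in fmids) {
    idx <- is.na(fhit) & startsWith(reads, paste0(fm, fwd))
    fhit[idx] <- fm
  }
  no_f <- is.na(fhit)
  if (any(no_f)) {
    # distinguish an unknown forward MID from a missing/broken primer:
    # the primer is present at a plausible MID offset but the MID is new
    unk <- rep(FALSE, n)
    for (L in unique(nchar(fmids))) {
      cand <- no_f & substr(reads, L + 1L, L + nchar(fwd)) == fwd
      unk <- unk | cand
    }
    reason[no_f & unk] <- "unknown_mid"
    reason[no_f & !unk] <- "no_forward_primer"
  }

  ok <- !no_f
  rest <- substring(reads, nchar(fhit) + nchar(fwd) + 1L)

  if (!is.null(spec$truncate_at)) {
    trimmed <- substr(rest, 1L, spec$truncate_at)
    smap <- setNames(mm$sample, mm$forward_mid)
    sample_out[ok] <- smap[fhit[ok]]
    seq_out[ok] <- trimmed[ok]
  } else {
    rc_rev <- revcomp(spec$reverse_primer)
    pair_map <- setNames(mm$sample, paste(mm$forward_mid, mm$reverse_mid))
    # fast path: read ends exactly with rc(reverse primer) + rc(reverse MID)
    done <- rep(FALSE, n)
    for (r in seq_len(nrow(mm))) {
      suffix <- paste0(rc_rev, revcomp(mm$reverse_mid[r]))
      sel <- ok & !done & fhit == mm$forward_mid[r] & endsWith(rest, suffix)
      if (any(sel)) {
        sample_out[sel] <- mm$sample[r]
        seq_out[sel] <- substr(rest[sel], 1L,
                               nchar(rest[sel]) - nchar(suffix))
        done[sel] <- TRUE
      }
    }
    # general path: first rc(reverse primer) occurrence from the 3' end,
    # followed by the reverse MID (read may carry trailing adapter bases)
    for (i in which(ok & !done)) {
      hits <- gregexpr(rc_rev, rest[i], fixed = TRUE)[[1]]
      if (hits[1] == -1) { reason[i] <- "no_reverse_primer"; next }
      pos <- hits[length(hits)]
      tail_seq <- substring(rest[i], pos + nchar(rc_rev))
      rmid <- revcomp(tail_seq)
      sample <- pair_map[paste(fhit[i], rmid)]
      if (is.na(sample)) { reason[i] <- "unknown_mid"; next }
      sample_out[i] <- sample
      seq_out[i] <- substr(rest[i], 1L, pos - 1L)
    }
  }

  acc <- reason == "" & nzchar(sample_out)
  short <- acc & nchar(seq_out) < spec$min_length
  reason[short] <- "too_short"
  acc <- acc & !short

  list(
    accepted = data.frame(read_id = names(reads)[acc],
                          sample = sample_out[acc],
                          sequence = seq_out[acc],
                          stringsAsFactors = FALSE),
    rejected = data.frame(read_id = names(reads)[!acc],
                          reason = reason[!acc],
                          stringsAsFactors = FALSE)
  )
}

#' Bin accepted reads into a unique-sequence abundance table
#'
#' @param accepted data.frame with columns `sample` and `sequence` (the
#'   `accepted` element of [demultiplex()]).
#' @param samples optional character vector fixing the sample columns
#'   (e.g. all samples of the design, including any with zero accepted
#'   reads); defaults to the samples observed.
#' @return data.frame of class `abundance_table`: columns `sequence_id`,
#'   `sequence`, `total_reads`, then one integer column per sample. Rows
#'   ordered by descending `total_reads`, ties lexicographic by sequence.
#' @export
build_abundance_table <- function(accepted, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(accepted$sample))
  if (nrow(accepted) == 0) {
    out <- data.frame(sequence_id = character(), sequence = character(),
                      total_reads = integer(), stringsAsFactors = FALSE)
    for (s in samples) out[[s]] <- integer()
    class(out) <- c("abundance_table", "data.frame")
    return(out)
  }
  stopifnot(all(accepted$sample %in% samples))
  tab <- table(factor(accepted$sequence),
               factor(accepted$sample, levels = samples))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  total <- as.integer(rowSums(counts))
  seqs <- rownames(counts)
  ord <- order_by_abundance(total, seqs)
  out <- data.frame(sequence_id = sprintf("sq%05d", seq_along(ord)),
                    sequence = seqs[ord],
                    total_reads = total[ord],
                    stringsAsFactors = FALSE)
  for (s in samples) out[[s]] <- unname(counts[ord, s])
  rownames(out) <- NULL
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Sample columns of an abundance table
#' @param table an `abundance_table`.
#' @return character vector of sample names.
#' @export
table_samples <- function(table) {
  setdiff(names(table), c("sequence_id", "sequence", "total_reads"))
}

# per-sample count matrix (sequences x samples), rownames = sequence_id
count_matrix <- function(table) {
  s <- table_samples(table)
  m <- as.matrix(table[, s, drop = FALSE])
  rownames(m) <- table$sequence_id
  m
}

#' Pre-validation filtering of the abundance table
#'
#' Removes rows whose sequence contains an ambiguous base (N), rows whose
#' trimmed sequence still contains an occurrence of the forward primer or
#' the reverse-complemented reverse primer (trimming should have consumed
#' both, so any occurrence marks a concatemer-like artefact), and global
#' singletons (sequences with exactly one read in the whole dataset).
#' Local singletons -- multiple reads in the dataset but a single read in
#' some samples -- are retained.
#'
#' @param table an `abundance_table` from [build_abundance_table()].
#' @param spec the [primer_spec()] used for demultiplexing.
#' @return list with `table` (the filtered `abundance_table`) and
#'   `removed` (data.frame `sequence_id`, `sequence`, `total_reads`,
#'   `reason`).
#' @export
prefilter <- function(table, spec) {
  stopifnot(inherits(table, "abundance_table"), inherits(spec, "primer_spec"))
  reason <- rep(NA_character_, nrow(table))
  has_n <- grepl("N", table$sequence, fixed = TRUE)
  reason[has_n] <- "ambiguous_base"
  multi <- grepl(spec$forward_primer, table$sequence, fixed = TRUE) |
    grepl(revcomp(spec$reverse_primer), table$sequence, fixed = TRUE)
  reason[is.na(reason) & multi] <- "multiple_primer"
  reason[is.na(reason) & table$total_reads < 2L] <- "global_singleton"
  keep <- is.na(reason)
  removed <- data.frame(sequence_id = table$sequence_id[!keep],
                        sequence = table$sequence[!keep],
                        total_reads = table$total_reads[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("abundance_table", "data.frame")
  list(table = out, removed = removed)
}

#' Write / read an abundance table as TSV
#' @param table an `abundance_table`.
#' @param file path of the TSV.
#' @export
write_abundance_table <- function(table, file) {
  write_tsv(as.data.frame(table), file)
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(file) {
  out <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("sequence_id", "sequence", "total_reads") %in% names(out)))
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Read a MID map TSV (columns sample, forward_mid, reverse_mid)
#' @param file path of the TSV.
#' @return data.frame suitable for [primer_spec()].
#' @export
read_mid_map <- function(file) {
  mm <- read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "forward_mid", "reverse_mid") %in% names(mm)))
  mm
}
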