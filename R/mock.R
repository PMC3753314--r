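# Synthetic mock-community generator: clone assemblages mixed at
# dilution-group ratios, replicate PCRs with MID barcoding, and injected
# substitution / homopolymer-indel / chimera errors with full ground
# truth, so every pipeline stage is testable without external data.

# Roche-style 10-mer multiplex identifiers used for the default replicates
.default_mids <- c("ACGAGTGCGT", "ACGCTCGACA", "AGACGCACTC", "AGCACTGTAG",
                   "ATCAGACACG", "ATATCGCGAG", "CGTGTCTCTA", "CTCGCGTGTC",
                   "TAGTATCAGC", "TCTCTATGCG")

.default_fwd_primer <- "TGGTGCATGGCCGTTCTTAGT"
.default_rev_primer <- "CATCTAAGGGCATCACAGACC"

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# homopolymer runs of length >= 2: data.frame(start, length) in 1-based
# string coordinates
homopolymer_runs <- function(seq) {
  r <- rle(strsplit(seq, "")[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= 2
  data.frame(start = (ends - r$lengths + 1L)[keep],
             length = r$lengths[keep])
}

random_clone <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Mock-community design
#'
#' Describes a synthetic positive-control experiment: a set of clone
#' sequences mixed at dilution-group ratios, amplified in several
#' replicate "PCRs" each carrying its own MID pair, with per-read error
#' rates for the three modelled error types. The default mirrors a
#' 16-clone, three-dilution-group, five-replicate design: eight clones at
#' relative concentration 1 (group 1), six at 0.1 (group 2), and two very
#' similar clones -- a simulated heterozygote, two substitutions apart --
#' each at half the group-2 concentration (group 3).
#'
#' @param n_replicates number of replicate samples (default 5).
#' @param reads_per_replicate reads emitted per replicate (default 2000).
#' @param sub_rate substitution rate per base per read (default 2e-4).
#' @param indel_rate indel rate per homopolymer run (length >= 2) per
#'   read (default 1e-3).
#' @param chimera_rate probability that a read is a single-breakpoint
#'   hybrid of two clones (default 0.01).
#' @param clones optional data.frame (`clone_id`, `sequence`, `group`,
#'   `concentration`) overriding the generated default clones.
#' @param clone_length_range lengths of the generated clones (default
#'   140--160 nt).
#' @param seed integer seed governing clone generation and read sampling.
#' @return object of class `mock_design`.
#' @examples
#' d <- mock_design(seed = 7)
#' nrow(d$clones)  # 16
#' @export
mock_design <- function(n_replicates = 5L, reads_per_replicate = 2000L,
                        sub_rate = 2e-4, indel_rate = 1e-3,
                        chimera_rate = 0.01, clones = NULL,
                        clone_length_range = c(140L, 160L), seed = 1L) {
  stopifnot(n_replicates >= 1, reads_per_replicate >= 0,
            sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1,
            chimera_rate >= 0, chimera_rate < 1,
            n_replicates <= length(.default_mids) - 1L)
  if (is.null(clones)) {
    clones <- with_seed(seed, {
      lens <- sample(seq(clone_length_range[1], clone_length_range[2]),
                     15L, replace = TRUE)
      seqs <- vapply(lens, random_clone, character(1))
      # group 3 pair: a near-identical variant (simulated heterozygote)
      base15 <- seqs[15]
      pos <- sample(nchar(base15), 2L)
      ch <- strsplit(base15, "")[[1]]
      for (p in pos)
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      seqs <- c(seqs, paste(ch, collapse = ""))
      data.frame(
        clone_id = sprintf("clone%02d", 1:16),
        sequence = seqs,
        group = rep(c(1L, 2L, 3L), times = c(8L, 6L, 2L)),
        concentration = rep(c(1, 0.1, 0.05), times = c(8L, 6L, 2L)),
        stringsAsFactors = FALSE)
    })
  }
  stopifnot(all(c("clone_id", "sequence", "concentration") %in% names(clones)),
            all(clones$concentration > 0),
            !anyDuplicated(clones$clone_id),
            !anyDuplicated(clones$sequence),
            all(grepl("^[ACGT]+$", clones$sequence)))
  samples <- sprintf("rep%d", seq_len(n_replicates))
  mid_map <- data.frame(sample = samples,
                        forward_mid = .default_mids[seq_len(n_replicates)],
                        reverse_mid = .default_mids[length(.default_mids)],
                        stringsAsFactors = FALSE)
  structure(list(clones = clones, n_replicates = as.integer(n_replicates),
                 reads_per_replicate = as.integer(reads_per_replicate),
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 chimera_rate = chimera_rate, mid_map = mid_map,
                 forward_primer = .default_fwd_primer,
                 reverse_primer = .default_rev_primer,
                 seed = as.integer(seed)),
            class = "mock_design")
}

#' Primer/MID specification matching a mock design
#' @param design a [mock_design()].
#' @param min_length passed through to [primer_spec()].
#' @return a [primer_spec()] that demultiplexes the simulated reads.
#' @export
mock_spec <- function(design, min_length = 50L) {
  primer_spec(design$forward_primer, design$reverse_primer,
              design$mid_map, min_length = min_length)
}

#' Simulate mock-community amplicon reads with ground truth
#'
#' For each replicate, reads are drawn multinomially from the clones in
#' proportion to their concentrations. With probability `chimera_rate` a
#' read is replaced by a single-breakpoint hybrid of two distinct clones
#' (drawn proportional to concentration, breakpoint uniform over the
#' alignable interior). Each read then receives binomial substitution
#' errors (per base) and homopolymer indels (per run of length >= 2,
#' insertion or deletion of one base with equal probability). Reads are
#' wrapped with the replicate's MID pair and the primers. Fully
#' reproducible from `design$seed`.
#'
#' @param design a [mock_design()].
#' @param spike optional data.frame (`sequence`, `sample`, `reads`)
#'   appending error-free reads of arbitrary trimmed sequences to chosen
#'   samples -- used to place sequences deliberately above or below the
#'   validation thresholds.
#' @return object of class `mock_sim`: list with `reads` (named character
#'   vector of raw reads), `truth` (per-read data.frame: `read_id`,
#'   `sample`, `clone1`, `clone2`, `breakpoint`, `n_sub`, `n_indel`,
#'   `spike`), `design`, and `sequences` (the trimmed per-read sequences,
#'   for truth bookkeeping).
#' @export
simulate_mock <- function(design, spike = NULL) {
  stopifnot(inherits(design, "mock_design"))
  cl <- design$clones
  prob <- cl$concentration / sum(cl$concentration)
  runs <- lapply(cl$sequence, homopolymer_runs)
  lens <- nchar(cl$sequence)

  with_seed(design$seed, {
    recs <- list()
    for (r in seq_len(design$n_replicates)) {
      n <- design$reads_per_replicate
      if (n == 0) next
      sm <- design$mid_map$sample[r]
      idx <- sample.int(nrow(cl), n, replace = TRUE, prob = prob)
      is_chi <- runif(n) < design$chimera_rate
      clone1 <- cl$clone_id[idx]
      clone2 <- rep(NA_character_, n)
      brk <- rep(NA_integer_, n)
      seqs <- cl$sequence[idx]
      for (i in which(is_chi)) {
        p12 <- sample.int(nrow(cl), 2L, replace = FALSE, prob = prob)
        f <- runif(1)
        c1 <- max(1L, min(lens[p12[1]] - 1L, round(f * lens[p12[1]])))
        c2 <- max(1L, min(lens[p12[2]] - 1L, round(f * lens[p12[2]])))
        seqs[i] <- paste0(substr(cl$sequence[p12[1]], 1L, c1),
                          substr(cl$sequence[p12[2]], c2 + 1L, lens[p12[2]]))
        clone1[i] <- cl$clone_id[p12[1]]
        clone2[i] <- cl$clone_id[p12[2]]
        brk[i] <- c1
      }
      # per-read error event counts (chimeric reads keep the error model
      # of their first parent's homopolymer profile, recomputed on edit)
      n_sub <- rbinom(n, nchar(seqs), design$sub_rate)
      n_run <- vapply(seq_len(n), function(i)
        if (is_chi[i]) nrow(homopolymer_runs(seqs[i]))
        else nrow(runs[[idx[i]]]), integer(1))
      n_ind <- rbinom(n, n_run, design$indel_rate)
      for (i in which(n_ind > 0L)) {
        hr <- homopolymer_runs(seqs[i])
        pick <- sample.int(nrow(hr), n_ind[i])
        # apply right-to-left so positions stay valid
        for (k in pick[order(-hr$start[pick])]) {
          pos <- hr$start[k]
          base <- substr(seqs[i], pos, pos)
          if (runif(1) < 0.5) {
            seqs[i] <- paste0(substr(seqs[i], 1L, pos), base,
                              substring(seqs[i], pos + 1L))
          } else {
            seqs[i] <- paste0(substr(seqs[i], 1L, pos - 1L),
                              substring(seqs[i], pos + 1L))
          }
        }
      }
      for (i in which(n_sub > 0L)) {
        ch <- strsplit(seqs[i], "")[[1]]
        pos <- sample.int(length(ch), min(n_sub[i], length(ch)))
        for (p in pos)
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        seqs[i] <- paste(ch, collapse = "")
      }
      recs[[r]] <- data.frame(
        read_id = sprintf("%s_%06d", sm, seq_len(n)),
        sample = sm, clone1 = clone1, clone2 = clone2, breakpoint = brk,
        n_sub = n_sub, n_indel = n_ind, spike = FALSE,
        sequence = seqs, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, recs)
    if (is.null(truth))
      truth <- data.frame(read_id = character(), sample = character(),
                          clone1 = character(), clone2 = character(),
                          breakpoint = integer(), n_sub = integer(),
                          n_indel = integer(), spike = logical(),
                          sequence = character(), stringsAsFactors = FALSE)
    if (!is.null(spike) && nrow(spike) > 0) {
      stopifnot(all(spike$sample %in% design$mid_map$sample),
                all(spike$reads >= 0))
      sp <- spike[rep(seq_len(nrow(spike)), spike$reads), , drop = FALSE]
      if (nrow(sp) > 0) {
        sp_truth <- data.frame(
          read_id = sprintf("spike_%06d", seq_len(nrow(sp))),
          sample = sp$sample, clone1 = "spike", clone2 = NA_character_,
          breakpoint = NA_integer_, n_sub = 0L, n_indel = 0L,
          spike = TRUE, sequence = sp$sequence, stringsAsFactors = FALSE)
        truth <- rbind(truth, sp_truth)
      }
    }
    mm <- design$mid_map
    i <- match(truth$sample, mm$sample)
    reads <- paste0(mm$forward_mid[i], design$forward_primer,
                    truth$sequence,
                    revcomp(design$reverse_primer), revcomp(mm$reverse_mid[i]))
    names(reads) <- truth$read_id
    structure(list(reads = reads,
                   truth = truth[, setdiff(names(truth), "sequence")],
                   sequences = setNames(truth$sequence, truth$read_id),
                   design = design),
              class = "mock_sim")
  })
}

#' Ground-truth labels for the unique trimmed sequences of a simulation
#'
#' @param sim a `mock_sim` from [simulate_mock()].
#' @return data.frame `sequence`, `label` (a clone id, "spike", or one of
#'   "substitution", "indel", "mixed", "chimera"), `reads`.
#' @export
mock_truth_sequences <- function(sim) {
  stopifnot(inherits(sim, "mock_sim"))
  seqs <- sim$sequences
  truth <- sim$truth
  clone_of <- setNames(sim$design$clones$clone_id, sim$design$clones$sequence)
  res <- lapply(split(seq_along(seqs), seqs), function(ii) {
    sq <- seqs[ii[1]]
    lab <- if (!is.na(clone_of[sq])) {
      unname(clone_of[sq])
    } else if (all(truth$spike[ii])) {
      "spike"
    } else if (all(!is.na(truth$clone2[ii]))) {
      "chimera"
    } else if (all(truth$n_sub[ii] > 0 & truth$n_indel[ii] == 0)) {
      "substitution"
    } else if (all(truth$n_indel[ii] > 0 & truth$n_sub[ii] == 0)) {
      "indel"
    } else {
      "mixed"
    }
    data.frame(sequence = sq, label = lab, reads = length(ii),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(-out$reads, out$sequence), , drop = FALSE]
}

#' Expected read abundance of an error class for one clone
#'
#' Closed-form expectation used to position injected error abundances
#' deliberately above or below the validation thresholds: rate times
#' parent reads times opportunity count. For substitutions the
#' opportunity count is the clone length in bases, for indels the number
#' of homopolymer runs (length >= 2), for chimeras one (per read). The
#' expectation refers to the whole dataset (all replicates) and, for
#' chimeras, counts reads drawn with the clone as first parent.
#'
#' @param design a [mock_design()].
#' @param clone_id one of the design's clone ids.
#' @param type "substitution", "indel" or "chimera".
#' @return expected read count (real).
#' @export
expected_error_abundance <- function(design, clone_id,
                                     type = c("substitution", "indel",
                                              "chimera")) {
  stopifnot(inherits(design, "mock_design"))
  type <- match.arg(type)
  cl <- design$clones
  i <- match(clone_id, cl$clone_id)
  if (is.na(i)) stop("unknown clone: ", clone_id)
  p <- cl$concentration[i] / sum(cl$concentration)
  n_reads <- p * design$reads_per_replicate * design$n_replicates
  switch(type,
         substitution = design$sub_rate * nchar(cl$sequence[i]) * n_reads,
         indel = design$indel_rate *
           nrow(homopolymer_runs(cl$sequence[i])) * n_reads,
         chimera = design$chimera_rate * n_reads)
}

#' Write a simulation to disk (FASTA reads, MID map, truth table)
#' @param sim a `mock_sim`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_mock <- function(sim, dir) {
  stopifnot(inherits(sim, "mock_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$reads),
                              file.path(dir, "reads.fasta"))
  write_tsv(sim$design$mid_map, file.path(dir, "mid_map.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(file.path(dir, c("reads.fasta", "mid_map.tsv", "truth.tsv")))
}
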