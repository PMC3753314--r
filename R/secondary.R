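#' Substitution-error abundance threshold
#'
#' A candidate sequence differing from a more abundant co-occurring
#' sequence by `n` substitutions (and no indels) is treated as a potential
#' polymerase error and flagged invalid in that sample when its reads fall
#' strictly below \eqn{a x^n}: each additional mismatch makes an error
#' less likely by a factor `x`.
#'
#' @param a in-sample reads of the more abundant sequence (>= 1).
#' @param n number of nucleotide mismatches between the pair (>= 1;
#'   identical sequences cannot coexist as distinct table rows).
#' @param x per-mismatch proportion, in (0, 1]; default 0.02 in
#'   [error_params()].
#' @return the real-valued threshold \eqn{a x^n}; comparison is strict
#'   ("fewer than"), fractional thresholds are not rounded.
#' @examples
#' substitution_threshold(1000, 1, 0.02)  # 20
#' substitution_threshold(1000, 3, 0.02)  # 0.008
#' @export
substitution_threshold <- function(a, n, x) {
  stopifnot(a >= 1, n >= 1, n == as.integer(n), x > 0, x <= 1)
  a * x^n
}

#' Chimera abundance threshold
#'
#' A daughter explainable as a hybrid of two co-occurring parents with `s`
#' template switches is flagged invalid in that sample when its reads fall
#' strictly below \eqn{b y^s}, `b` being the in-sample reads of the less
#' abundant parent: each additional switch makes a PCR chimera less
#' likely by a factor `y`.
#'
#' @param b in-sample reads of the less abundant parent (>= 1).
#' @param s number of switches (>= 1; s = 0 means the daughter is not a
#'   chimera candidate and the threshold must not be applied).
#' @param y per-switch proportion, in (0, 1]; default 0.15 in
#'   [error_params()].
#' @return the real-valued threshold \eqn{b y^s}.
#' @examples
#' chimera_threshold(200, 1, 0.15)  # 30
#' chimera_threshold(200, 2, 0.15)  # 4.5
#' @export
chimera_threshold <- function(b, s, y) {
  stopifnot(b >= 1, s >= 1, s == as.integer(s), y > 0, y <= 1)
  b * y^s
}

#' Count parent switches of a potential chimera
#'
#' Scans the non-terminal columns of a three-way alignment from left to
#' right. If the daughter mismatches both parents at any non-terminal
#' column it cannot be their chimera and `NA` is returned. Otherwise the
#' informative columns (daughter matches exactly one parent) are read off
#' in order and the number of transitions between matching one parent and
#' matching the other is the switch count `s`. `s = 0` (the daughter
#' tracks a single parent) is a degenerate case, not a chimera.
#'
#' @param tri a [triple_alignment()].
#' @return integer switch count, or `NA` if the daughter is not a chimera
#'   candidate.
#' @examples
#' chimera_scan(align_triple("AAAATTTT", "CCCCGGGG", "AAAAGGGG"))  # 1
#' @export
chimera_scan <- function(tri) {
  stopifnot(inherits(tri, "triple_alignment"))
  cls <- tri$class[!tri$terminal]
  if (any(cls == "d_matches_neither")) return(NA_integer_)
  info <- cls[cls %in% c("d_matches_p1_only", "d_matches_p2_only")]
  if (length(info) < 2) return(0L)
  sum(info[-1] != info[-length(info)])
}

#' Indel-only relation between the two parents of a triple
#'
#' @param tri a [triple_alignment()].
#' @return TRUE when the parents differ only by indels (at least one
#'   non-terminal indel column, no substitution column).
#' @export
parents_indel_only <- function(tri) {
  stopifnot(inherits(tri, "triple_alignment"))
  pd <- tri$parent_diff[!tri$terminal]
  any(pd == "indel") && !any(pd == "substitution")
}

#' Within-sample secondary validation
#'
#' Ranks the sequences present in one sample by abundance and tests every
#' candidate daughter against the more abundant sequences of the same
#' sample, ignoring groups. Sequences with a single read in the sample are
#' labelled `ambiguous` and excluded from testing. Three tests can flag a
#' sequence invalid in the sample:
#' \itemize{
#'   \item \strong{indel}: the lower-ranked member of a pair differing only
#'     by indels is a potential pyrosequencing (homopolymer) error.
#'   \item \strong{substitution}: the lower-ranked member of a pair
#'     differing only by substitutions, with fewer than
#'     [substitution_threshold()] reads.
#'   \item \strong{chimera}: a daughter consistent with a hybrid of two
#'     higher-ranked parents, with fewer than [chimera_threshold()] reads.
#' }
#' Pair tests are applied to all ordered pairs; chimera triples enumerate
#' parent pairs in descending combined abundance. Testing of a daughter
#' stops at its first flag (further tests cannot change the outcome).
#' Flags are per-sample only: a sequence invalid here may be valid in
#' other samples.
#'
#' @param table an `abundance_table` (normally the filtered table).
#' @param sample sample (column) name to evaluate.
#' @param params an [error_params()].
#' @param max_parents optional cap on the number of higher-ranked
#'   sequences considered as parents for each daughter (guards cubic
#'   blow-up on very deep samples); default unlimited.
#' @return data.frame with one row per sequence present in the sample:
#'   `sequence_id`, `sample`, `status` (valid/invalid/ambiguous),
#'   `firing_test`, `parent1`, `parent2`, `threshold`, `observed_reads`.
#' @export
validate_sample <- function(table, sample, params = error_params(),
                            max_parents = Inf) {
  stopifnot(inherits(table, "abundance_table"),
            sample %in% table_samples(table),
            inherits(params, "error_params"))
  cnt_all <- table[[sample]]
  present <- which(cnt_all > 0)
  np <- length(present)
  out <- data.frame(sequence_id = table$sequence_id[present],
                    sample = rep(sample, np),
                    status = rep("valid", np),
                    firing_test = rep(NA_character_, np),
                    parent1 = rep(NA_character_, np),
                    parent2 = rep(NA_character_, np),
                    threshold = rep(NA_real_, np),
                    observed_reads = cnt_all[present],
                    stringsAsFactors = FALSE)
  if (length(present) == 0) return(out)
  out$status[out$observed_reads == 1L] <- "ambiguous"

  el <- which(out$observed_reads >= 2L)
  if (length(el) < 2) return(out)
  seqs <- table$sequence[present][el]
  ids <- out$sequence_id[el]
  cnt <- out$observed_reads[el]
  ord <- order_by_abundance(cnt, seqs)
  seqs <- seqs[ord]; ids <- ids[ord]; cnt <- cnt[ord]
  k <- length(ord)
  rowidx <- el[ord]  # rows of `out` in rank order

  flag <- function(j, test, p1, p2, thr) {
    out$status[rowidx[j]] <<- "invalid"
    out$firing_test[rowidx[j]] <<- test
    out$parent1[rowidx[j]] <<- p1
    out$parent2[rowidx[j]] <<- p2
    out$threshold[rowidx[j]] <<- thr
  }

  pair_cache <- new.env(parent = emptyenv())
  get_pair <- function(i, j) {
    key <- paste0(i, "_", j)
    if (!is.null(pc <- pair_cache[[key]])) return(pc)
    pair_cache[[key]] <- align_pair(seqs[i], seqs[j])
    pair_cache[[key]]
  }

  flagged <- rep(FALSE, k)
  # pairwise indel / substitution tests: lower-ranked member of each pair
  for (j in 2:k) {
    limit <- min(j - 1, max_parents)
    for (i in seq_len(limit)) {
      st <- get_pair(i, j)
      if (st$n_indel > 0 && st$n_sub == 0) {
        flag(j, "indel", ids[i], NA_character_, NA_real_)
        flagged[j] <- TRUE
      } else if (st$n_sub > 0 && st$n_indel == 0) {
        thr <- substitution_threshold(cnt[i], st$n_sub, params$sub_x)
        if (cnt[j] < thr) {
          flag(j, "substitution", ids[i], NA_character_, thr)
          flagged[j] <- TRUE
        }
      }
      if (flagged[j]) break
    }
  }
  # chimera triples for surviving daughters (need two distinct parents)
  if (k >= 3) {
    for (j in 3:k) {
      if (flagged[j]) next
      limit <- min(j - 1, max_parents)
      pairs <- combn(seq_len(limit), 2)
      comb <- cnt[pairs[1, ]] + cnt[pairs[2, ]]
      for (pi in order(-comb)) {
        i1 <- pairs[1, pi]; i2 <- pairs[2, pi]
        pa <- get_pair(i1, i2)
        tr <- .align_daughter_cpp(pa$a, pa$b, seqs[j])
        tri <- triple_alignment(tr$p1, tr$p2, tr$d)
        s <- chimera_scan(tri)
        if (!is.na(s) && s >= 1L) {
          thr <- chimera_threshold(cnt[i2], s, params$chi_y)
          if (cnt[j] < thr) {
            flag(j, "chimera", ids[i1], ids[i2], thr)
            flagged[j] <- TRUE
            break
          }
        }
      }
    }
  }
  out
}

#' Secondary validation over all samples
#'
#' Runs [validate_sample()] for every sample column of the table and
#' binds the per-sample flags.
#'
#' @inheritParams validate_sample
#' @return data.frame of per-(sequence, sample) flags.
#' @export
validate_all_samples <- function(table, params = error_params(),
                                 max_parents = Inf) {
  flags <- lapply(table_samples(table), function(s)
    validate_sample(table, s, params, max_parents))
  do.call(rbind, flags)
}
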