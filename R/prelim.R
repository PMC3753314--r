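# Cross-sample (preliminary) validation: within each group, provisionally
# accept or reject sequences from their abundance distribution across
# samples. Errors are expected to co-occur with their parent at much lower
# frequency; real related sequences occur in different samples or at high
# relative frequency.

# shared rare-sequence bounds, applied to top and additional sequences
# alike; returns NULL when passing, otherwise the rule that fired
rare_bounds_rule <- function(counts, total, params, mode) {
  if (max(counts) < 2L) return("local_singleton_only")
  if (mode == "MS") {
    if (total < params$rare_dataset_bound) {
      if (sum(counts > 0L) < 2L) return("rare_single_sample")
      if (total < params$rare_min_reads_ms) return("rare_too_few_reads")
    }
  } else {
    if (total < params$rare_min_reads_ss) return("rare_too_few_reads")
  }
  NULL
}

#' Preliminary validation of a group's most abundant sequence
#'
#' The most abundant sequence of a group is provisionally accepted unless
#' it is only ever observed as a local singleton, or (multi-sample mode)
#' it is rare (fewer than `rare_dataset_bound` reads in the dataset) and
#' observed in a single sample. Equivalently, a rare sequence must have at
#' least three reads, be present in more than one sample and have
#' multiple reads in at least one of them. Single-sample (SS) mode waives
#' the multiple-sample requirement, so two reads suffice.
#'
#' @param counts named integer vector of per-sample reads of the sequence.
#' @param params an [error_params()].
#' @param mode "MS" or "SS".
#' @return list with `accepted` (logical) and `rule` (the rule that fired,
#'   or "top_accepted").
#' @export
validate_top_sequence <- function(counts, params = error_params(),
                                  mode = c("MS", "SS")) {
  mode <- match.arg(mode)
  stopifnot(length(counts) >= 1, all(counts >= 0))
  rule <- rare_bounds_rule(counts, sum(counts), params, mode)
  if (is.null(rule)) list(accepted = TRUE, rule = "top_accepted")
  else list(accepted = FALSE, rule = rule)
}

#' Preliminary validation of an additional group member
#'
#' An additional sequence (ranked below the group's accepted top
#' sequence) is retained when it is observed in at least one sample where
#' the top sequence is absent, or when it co-occurs with the top sequence
#' at a relative frequency at least `freq_cutoff` (default 0.50) of the
#' top sequence's reads in at least one shared sample -- probable errors
#' of the top sequence co-occur at much lower frequency. The
#' rare-sequence bounds of [validate_top_sequence()] apply here too.
#'
#' @param counts named per-sample reads of the candidate sequence.
#' @param top_counts per-sample reads of the group's top sequence, same
#'   sample order.
#' @param params an [error_params()].
#' @param mode "MS" or "SS".
#' @return list with `accepted` and `rule`.
#' @export
validate_additional_sequence <- function(counts, top_counts,
                                         params = error_params(),
                                         mode = c("MS", "SS")) {
  mode <- match.arg(mode)
  stopifnot(length(counts) == length(top_counts))
  rule <- rare_bounds_rule(counts, sum(counts), params, mode)
  if (!is.null(rule)) return(list(accepted = FALSE, rule = rule))
  if (any(counts > 0L & top_counts == 0L))
    return(list(accepted = TRUE, rule = "different_samples"))
  if (any(top_counts > 0L & counts >= params$freq_cutoff * top_counts))
    return(list(accepted = TRUE, rule = "cooccur_high_frequency"))
  list(accepted = FALSE, rule = "below_frequency_cutoff")
}

#' Preliminary (cross-sample) validation of all groups
#'
#' Applies [validate_top_sequence()] to each group's highest-ranked
#' member and [validate_additional_sequence()] to the rest. When a
#' group's top sequence is rejected, the next-ranked member is promoted
#' and re-evaluated as the top, so a group is not annihilated by one bad
#' seed. Counts of rejected sequences play no further role.
#'
#' @param groups grouping data.frame (`group_id`, `sequence_id`,
#'   `rank_in_group`) from [group_by_besthit()] or
#'   [group_by_precluster()].
#' @param table the filtered `abundance_table`.
#' @param params an [error_params()].
#' @param mode "MS" or "SS".
#' @return data.frame `sequence_id`, `group_id`, `status`
#'   ("provisional"/"rejected"), `rule`.
#' @export
prelim_validate <- function(groups, table, params = error_params(),
                            mode = c("MS", "SS")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "abundance_table"))
  if (nrow(groups) == 0) {
    return(data.frame(sequence_id = character(), group_id = character(),
                      status = character(), rule = character(),
                      stringsAsFactors = FALSE))
  }
  cm <- count_matrix(table)
  res <- lapply(split(groups, groups$group_id), function(g) {
    g <- g[order(g$rank_in_group), , drop = FALSE]
    ids <- g$sequence_id
    status <- character(length(ids))
    rule <- character(length(ids))
    top_counts <- NULL
    for (i in seq_along(ids)) {
      counts <- cm[ids[i], ]
      if (is.null(top_counts)) {  # candidate top (original or promoted)
        v <- validate_top_sequence(counts, params, mode)
        if (v$accepted) top_counts <- counts
      } else {
        v <- validate_additional_sequence(counts, top_counts, params, mode)
      }
      status[i] <- if (v$accepted) "provisional" else "rejected"
      rule[i] <- v$rule
    }
    data.frame(sequence_id = ids, group_id = g$group_id,
               status = status, rule = rule, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(match(out$sequence_id, table$sequence_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
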