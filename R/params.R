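#' Error-model parameters
#'
#' The tunable constants of the validation rules. Defaults are the values
#' calibrated on positive-control Titanium 18S rRNA amplicon runs and are
#' deliberately conservative.
#'
#' @param freq_cutoff co-occurrence frequency cutoff of the cross-sample
#'   (preliminary) validation: an additional group member co-occurring with
#'   the group's most abundant sequence must reach this fraction of the top
#'   sequence's reads in at least one shared sample. Default 0.50.
#' @param rare_dataset_bound dataset read count below which a sequence is
#'   treated as "rare" and subjected to the multi-sample presence rule
#'   (multi-sample mode only). Default 10.
#' @param rare_min_reads_ms minimum dataset reads for a rare sequence in
#'   multi-sample (MS) mode; implied by presence in >1 sample with multiple
#'   reads in at least one. Default 3.
#' @param rare_min_reads_ss minimum reads for a sequence in single-sample
#'   (SS) mode, which waives the multi-sample presence requirement.
#'   Default 2.
#' @param sub_x per-mismatch abundance proportion of the substitution test:
#'   a daughter differing from a more abundant co-occurring sequence by
#'   \eqn{n} substitutions is flagged when its reads fall below
#'   \eqn{a x^n}, \eqn{a} being the parent's in-sample reads. Default 0.02.
#' @param chi_y per-switch abundance proportion of the chimera test: a
#'   daughter explained as a hybrid of two parents with \eqn{s} template
#'   switches is flagged when its reads fall below \eqn{b y^s}, \eqn{b}
#'   being the less abundant parent's in-sample reads. Default 0.15.
#' @return object of class `error_params` (a validated list).
#' @examples
#' error_params()
#' error_params(sub_x = 0.05)
#' @export
error_params <- function(freq_cutoff = 0.50, rare_dataset_bound = 10L,
                         rare_min_reads_ms = 3L, rare_min_reads_ss = 2L,
                         sub_x = 0.02, chi_y = 0.15) {
  stopifnot(
    freq_cutoff > 0, freq_cutoff <= 1,
    sub_x > 0, sub_x <= 1,
    chi_y > 0, chi_y <= 1,
    rare_dataset_bound >= 1, rare_min_reads_ms >= 1, rare_min_reads_ss >= 1,
    rare_min_reads_ss <= rare_min_reads_ms
  )
  structure(list(
    freq_cutoff = freq_cutoff,
    rare_dataset_bound = as.integer(rare_dataset_bound),
    rare_min_reads_ms = as.integer(rare_min_reads_ms),
    rare_min_reads_ss = as.integer(rare_min_reads_ss),
    sub_x = sub_x, chi_y = chi_y
  ), class = "error_params")
}

#' Replication design for final validation
#'
#' Describes how per-sample valid observations are combined into the final
#' keep/reject decision. Two threshold rules are supported: at least `k`
#' valid observations anywhere (`min_valid_obs`), or, when `blocks` is
#' given, a valid observation in every sample of at least one block (the
#' "all replicates within one sequencing center" style rule).
#'
#' @param mode "MS" (multi-sample; rare sequences must appear in more than
#'   one sample) or "SS" (single-sample; that requirement is waived).
#' @param min_valid_obs integer k >= 1; a sequence is retained when valid
#'   in at least k samples. Ignored when `blocks` is supplied. Default 1.
#' @param blocks optional named list partitioning sample names into
#'   replicate blocks, e.g. `list(centerA = c("a1","a2","a3"), ...)`.
#' @param samples optional character vector of all sample names; required
#'   when `blocks` is given (to check the partition).
#' @return object of class `replication_design`.
#' @examples
#' replication_design("MS", min_valid_obs = 4)
#' replication_design("SS")
#' @export
replication_design <- function(mode = c("MS", "SS"), min_valid_obs = 1L,
                               blocks = NULL, samples = NULL) {
  mode <- match.arg(mode)
  min_valid_obs <- as.integer(min_valid_obs)
  stopifnot(min_valid_obs >= 1L)
  if (!is.null(blocks)) {
    stopifnot(is.list(blocks), length(blocks) >= 1)
    all_block <- unlist(blocks, use.names = FALSE)
    if (anyDuplicated(all_block))
      stop("blocks must not share samples")
    if (!is.null(samples) && !setequal(all_block, samples))
      stop("blocks must partition the sample set")
  }
  structure(list(mode = mode, min_valid_obs = min_valid_obs,
                 blocks = blocks, samples = samples),
            class = "replication_design")
}

#' Theoretical detection floor of a replication design
#'
#' The minimum read abundance a sequence needs, in the whole dataset and
#' within a sample, to be validatable at all under a given replication
#' design. A valid observation in a sample requires at least 2 reads there
#' (single in-sample reads are ambiguous), so the dataset floor is twice
#' the number of samples that must simultaneously hold valid observations,
#' and never below the cross-sample rare-sequence floor (3 reads in MS mode
#' with k = 1; 2 reads in SS mode).
#'
#' @param design a [replication_design()].
#' @return named integer vector with elements `min_dataset_reads` and
#'   `min_sample_reads`.
#' @examples
#' detection_floor(replication_design("MS", min_valid_obs = 4)) # 8, 2
#' detection_floor(replication_design("SS"))                    # 2, 2
#' @export
detection_floor <- function(design) {
  stopifnot(inherits(design, "replication_design"))
  min_sample <- 2L
  if (design$mode == "SS") {
    return(c(min_dataset_reads = 2L, min_sample_reads = min_sample))
  }
  n_simul <- if (!is.null(design$blocks)) {
    min(lengths(design$blocks))
  } else {
    design$min_valid_obs
  }
  floor_ms <- max(2L * as.integer(n_simul), 3L)
  c(min_dataset_reads = floor_ms, min_sample_reads = min_sample)
}
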