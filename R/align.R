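#' Deterministic pairwise global alignment
#'
#' Global alignment with unit mismatch and gap costs, terminal gaps free,
#' and deterministic tie-breaking (match over substitution over a gap in
#' the shorter sequence; homopolymer gaps left-shifted). Column counts
#' exclude terminal-gap columns, consistent with the distance convention
#' used throughout the package.
#'
#' @param a,b nucleotide strings.
#' @return list with aligned strings `a`, `b` and the terminal-excluded
#'   counts `n_sub`, `n_indel`, `n_cols`, and `dist` =
#'   (n_sub + n_indel) / n_cols.
#' @examples
#' align_pair("ACGTT", "ACGT")
#' @export
align_pair <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  al <- .align_pair_cpp(a, b)
  c(al, .pair_stats_cpp(al$a, al$b))
}

#' Three-way alignment of two parents and a daughter
#'
#' The parents are aligned pairwise first; the daughter is then aligned to
#' the resulting two-row profile with the same cost scheme (a daughter
#' base matching either parent costs nothing, a daughter gap mirroring a
#' parent gap costs nothing, everything else one unit, terminal gaps
#' free). The result is deterministic.
#'
#' @param p1,p2 parent sequences, `p1` the more abundant.
#' @param d daughter sequence.
#' @return a `triple_alignment`; see [triple_alignment()].
#' @examples
#' align_triple("ACGT", "AGGT", "ACGT")
#' @export
align_triple <- function(p1, p2, d) {
  stopifnot(nzchar(p1), nzchar(p2), nzchar(d))
  pa <- .align_pair_cpp(p1, p2)
  tri <- .align_daughter_cpp(pa$a, pa$b, d)
  triple_alignment(tri$p1, tri$p2, tri$d)
}

#' Construct a classified three-way alignment from gapped strings
#'
#' Classifies every column by the daughter's relation to the parents
#' (`match_all`, `d_matches_p1_only`, `d_matches_p2_only`,
#' `d_matches_neither`) and by the parents' relation to each other
#' (`none`, `substitution`, `indel`). A gap character participates in
#' matching: a daughter gap shared with exactly one parent is informative
#' for that parent. Columns inside the leading or trailing gap run of any
#' of the three rows are flagged terminal and excluded from mismatch
#' counting and the chimera scan.
#'
#' @param p1_aln,p2_aln,d_aln equal-length gapped strings.
#' @return object of class `triple_alignment`: list with the three aligned
#'   strings, `class` (daughter relation per column), `parent_diff`
#'   (parent relation per column) and `terminal` (logical per column).
#' @export
triple_alignment <- function(p1_aln, p2_aln, d_aln) {
  L <- nchar(p1_aln)
  stopifnot(nchar(p2_aln) == L, nchar(d_aln) == L, L > 0)
  c1 <- strsplit(p1_aln, "")[[1]]
  c2 <- strsplit(p2_aln, "")[[1]]
  cd <- strsplit(d_aln, "")[[1]]
  if (any(c1 == "-" & c2 == "-" & cd == "-"))
    stop("all-gap column in triple alignment")

  cls <- ifelse(c1 == c2,
                ifelse(cd == c1, "match_all", "d_matches_neither"),
                ifelse(cd == c1, "d_matches_p1_only",
                       ifelse(cd == c2, "d_matches_p2_only",
                              "d_matches_neither")))
  pdiff <- ifelse(c1 == c2, "none",
                  ifelse(c1 == "-" | c2 == "-", "indel", "substitution"))

  terminal <- rep(FALSE, L)
  for (row in list(c1, c2, cd)) {
    nb <- which(row != "-")
    if (length(nb) == 0) stop("empty row in triple alignment")
    if (nb[1] > 1) terminal[seq_len(nb[1] - 1)] <- TRUE
    if (nb[length(nb)] < L) terminal[(nb[length(nb)] + 1):L] <- TRUE
  }

  structure(list(p1 = p1_aln, p2 = p2_aln, d = d_aln,
                 class = cls, parent_diff = pdiff, terminal = terminal),
            class = "triple_alignment")
}

#' @export
print.triple_alignment <- function(x, ...) {
  cat("p1: ", x$p1, "\np2: ", x$p2, "\nd:  ", x$d, "\n", sep = "")
  invisible(x)
}
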