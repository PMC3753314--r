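#' Group sequences by best-hit accession
#'
#' Partitions the filtered unique sequences into groups of presumed
#' conspecific (or at least co-derived) sequences using an externally
#' produced best-hit table: all sequences whose best database hit shares
#' an accession fall into one group. Hit scores play no role -- high
#' identity is not required. Sequences without a hit are treated as
#' unknown, non-target sequences: they are dropped from all downstream
#' group-wise validation.
#'
#' @param table an `abundance_table`.
#' @param hits named character vector mapping every `sequence_id` of the
#'   table to an accession, with `NA` marking no-hit. A missing id is a
#'   configuration error (the function refuses to guess).
#' @return list with `groups` (data.frame `group_id`, `sequence_id`,
#'   `rank_in_group`; members ranked by descending dataset reads, ties
#'   lexicographic by sequence) and `dropped` (character vector of no-hit
#'   sequence ids).
#' @export
group_by_besthit <- function(table, hits) {
  stopifnot(inherits(table, "abundance_table"))
  missing <- setdiff(table$sequence_id, names(hits))
  if (length(missing) > 0)
    stop("hit table does not cover sequence ids: ",
         paste(utils::head(missing, 5), collapse = ", "))
  acc <- hits[table$sequence_id]
  dropped <- table$sequence_id[is.na(acc)]
  keep <- !is.na(acc)
  # table rows are already in descending-abundance order with the
  # lexicographic tie-break, so within-group order is rank order
  ids <- table$sequence_id[keep]
  accs <- as.character(acc[keep])
  rank <- stats::ave(seq_along(ids), accs, FUN = seq_along)
  groups <- data.frame(group_id = accs, sequence_id = ids,
                       rank_in_group = as.integer(rank),
                       stringsAsFactors = FALSE)
  groups <- groups[order(match(groups$group_id, unique(groups$group_id)),
                         groups$rank_in_group), ]
  rownames(groups) <- NULL
  list(groups = groups, dropped = dropped)
}

#' Group sequences by abundance-sorted single-linkage preclustering
#'
#' Reference-free alternative to best-hit grouping: sequences are
#' processed in descending dataset abundance; each is attached to the
#' first existing group whose seed (most abundant member) lies within
#' `radius` pairwise distance (substitutions + indels over alignment
#' columns, terminal gaps excluded), otherwise it seeds a new group. With
#' `linkage = "transitive"` a sequence may instead attach to the first
#' group containing any member within the radius (full single linkage).
#' No sequence is dropped.
#'
#' @param table an `abundance_table`.
#' @param radius maximum distance to the group seed, in (0, 0.5);
#'   default 0.02 (the 2\% precluster convention).
#' @param linkage "seed" (default) or "transitive".
#' @return list with `groups` (as in [group_by_besthit()]) and an empty
#'   `dropped` vector.
#' @export
group_by_precluster <- function(table, radius = 0.02,
                                linkage = c("seed", "transitive")) {
  stopifnot(inherits(table, "abundance_table"), radius > 0, radius < 0.5)
  linkage <- match.arg(linkage)
  n <- nrow(table)
  if (n == 0)
    return(list(groups = data.frame(group_id = character(),
                                    sequence_id = character(),
                                    rank_in_group = integer()),
                dropped = character()))
  seqs <- table$sequence  # already abundance-sorted
  assign <- integer(n)
  members <- list()  # per group: indices in join order
  for (i in seq_len(n)) {
    hit <- 0L
    for (g in seq_along(members)) {
      targets <- if (linkage == "seed") members[[g]][1] else members[[g]]
      for (t in targets) {
        if (align_pair(seqs[t], seqs[i])$dist <= radius) { hit <- g; break }
      }
      if (hit > 0L) break
    }
    if (hit == 0L) {
      members[[length(members) + 1L]] <- i
      assign[i] <- length(members)
    } else {
      members[[hit]] <- c(members[[hit]], i)
      assign[i] <- hit
    }
  }
  gid <- sprintf("cl%04d", assign)
  rank <- stats::ave(seq_len(n), assign, FUN = seq_along)
  groups <- data.frame(group_id = gid, sequence_id = table$sequence_id,
                       rank_in_group = as.integer(rank),
                       stringsAsFactors = FALSE)
  groups <- groups[order(assign, groups$rank_in_group), ]
  rownames(groups) <- NULL
  list(groups = groups, dropped = character())
}

#' Read a best-hit table TSV
#'
#' Expected columns: `sequence_id`, `accession`, optionally `bitscore`
#' (stored but unused). The token "NA" (or an empty field) marks no-hit.
#'
#' @param file path of the TSV.
#' @return named character vector suitable for [group_by_besthit()].
#' @export
read_hit_table <- function(file) {
  h <- read.delim(file, stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
  stopifnot(all(c("sequence_id", "accession") %in% names(h)))
  setNames(as.character(h$accession), h$sequence_id)
}
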