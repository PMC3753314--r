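# shared fixtures and independent oracles, all built in code

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# mutate a sequence at k distinct positions (substitutions only)
mutate_subs <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# small demultiplexing spec used across ingest tests
tiny_spec <- function(min_length = 4L, truncate_at = NULL) {
  mids <- data.frame(sample = c("S1", "S2"),
                     forward_mid = c("AAAACCCC", "GGGGAAAA"),
                     reverse_mid = c("TTTTGGGG", "TTTTGGGG"),
                     stringsAsFactors = FALSE)
  primer_spec("TGGTGCATGG", "CATCTAAGGG", mids,
              min_length = min_length, truncate_at = truncate_at)
}

# wrap a trimmed amplicon into a raw read for the given sample
wrap_read <- function(seq, sample, spec) {
  mm <- spec$mid_map
  i <- match(sample, mm$sample)
  paste0(mm$forward_mid[i], spec$forward_primer, seq,
         revcomp(spec$reverse_primer), revcomp(mm$reverse_mid[i]))
}

# build an abundance_table directly from per-sample count vectors:
# counts is a named list sequence -> c(S1 = n1, S2 = n2, ...)
make_table <- function(counts, samples = NULL) {
  if (is.null(samples)) samples <- names(counts[[1]])
  acc <- do.call(rbind, lapply(names(counts), function(sq) {
    cc <- counts[[sq]]
    data.frame(sample = rep(names(cc), cc), sequence = sq,
               stringsAsFactors = FALSE)
  }))
  build_abundance_table(acc, samples = samples)
}

.grid_cache <- new.env(parent = emptyenv())

# independent oracle for the switch count: minimum number of parent-label
# transitions over all label assignments consistent with the informative
# columns, by exhaustive enumeration (alignments of <= 12 columns)
chimera_scan_oracle <- function(c1, c2, cd) {
  m <- length(c1)
  stopifnot(m <= 12)
  # daughter must match at least one parent everywhere
  if (any(cd != c1 & cd != c2)) return(NA_integer_)
  forced <- ifelse(c1 != c2 & cd == c1, 1L,
                   ifelse(c1 != c2 & cd == c2, 2L, NA_integer_))
  if (all(is.na(forced))) return(0L)
  key <- as.character(m)
  if (is.null(.grid_cache[[key]]))
    .grid_cache[[key]] <- as.matrix(expand.grid(rep(list(1:2), m)))
  grid <- .grid_cache[[key]]
  keep <- rep(TRUE, nrow(grid))
  for (j in which(!is.na(forced))) keep <- keep & grid[, j] == forced[j]
  grid <- grid[keep, , drop = FALSE]
  if (m == 1) return(0L)
  trans <- rowSums(grid[, -1, drop = FALSE] != grid[, -m, drop = FALSE])
  as.integer(min(trans))
}

# brute-force a * x^n by repeated multiplication (no pow call)
pow_oracle <- function(base, mult, k) {
  out <- base
  for (i in seq_len(k)) out <- out * mult
  out
}
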