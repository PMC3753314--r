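test_that("accept_and_trim demands exact primer/MID structure", {
  spec <- tiny_spec()
  read <- wrap_read("ACGTACGT", "S1", spec)
  r <- accept_and_trim(read, spec)
  expect_true(r$accepted)
  expect_identical(r$sequence, "ACGTACGT")
  expect_identical(r$sample, "S1")

  # one substitution inside the forward primer breaks the exact match
  bad <- read
  substr(bad, 9 + 3, 9 + 3) <- "A"  # forward primer starts at 9; TGG -> TGA
  r2 <- accept_and_trim(bad, spec)
  expect_false(r2$accepted)
  expect_identical(r2$reason, "no_forward_primer")

  # forward structure fine, reverse primer absent
  mm <- spec$mid_map
  norev <- paste0(mm$forward_mid[1], spec$forward_primer, "ACGTACGT")
  r3 <- accept_and_trim(norev, spec)
  expect_false(r3$accepted)
  expect_identical(r3$reason, "no_reverse_primer")

  # unknown forward MID with the primer at a plausible offset
  unk <- paste0("CCCCAAAA", spec$forward_primer, "ACGTACGT",
                revcomp(spec$reverse_primer), revcomp(mm$reverse_mid[1]))
  r4 <- accept_and_trim(unk, spec)
  expect_false(r4$accepted)
  expect_identical(r4$reason, "unknown_mid")

  # shorter than min_length after trimming
  r5 <- accept_and_trim(wrap_read("ACG", "S1", spec), spec)
  expect_false(r5$accepted)
  expect_identical(r5$reason, "too_short")
})

test_that("accept_and_trim is idempotent: trimmed output is rejected on re-entry", {
  spec <- tiny_spec()
  r <- accept_and_trim(wrap_read("ACGTACGTACGT", "S2", spec), spec)
  expect_true(r$accepted)
  r2 <- accept_and_trim(r$sequence, spec)
  expect_false(r2$accepted)
})

test_that("truncation mode skips the reverse primer and cuts the read", {
  spec <- tiny_spec(min_length = 4L, truncate_at = 6L)
  mm <- spec$mid_map
  read <- paste0(mm$forward_mid[1], spec$forward_primer, "ACGTACGTACGT")
  r <- accept_and_trim(read, spec)
  expect_true(r$accepted)
  expect_identical(r$sequence, "ACGTAC")
  expect_identical(r$sample, "S1")
})

test_that("demultiplex partitions reads and reasons are a fixed vocabulary", {
  spec <- tiny_spec()
  set.seed(11)
  good <- vapply(1:20, function(i) wrap_read(rand_seq(30), "S1", spec),
                 character(1))
  reads <- c(good, junk1 = "TTTTTTTTTTTTTTTTTTTTTTTT",
             junk2 = paste0(spec$mid_map$forward_mid[2],
                            spec$forward_primer, rand_seq(30)))
  names(reads)[1:20] <- sprintf("g%02d", 1:20)
  dm <- demultiplex(reads, spec)
  expect_equal(nrow(dm$accepted) + nrow(dm$rejected), length(reads))
  expect_setequal(intersect(dm$rejected$read_id, c("junk1", "junk2")),
                  c("junk1", "junk2"))
  expect_true(all(dm$rejected$reason %in%
                  c("no_forward_primer", "no_reverse_primer",
                    "unknown_mid", "too_short")))
})

test_that("abundance table bins identical sequences and counts exactly", {
  acc <- data.frame(sample = c("S1", "S1", "S1", "S2"),
                    sequence = rep("AAAC", 4))
  tab <- build_abundance_table(acc, samples = c("S1", "S2"))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$total_reads, 4L)
  expect_equal(tab$S1, 3L)
  expect_equal(tab$S2, 1L)

  empty <- build_abundance_table(acc[0, ], samples = c("S1", "S2"))
  expect_equal(nrow(empty), 0)

  two <- build_abundance_table(
    data.frame(sample = c("S1", "S1"), sequence = c("AAAC", "AAAT")),
    samples = "S1")
  expect_equal(nrow(two), 2)
})

test_that("prefilter removes Ns, embedded primers and global singletons only", {
  spec <- tiny_spec()
  set.seed(3)
  keepseq <- rand_seq(40)
  localsing <- rand_seq(40)
  counts <- list()
  counts[[keepseq]] <- c(S1 = 5L, S2 = 2L)
  counts[[localsing]] <- c(S1 = 1L, S2 = 2L)
  counts[[paste0(substr(rand_seq(40), 1, 20), "N", rand_seq(19))]] <-
    c(S1 = 4L, S2 = 4L)
  counts[[paste0(rand_seq(10), spec$forward_primer, rand_seq(10))]] <-
    c(S1 = 3L, S2 = 3L)
  counts[[rand_seq(41)]] <- c(S1 = 1L, S2 = 0L)  # global singleton
  tab <- make_table(counts, samples = c("S1", "S2"))
  pf <- prefilter(tab, spec)
  expect_setequal(pf$table$sequence, c(keepseq, localsing))
  expect_setequal(pf$removed$reason,
                  c("ambiguous_base", "multiple_primer", "global_singleton"))
  # no sequence below two dataset reads survives
  expect_true(all(pf$table$total_reads >= 2))
})

test_that("table construction is order-independent", {
  spec <- tiny_spec()
  set.seed(21)
  seqs <- replicate(6, rand_seq(30))
  reads <- unlist(lapply(seq_along(seqs), function(i) {
    n <- sample(1:4, 1)
    setNames(rep(wrap_read(seqs[i], sample(c("S1", "S2"), 1), spec), n),
             sprintf("r%d_%d", i, seq_len(n)))
  }))
  t1 <- build_abundance_table(demultiplex(reads, spec)$accepted,
                              samples = c("S1", "S2"))
  perm <- sample(length(reads))
  t2 <- build_abundance_table(demultiplex(reads[perm], spec)$accepted,
                              samples = c("S1", "S2"))
  expect_identical(t1, t2)
})
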