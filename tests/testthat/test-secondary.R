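test_that("threshold formulas match direct arithmetic", {
  expect_equal(substitution_threshold(1000, 1, 0.02), 20)
  expect_equal(substitution_threshold(1000, 3, 0.02), 0.008)
  expect_equal(substitution_threshold(50, 2, 0.5), 12.5)
  expect_equal(chimera_threshold(200, 1, 0.15), 30)
  expect_equal(chimera_threshold(200, 2, 0.15), 4.5)
  expect_equal(chimera_threshold(10, 3, 0.15), 0.03375)
  expect_error(substitution_threshold(100, 0, 0.02))
  expect_error(chimera_threshold(100, 0, 0.15))
})

test_that("thresholds are monotone in their proportions and exponents", {
  set.seed(13)
  for (i in 1:200) {
    a <- sample(1:5000, 1); n <- sample(1:6, 1); x <- runif(1, 0.01, 0.99)
    expect_lt(substitution_threshold(a, n + 1, x),
              substitution_threshold(a, n, x))
    expect_gt(substitution_threshold(a, n, min(x * 1.5, 1)),
              substitution_threshold(a, n, x))
    expect_lt(chimera_threshold(a, n + 1, x), chimera_threshold(a, n, x))
    expect_gt(chimera_threshold(a, n, min(x * 1.5, 1)),
              chimera_threshold(a, n, x))
  }
})

test_that("three-way alignment classifies columns correctly", {
  t1 <- align_triple("ACGT", "ACGT", "ACGT")
  expect_true(all(t1$class == "match_all"))

  t2 <- align_triple("ACGT", "AGGT", "ACGT")
  expect_equal(sum(t2$parent_diff == "substitution"), 1)
  expect_identical(t2$class[t2$parent_diff == "substitution"],
                   "d_matches_p1_only")

  t3 <- align_triple("ACGTT", "ACGT", "ACGT")
  expect_equal(sum(t3$parent_diff == "indel"), 1)
  # ungapping recovers the inputs
  expect_identical(gsub("-", "", t3$p1), "ACGTT")
  expect_identical(gsub("-", "", t3$p2), "ACGT")
  expect_identical(gsub("-", "", t3$d), "ACGT")
})

test_that("chimera scan counts switches and vetoes double mismatches", {
  set.seed(23)
  p1 <- rand_seq(80); p2 <- mutate_subs(p1, sample(80, 30))
  d <- paste0(substr(p1, 1, 40), substr(p2, 41, 80))
  expect_equal(chimera_scan(align_triple(p1, p2, d)), 1L)
  # daughter identical to one parent: degenerate, no switches
  expect_equal(chimera_scan(align_triple(p1, p2, p1)), 0L)
  # daughter mismatching both parents internally: not a chimera candidate
  dbad <- mutate_subs(d, 20)
  while (substr(dbad, 20, 20) %in% c(substr(p1, 20, 20), substr(p2, 20, 20)))
    dbad <- mutate_subs(d, 20)
  expect_true(is.na(chimera_scan(align_triple(p1, p2, dbad))))
  # two-breakpoint hybrid
  d2 <- paste0(substr(p1, 1, 25), substr(p2, 26, 55), substr(p1, 56, 80))
  expect_equal(chimera_scan(align_triple(p1, p2, d2)), 2L)
})

test_that("switch count equals the exhaustive-enumeration oracle", {
  set.seed(29)
  bases <- c("A", "C", "G")
  for (i in 1:300) {
    m <- sample(3:12, 1)
    c1 <- sample(bases, m, replace = TRUE)
    c2 <- sample(bases, m, replace = TRUE)
    cd <- ifelse(runif(m) < 0.5, c1,
                 ifelse(runif(m) < 0.8, c2, sample(bases, m, replace = TRUE)))
    tri <- triple_alignment(paste(c1, collapse = ""),
                            paste(c2, collapse = ""),
                            paste(cd, collapse = ""))
    expect_identical(chimera_scan(tri), chimera_scan_oracle(c1, c2, cd))
  }
})

test_that("indel-only pairs flag the lower-ranked member in the sample", {
  set.seed(37)
  base <- rand_seq(100)
  # delete one base of a homopolymer run
  runs <- gregexpr("(A{2,}|C{2,}|G{2,}|T{2,})", base)[[1]]
  pos <- runs[1]
  indel <- paste0(substr(base, 1, pos - 1), substring(base, pos + 1))
  tab <- make_table(setNames(list(c(S1 = 200L), c(S1 = 30L)),
                             c(base, indel)), samples = "S1")
  fl <- validate_sample(tab, "S1")
  expect_identical(fl$status[fl$observed_reads == 200L], "valid")
  expect_identical(fl$status[fl$observed_reads == 30L], "invalid")
  expect_identical(fl$firing_test[fl$observed_reads == 30L], "indel")

  # one gap AND one substitution: the indel test must not fire
  mixed <- mutate_subs(indel, 50)
  tab2 <- make_table(setNames(list(c(S1 = 200L), c(S1 = 30L)),
                              c(base, mixed)), samples = "S1")
  fl2 <- validate_sample(tab2, "S1")
  expect_true(all(fl2$status == "valid"))
})

test_that("substitution test flags below a*x^n with strict inequality", {
  set.seed(41)
  parent <- rand_seq(120)
  daughter <- mutate_subs(parent, 60)  # one mismatch
  for (reads in c(19L, 20L)) {
    tab <- make_table(setNames(list(c(S1 = 1000L), c(S1 = reads)),
                               c(parent, daughter)), samples = "S1")
    fl <- validate_sample(tab, "S1")
    got <- fl$status[fl$observed_reads == reads]
    if (reads < 20L) {
      expect_identical(got, "invalid")
      expect_identical(fl$firing_test[fl$observed_reads == reads],
                       "substitution")
      expect_equal(fl$threshold[fl$observed_reads == reads], 20)
    } else {
      expect_identical(got, "valid")  # 20 reads is not fewer than 20
    }
  }
})

test_that("chimera test uses the less abundant parent and strict inequality", {
  set.seed(43)
  p1 <- rand_seq(100); p2 <- mutate_subs(p1, sample(100, 35))
  d <- paste0(substr(p1, 1, 50), substr(p2, 51, 100))
  for (reads in c(29L, 30L)) {
    tab <- make_table(setNames(list(c(S1 = 500L), c(S1 = 200L), c(S1 = reads)),
                               c(p1, p2, d)), samples = "S1")
    fl <- validate_sample(tab, "S1")
    got <- fl$status[fl$observed_reads == reads]
    if (reads < 30L) {
      expect_identical(got, "invalid")
      expect_identical(fl$firing_test[fl$observed_reads == reads], "chimera")
      expect_equal(fl$threshold[fl$observed_reads == reads], 30)  # 200 * 0.15
    } else {
      expect_identical(got, "valid")
    }
  }
})

test_that("within-sample validation statuses behave at the boundaries", {
  set.seed(47)
  # a lone sequence with several reads: valid (no triples possible)
  lone <- make_table(setNames(list(c(S1 = 5L)), rand_seq(50)), samples = "S1")
  expect_identical(validate_sample(lone, "S1")$status, "valid")
  # single-read sequences are ambiguous regardless of tests
  parent <- rand_seq(80)
  tab <- make_table(setNames(list(c(S1 = 1000L), c(S1 = 1L)),
                             c(parent, mutate_subs(parent, 10))),
                    samples = "S1")
  fl <- validate_sample(tab, "S1")
  expect_identical(fl$status[fl$observed_reads == 1L], "ambiguous")
})

test_that("flags are deterministic and never cross samples", {
  tab <- pipeline42$table
  fl1 <- validate_all_samples(tab)
  perm <- tab[sample(nrow(tab)), , drop = FALSE]
  rownames(perm) <- NULL
  class(perm) <- c("abundance_table", "data.frame")
  fl2 <- validate_all_samples(perm)
  key <- function(f) f[order(f$sequence_id, f$sample),
                       c("sequence_id", "sample", "status", "firing_test")]
  o1 <- key(fl1); o2 <- key(fl2)
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)

  # zeroing another sample's counts leaves this sample's flags unchanged
  mod <- tab
  mod[["rep2"]] <- 0L
  mod$total_reads <- as.integer(rowSums(mod[, table_samples(mod)]))
  class(mod) <- c("abundance_table", "data.frame")
  f_before <- validate_sample(tab, "rep1")
  f_after <- validate_sample(mod, "rep1")
  expect_identical(f_before, f_after)
})

test_that("the most abundant sequence of a sample is never flagged", {
  set.seed(53)
  for (rep in 1:5) {
    base <- rand_seq(90)
    counts <- setNames(list(c(S1 = 500L)), base)
    for (i in 1:4)
      counts[[mutate_subs(base, sample(90, sample(1:3, 1)))]] <-
        c(S1 = sample(2:50, 1))
    tab <- make_table(counts, samples = "S1")
    fl <- validate_sample(tab, "S1")
    expect_identical(fl$status[fl$observed_reads == 500L], "valid")
  }
})
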