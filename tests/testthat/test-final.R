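flags_from <- function(per_seq) {
  # per_seq: named list sequence_id -> named status vector by sample
  do.call(rbind, lapply(names(per_seq), function(id) {
    st <- per_seq[[id]]
    data.frame(sequence_id = id, sample = names(st), status = unname(st),
               firing_test = NA_character_, parent1 = NA_character_,
               parent2 = NA_character_, threshold = NA_real_,
               observed_reads = ifelse(st == "ambiguous", 1L, 2L),
               stringsAsFactors = FALSE)
  }))
}

prelim_from <- function(ids, status = "provisional") {
  data.frame(sequence_id = ids, group_id = "G", status = status,
             rule = "top_accepted", stringsAsFactors = FALSE)
}

test_that("final validation counts valid observations against k", {
  set.seed(61)
  samples <- sprintf("rep%d", 1:5)
  sq <- c(a = rand_seq(50), b = rand_seq(50), c = rand_seq(50))
  tab <- make_table(setNames(
    list(setNames(rep(2L, 5), samples),
         setNames(rep(2L, 5), samples),
         setNames(rep(1L, 5), samples)), sq), samples = samples)
  ids <- setNames(tab$sequence_id, tab$sequence)
  fl <- flags_from(setNames(list(
    setNames(c("valid", "valid", "valid", "valid", "invalid"), samples),
    setNames(c("valid", "invalid", "invalid", "invalid", "invalid"), samples),
    setNames(rep("ambiguous", 5), samples)
  ), ids[sq]))
  prelim <- prelim_from(unname(ids))
  led <- finalize(fl, prelim, replication_design("MS", min_valid_obs = 4), tab)
  expect_identical(led$final_status[led$sequence_id == ids[sq["a"]]], "valid")
  expect_identical(led$final_status[led$sequence_id == ids[sq["b"]]], "rejected")
  # ambiguous observations never count, even with k = 1
  led1 <- finalize(fl, prelim, replication_design("MS", min_valid_obs = 1), tab)
  expect_identical(led1$final_status[led1$sequence_id == ids[sq["c"]]],
                   "rejected")
  # and with zero valid observations a sequence is always rejected
  expect_equal(led$n_valid[led$sequence_id == ids[sq["c"]]], 0L)
})

test_that("raising k never enlarges the validated set", {
  fl <- pipeline42$flags
  prelim <- pipeline42$prelim
  tab <- pipeline42$table
  prev <- NULL
  for (k in 1:5) {
    led <- finalize(fl, prelim, replication_design("MS", min_valid_obs = k),
                    tab)
    v <- led$sequence_id[led$final_status == "valid"]
    if (!is.null(prev)) expect_true(all(v %in% prev))
    prev <- v
  }
})

test_that("block rule demands a fully valid block", {
  set.seed(67)
  samples <- sprintf("s%d", 1:6)
  blocks <- list(c1 = samples[1:3], c2 = samples[4:6])
  sq <- c(a = rand_seq(50), b = rand_seq(50))
  tab <- make_table(setNames(
    list(setNames(rep(2L, 6), samples), setNames(rep(2L, 6), samples)), sq),
    samples = samples)
  ids <- setNames(tab$sequence_id, tab$sequence)
  fl <- flags_from(setNames(list(
    setNames(c("valid", "valid", "valid", "invalid", "invalid", "invalid"),
             samples),                      # full block c1
    setNames(c("valid", "valid", "invalid", "valid", "valid", "invalid"),
             samples)                       # 2+2, no full block
  ), ids[sq]))
  design <- replication_design("MS", blocks = blocks, samples = samples)
  led <- finalize(fl, prelim_from(unname(ids)), design, tab)
  expect_identical(led$final_status[led$sequence_id == ids[sq["a"]]], "valid")
  expect_identical(led$final_status[led$sequence_id == ids[sq["b"]]],
                   "rejected")
  # referencing unknown samples is a configuration error
  bad <- replication_design("MS", blocks = list(x = c("s1", "nope")))
  expect_error(finalize(fl, prelim_from(unname(ids)), bad, tab), "unknown")
})

test_that("detection floors follow the replication design", {
  # 4-of-5 technical replicates
  expect_equal(unname(detection_floor(
    replication_design("MS", min_valid_obs = 4))), c(8L, 2L))
  # all three replicates of at least one of four centers
  blocks <- split(sprintf("s%d", 1:12), rep(1:4, each = 3))
  expect_equal(unname(detection_floor(
    replication_design("MS", blocks = blocks,
                       samples = sprintf("s%d", 1:12)))), c(6L, 2L))
  # default single valid observation, multi-sample
  expect_equal(unname(detection_floor(replication_design("MS"))), c(3L, 2L))
  # single-sample variant
  expect_equal(unname(detection_floor(replication_design("SS"))), c(2L, 2L))
})
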