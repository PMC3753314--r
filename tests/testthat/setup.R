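# shared study-condition objects, built once per test run: the default
# 16-clone, 5-replicate mock community (seed 42) and its full pipeline run
mock42 <- local({
  design <- mock_design(seed = 42)
  sim <- simulate_mock(design)
  list(design = design, sim = sim, spec = mock_spec(design))
})

pipeline42 <- local({
  t0 <- Sys.time()
  res <- run_pipeline(mock42$sim$reads, mock42$spec,
                      replication_design("MS", min_valid_obs = 4))
  attr(res, "elapsed_secs") <-
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res
})
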