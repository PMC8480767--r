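test_that("session generation is reproducible and structurally valid", {
  s1 <- generate_session(100, seed = 42)
  s2 <- generate_session(100, seed = 42)
  expect_identical(s1, s2)
  expect_silent(validate_session(s1))
  # timing: every image presentation followed by exactly two gray frames
  pres <- which(s1$frame_kind != "gray")
  expect_true(all(diff(pres) == 3L))
  expect_true(all(s1$frame_kind[setdiff(seq_len(nrow(s1)), pres)] == "gray"))
})

test_that("omission placement respects the task constraints", {
  for (seed in 1:5) {
    s <- generate_session(200, p_omit = 0.15, seed = seed)
    p <- presentation_info(s)
    ev <- p$is_change | p$is_sham_change
    expect_false(any(p$omitted & ev))
    expect_false(any(p$omitted[-nrow(p)] & ev[-1L]))
  }
  s0 <- generate_session(200, p_omit = 0, seed = 1)
  expect_false(any(s0$frame_kind == "omitted"))
})

test_that("omission rate matches its hazard within the binomial 99% interval", {
  s <- generate_session(1700, p_omit = 0.05, seed = 7)
  p <- presentation_info(s)
  expect_gt(nrow(p), 10000)
  ev <- p$is_change | p$is_sham_change
  eligible <- !ev & !c(ev[-1L], FALSE)   # where the omission hazard applies
  n <- sum(eligible)
  n_om <- sum(p$omitted)
  expect_gte(n_om, qbinom(0.005, n, 0.05))
  expect_lte(n_om, qbinom(0.995, n, 0.05))
})

test_that("repeat counts follow the truncated geometric law on [4, 11]", {
  s <- generate_session(10000, seed = 11)
  p <- presentation_info(s)
  ev <- which(p$is_change | p$is_sham_change)
  gaps <- diff(ev)                      # presentations between events
  expect_true(all(gaps >= 4 & gaps <= 11))
  # goodness of fit against the specified hazard-0.3 law truncated at 11
  ks <- 4:11
  pk <- 0.3 * 0.7^(ks - 4)
  pk[8] <- 0.7^7
  obs <- tabulate(gaps - 3L, nbins = 8L)
  expect_gt(suppressWarnings(chisq.test(obs, p = pk)$p.value), 0.001)
})

test_that("change and sham events behave as labeled", {
  s <- generate_session(500, seed = 3)
  p <- presentation_info(s)
  i <- which(p$is_change)
  expect_true(all(p$image_id[i] != p$image_id[i - 1L]))
  j <- which(p$is_sham_change)
  expect_true(all(p$image_id[j] == p$image_id[j - 1L]))
  # repeat counter restarts at each scheduled event
  expect_true(all(p$repeat_index[c(i, j)] == 1L))
})

test_that("sessions round-trip through the delimited format", {
  s <- generate_session(30, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_session(s, path)
  s2 <- read_session(path)
  expect_equal(as.data.frame(s), as.data.frame(s2))
  expect_equal(attr(s2, "dt"), attr(s, "dt"))
  expect_error(read_session(withr::local_tempfile(lines = "x\ty")),
               "magic")
})

test_that("invalid generator parameters are rejected", {
  expect_error(generate_session(10, p_omit = 1.2), "probability")
  expect_error(generate_session(10, min_repeats = 8, max_repeats = 5),
               "max_repeats")
  expect_error(generate_session(0), "n_trials")
})
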