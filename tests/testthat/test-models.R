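make_par <- function(kind, seed = 1, n_input = 64, n_hidden = 16) {
  set.seed(seed)
  changenet:::init_weights(kind, n_input, n_hidden)
}

test_that("multiplicative noise preserves zeros and is nearly mean-neutral", {
  a <- c(0, 1, 2, 0, 5)
  expect_identical(apply_noise(a, 0), a)
  set.seed(1)
  out <- apply_noise(rep(0, 1000), 0.5)
  expect_true(all(out == 0))
  set.seed(2)
  draws <- replicate(4000, apply_noise(c(1, 2), 0.5))
  bias <- rowMeans(draws) / c(1, 2) - 1
  expect_lt(max(abs(bias)), 0.05)  # rectification bias stays small
  expect_error(apply_noise(c(-1, 1), 0.5), "non-negative")
})

test_that("noise-free STPNet forward pass matches the depression oracle", {
  emb <- generate_embeddings(seed = 10)
  sess <- generate_session(10, p_omit = 0, seed = 10)
  par <- make_par("stpnet", seed = 10)
  run <- run_session(par, "stpnet", sess, emb, noise_sd = 0)
  # independent R-side replay with step_depression and plain matrix algebra
  p <- stp_params()
  inp <- changenet:::session_inputs(sess, emb)
  x <- rep(1, 64)
  for (t in seq_len(nrow(sess))) {
    x <- step_depression(x, inp$drive[t, ], p)
    h <- pmax(0, drop(par$W_ad %*% (x * inp$drive[t, ])) + par$b_h)
    z <- sum(par$w_out * h) + par$b_out
    expect_equal(run$x[t, ], x, tolerance = 1e-10)
    expect_equal(run$hidden[t, ], h, tolerance = 1e-10)
    expect_equal(run$logits[t], z, tolerance = 1e-10)
  }
})

test_that("vanishing release fraction reduces STPNet to a static network", {
  emb <- generate_embeddings(seed = 11)
  sess <- generate_session(20, seed = 11)
  par <- make_par("stpnet", seed = 11)
  run <- run_session(par, "stpnet", sess, emb, noise_sd = 0,
                     stp = stp_params(U = 1e-12))
  inp <- changenet:::session_inputs(sess, emb)
  static <- t(apply(inp$drive, 1, function(r)
    pmax(0, drop(par$W_ad %*% r) + par$b_h)))
  expect_equal(run$hidden, static, tolerance = 1e-6)
})

test_that("STPRNN reduces to RNN and STPNet under weight zeroing", {
  emb <- generate_embeddings(seed = 12)
  sess <- generate_session(30, seed = 12)
  par3 <- make_par("stprnn", seed = 12)

  parR <- par3[c("W_pl", "W_rec", "b_h", "w_out", "b_out")]
  parR$W_ad <- matrix(0, 0, 0)
  z3 <- par3
  z3$W_ad[] <- 0
  set.seed(77)
  run3 <- run_session(z3, "stprnn", sess, emb)
  set.seed(77)
  runR <- run_session(parR, "rnn", sess, emb)
  expect_equal(run3$logits, runR$logits, tolerance = 1e-10)
  expect_equal(run3$hidden, runR$hidden, tolerance = 1e-10)

  parS <- par3[c("W_ad", "b_h", "w_out", "b_out")]
  parS$W_pl <- matrix(0, 0, 0)
  parS$W_rec <- matrix(0, 0, 0)
  z3 <- par3
  z3$W_pl[] <- 0
  z3$W_rec[] <- 0
  set.seed(78)
  run3 <- run_session(z3, "stprnn", sess, emb)
  set.seed(78)
  runS <- run_session(parS, "stpnet", sess, emb)
  expect_equal(run3$logits, runS$logits, tolerance = 1e-10)
})

test_that("hidden activity is non-negative and zero input silences STPNet", {
  emb <- generate_embeddings(seed = 13)
  sess <- generate_session(60, p_omit = 0.1, seed = 13)
  par <- make_par("stpnet", seed = 13)
  set.seed(13)
  run <- run_session(par, "stpnet", sess, emb, noise_sd = 0.5)
  expect_true(all(run$hidden >= 0))
  om <- sess$step[sess$frame_kind == "omitted"]
  gray <- sess$step[sess$frame_kind == "gray"]
  run0 <- run_session(par, "stpnet", sess, emb, noise_sd = 0)
  expect_true(all(run0$hidden[c(om, gray), ] == 0))
})

test_that("recurrence carries activity through omissions", {
  emb <- generate_embeddings(seed = 14)
  sess <- generate_session(60, p_omit = 0.1, seed = 14)
  par <- make_par("rnn", seed = 14)
  par$W_pl <- abs(par$W_pl)         # positive pathways guarantee propagation
  par$W_rec <- abs(par$W_rec) / 10  # stable: spectral radius well below 1
  par$b_h[] <- 0
  run <- run_session(par, "rnn", sess, emb, noise_sd = 0)
  om <- sess$step[sess$frame_kind == "omitted"]
  om <- om[om > 1]
  pre_active <- rowSums(run$hidden[om - 1L, , drop = FALSE]) > 0
  expect_true(any(pre_active))
  expect_true(all(rowSums(run$hidden[om, , drop = FALSE])[pre_active] > 0))
})

test_that("empty sessions and mismatched embeddings are handled", {
  emb <- generate_embeddings(seed = 15)
  sess <- generate_session(5, n_images = 4, seed = 15)
  expect_error(run_session(make_par("rnn"), "rnn", sess, emb), "image set")
})
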