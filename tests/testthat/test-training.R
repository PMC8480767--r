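test_that("masked weighted cross-entropy matches hand-computed values", {
  # single masked label-1 step at logit 0: 5 * ln 2
  expect_equal(compute_loss(0, 1, 1), 5 * log(2))
  # saturated logits with zero activity drive the loss to ~0
  expect_lt(compute_loss(c(30, -30), c(1, 0), c(1, 1)), 1e-10)
  # masked-out steps contribute nothing
  l1 <- compute_loss(c(0, 3), c(1, 0), c(1, 0))
  l2 <- compute_loss(c(0, -7), c(1, 0), c(1, 0))
  expect_equal(l1, l2)
  # all-masked-out batch: activity penalty only
  h <- matrix(2, 3, 2)
  expect_equal(compute_loss(c(1, 2, 3), c(0, 0, 0), c(0, 0, 0), h), 0.001 * 4)
})

test_that("R loss agrees with the compiled training loss", {
  emb <- generate_embeddings(seed = 20)
  sess <- generate_session(20, seed = 20)
  par <- changenet:::init_weights("rnn", 64, 16)
  set.seed(20)
  run <- run_session(par, "rnn", sess, emb, noise_sd = 0.5)
  expect_equal(run$loss,
               compute_loss(run$logits, run$y, run$mask, run$hidden),
               tolerance = 1e-10)
})

test_that("compiled gradients match finite differences", {
  emb <- generate_embeddings(seed = 21)
  sess <- generate_session(5, seed = 21)
  par <- changenet:::init_weights("stprnn", 64, 4)
  # move thresholds off zero so no unit sits exactly on the relu kink at
  # zero-input steps (finite differences are one-sided at a kink)
  par$b_h <- c(-0.05, 0.03, -0.02, 0.04)
  loss_at <- function(p) run_session(p, "stprnn", sess, emb,
                                     noise_sd = 0)$loss
  run <- run_session(par, "stprnn", sess, emb, noise_sd = 0, grad = TRUE)
  eps <- 1e-6
  for (nm in c("W_ad", "W_pl", "W_rec", "b_h", "w_out", "b_out")) {
    idx <- if (length(par[[nm]]) > 3) c(1, 3) else 1
    for (i in idx) {
      up <- dn <- par
      up[[nm]][i] <- up[[nm]][i] + eps
      dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_lt(abs(run$grads[[nm]][i] - num), 1e-5 + 1e-3 * abs(num))
    }
  }
})

test_that("d-prime matches standard-normal quantiles and clips extremes", {
  expect_equal(dprime(0.5, 0.5, 100, 100), 0)
  expect_equal(dprime(0.841345, 0.158655, 1e6, 1e6), 2, tolerance = 1e-4)
  expect_equal(dprime(1, 0, 50, 50), qnorm(0.99) - qnorm(0.01))
  expect_equal(dprime(0.2, 0.7, 100, 100), -dprime(0.7, 0.2, 100, 100))
  expect_error(dprime(0.5, 0.5, 0, 10), "n_go")
})

test_that("a vacuous criterion stops training after exactly patience epochs", {
  fit <- changenet("stpnet", seed = 30,
                   control = train_control(trials_per_epoch = 10,
                                           max_epochs = 50,
                                           dprime_criterion = -Inf,
                                           patience = 5))
  expect_equal(fit$stop_epoch, 5L)
  expect_equal(fit$stop_reason, "criterion")
  # criterion held for >= patience consecutive epochs at stop
  tail_dp <- tail(fit$history$dprime, 5)
  expect_true(all(tail_dp >= -Inf))
})

test_that("training is deterministic given the seed", {
  f1 <- changenet("rnn", seed = 31, control = quick_control())
  f2 <- changenet("rnn", seed = 31, control = quick_control())
  expect_identical(f1$par, f2$par)
  expect_identical(f1$history, f2$history)
})

test_that("loss trends downward over early training", {
  drops <- vapply(1:3, function(s) {
    fit <- changenet("stpnet", seed = 40 + s,
                     control = train_control(trials_per_epoch = 50,
                                             max_epochs = 40))
    h <- fit$history$loss
    mean(h[1:5]) - mean(tail(h, 5))
  }, 0)
  expect_gt(mean(drops), 0)
})

test_that("model methods expose the fit coherently", {
  fit <- quick_fit("stpnet", 1)
  expect_s3_class(fit, "changenet")
  expect_output(print(fit), "STPNET")
  sm <- summary(fit)
  expect_output(print(sm), "weight norms")
  expect_named(coef(fit),
               c("W_ad", "W_pl", "W_rec", "b_h", "w_out", "b_out"))
  expect_true(all(coef(fit)$b_h <= 0))
  res <- residuals(fit)
  expect_true(all(abs(res) <= 1))
  run <- predict(fit, n_trials = 20, seed = 5)
  expect_s3_class(run, "changenet_run")
  sims <- simulate(fit, nsim = 2, seed = 6, n_trials = 20)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "changenet_eval")
})

test_that("a short recovery-constant sweep runs per-cell without aborting", {
  sw <- sweep_training("tau_x", c(0.05, 1.5), kind = "stpnet", seeds = 1,
                       control = quick_control())
  expect_equal(nrow(sw), 2)
  expect_true(all(is.na(sw$error)))
  expect_true(all(sw$stop_epoch <= 30))
})
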