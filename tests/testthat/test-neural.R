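# small labeled response fixture built by hand
fixture_pr <- function(rc, rp, n_each = 20) {
  info <- data.frame(
    presentation_id = seq_len(2 * n_each),
    image_id = 0L,
    is_change = rep(c(TRUE, FALSE), n_each),
    is_sham_change = FALSE,
    repeat_index = rep(c(1L, 5L), n_each),
    omitted = FALSE)
  info$is_pre_change <- !info$is_change
  resp <- rbind(ifelse(info$is_change, rc, rp))
  structure(list(responses = resp, info = info),
            class = "presentation_responses")
}

test_that("CMI arithmetic and exclusion rules follow the definition", {
  expect_equal(change_modulation_index(fixture_pr(0.3, 0.1))$cmi, 0.5)
  expect_equal(change_modulation_index(fixture_pr(0.2, 0.2))$cmi, 0)
  expect_equal(change_modulation_index(fixture_pr(0.4, 0))$cmi, 1)
  neg <- change_modulation_index(fixture_pr(-0.1, 0.2))
  expect_true(neg$excluded)
  expect_match(neg$reason, "negative")
  zero <- change_modulation_index(fixture_pr(0, 0))
  expect_true(zero$excluded)
  expect_match(zero$reason, "denominator")
})

test_that("decoders recover labels carried by tuning and fail on shuffles", {
  s <- generate_session(250, seed = 50)
  pop <- generate_synthetic_population(60, noise_sd = 0.2, session = s,
                                       seed = 50)
  id <- decode_population(pop, "identity", seed = 1)
  expect_gt(id$accuracy, 0.5)           # chance is 1/8
  ch <- decode_population(pop, "change", seed = 1)
  expect_gt(ch$accuracy, 0.6)           # adaptation carries the change label
  expect_length(ch$fold_accuracy, 3)
  expect_length(ch$weights, 60)

  # negative control: non-adapting population carries no change signal beyond
  # the finite-session imbalance of which images happened to fill each role
  flat <- generate_synthetic_population(60, U = 0, noise_sd = 0.2,
                                        session = s, seed = 51)
  ch0 <- decode_population(flat, "change", seed = 1)
  expect_lt(abs(ch0$accuracy - 0.5), 0.1)
  expect_gt(ch$accuracy, ch0$accuracy + 0.05)

  # label shuffle: accuracy collapses to chance
  shuf <- pop
  set.seed(52)
  ord <- sample(ncol(shuf$responses))
  shuf$responses <- shuf$responses[, ord]
  chs <- decode_population(shuf, "change", seed = 1)
  expect_lt(abs(chs$accuracy - 0.5), 0.1)
})

test_that("perfectly separated classes decode at accuracy 1", {
  info <- data.frame(presentation_id = 1:40, image_id = 0L,
                     is_change = rep(c(TRUE, FALSE), 20),
                     is_sham_change = FALSE, repeat_index = 1L,
                     omitted = FALSE)
  info$is_pre_change <- !info$is_change
  resp <- rbind(ifelse(info$is_change, 1, 0) + rnorm(40, 0, 0.01),
                rnorm(40, 0, 0.01))
  pr <- structure(list(responses = resp, info = info),
                  class = "presentation_responses")
  expect_equal(decode_population(pr, "change", seed = 2)$accuracy, 1)
})

test_that("decoder weights correlate with change modulation by construction", {
  # only adapting units carry the change label
  set.seed(60)
  n_pres <- 300
  is_change <- rep(c(TRUE, FALSE), n_pres / 2)
  info <- data.frame(presentation_id = seq_len(n_pres), image_id = 0L,
                     is_change = is_change, is_sham_change = FALSE,
                     repeat_index = ifelse(is_change, 1L, 6L),
                     omitted = FALSE)
  info$is_pre_change <- !info$is_change
  adapting <- matrix(rep(ifelse(is_change, 1.5, 0.75), each = 10),
                     10, n_pres, byrow = FALSE)
  flat <- matrix(1, 10, n_pres)
  resp <- rbind(adapting, flat) * (1 + rnorm(20 * n_pres, 0, 0.15))
  pr <- structure(list(responses = resp, info = info),
                  class = "presentation_responses")
  dec <- decode_population(pr, "change", seed = 3)
  cmi <- change_modulation_index(pr)
  expect_gt(weight_cmi_correlation(dec, cmi), 0.8)
  # exact proportionality gives r = +/-1
  fake <- dec
  fake$weights <- cmi$cmi * 2
  expect_equal(weight_cmi_correlation(fake, cmi), 1)
  fake$weights <- -cmi$cmi
  expect_equal(weight_cmi_correlation(fake, cmi), -1)
})

test_that("subsampled decoding grows with population size", {
  s <- generate_session(200, seed = 61)
  pop <- generate_synthetic_population(40, noise_sd = 0.3, session = s,
                                       seed = 61)
  curve <- subsample_accuracy_curve(pop, "change", c(2, 40),
                                    n_samples = 5, seed = 4)
  expect_equal(curve$n_units, c(2, 40))
  expect_true(all(curve$mean_accuracy >= 0 & curve$mean_accuracy <= 1))
  expect_gte(curve$mean_accuracy[2] + 0.05, curve$mean_accuracy[1])
})

test_that("Jaccard agreement matches closed forms and flags degeneracy", {
  v <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(jaccard_agreement(v, v, n_shuffles = 10, seed = 1)$score, 1)
  expect_equal(jaccard_agreement(c(TRUE, FALSE), c(FALSE, TRUE),
                                 n_shuffles = 10, seed = 1)$score, 0)
  expect_error(jaccard_agreement(c(FALSE, FALSE), c(FALSE, FALSE)),
               "all-zero")
  # independent Bernoulli(0.3) vectors: E[J] ~ p / (2 - p)
  set.seed(5)
  a <- runif(1000) < 0.3
  b <- runif(1000) < 0.3
  j <- jaccard_agreement(a, b, n_shuffles = 500, seed = 6)
  expect_lt(abs(j$score - 0.3 / 1.7), 0.04)
  # shuffle null of independent vectors brackets the analytic expectation
  expect_gt(0.3 / 1.7, j$null_ci[1] - 0.03)
  expect_lt(0.3 / 1.7, j$null_ci[2] + 0.03)
})
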