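#' Generate a synthetic adapting neural population
#'
#' Test fixture with known ground truth for the neural-metrics analyses. Each
#' neuron is tuned to a single image with a random amplitude; its
#' presentation response is `tuning(image) * x(t) * (1 + noise)`, where the
#' resource fraction `x` follows the same backward-Euler depression dynamics
#' as the models (driven by that neuron's own noise-free activity). With
#' `U = 0` the population does not adapt and every ground-truth change
#' modulation index is 0; with depression on, change responses exceed
#' pre-change responses and the index is positive. The ground truth is
#' computed from the noise-free traces with the same estimator the analysis
#' applies, so recovery error isolates the effect of trial noise.
#'
#' @param n_neurons population size
#' @param U release fraction (0 allowed: non-adapting population)
#' @param tau_x recovery time constant, seconds
#' @param noise_sd multiplicative trial-noise sd on the responses
#' @param session a `stim_sequence` driving the population
#' @param seed optional integer seed
#' @return a `synthetic_population` list: `responses` (neurons x
#'   presentations, noisy), `noise_free` (same, without noise), `info`
#'   (presentation labels), `ground_truth_cmi`, `tuning` (per-neuron preferred
#'   image and amplitude), `noise_sd`
#' @export
generate_synthetic_population <- function(n_neurons = 200, U = 0.5,
                                          tau_x = 1.5, noise_sd = 0.2,
                                          session = NULL, seed = NULL) {
  n_neurons <- check_count(n_neurons, "n_neurons")
  stop_if(!is.numeric(U) || length(U) != 1L || is.na(U) || U < 0 || U > 1,
          "`U` must lie in [0, 1]")
  check_pos(tau_x, "tau_x")
  stop_if(!is.numeric(noise_sd) || noise_sd < 0, "`noise_sd` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(session)) session <- generate_session(300)
  stop_if(!inherits(session, "stim_sequence"), "not a stim_sequence")

  n_images <- attr(session, "n_images")
  dt <- attr(session, "dt")
  pref <- sample.int(n_images, n_neurons, replace = TRUE) - 1L
  amp <- runif(n_neurons, 0.5, 1.5)

  info <- presentation_info(session)
  n_steps <- nrow(session)
  k <- dt / tau_x
  x <- rep(1, n_neurons)
  resp <- matrix(0, n_neurons, nrow(info))
  pres_at <- integer(n_steps)
  pres_at[info$step] <- seq_len(nrow(info))
  shown <- rep(NA_integer_, n_steps)
  shown[info$step[!info$omitted]] <- info$image_id[!info$omitted]
  for (t in seq_len(n_steps)) {
    r <- if (is.na(shown[t])) 0 else amp * (pref == shown[t])
    x <- (x + k) / (1 + k + U * dt * r)
    if (pres_at[t] > 0L) resp[, pres_at[t]] <- r * x
  }
  noisy <- resp * (1 + rnorm(length(resp), 0, noise_sd))
  rownames(resp) <- rownames(noisy) <- paste0("n", seq_len(n_neurons))

  gt <- change_modulation_index(
    structure(list(responses = resp, info = info),
              class = "presentation_responses"))
  structure(list(responses = noisy, noise_free = resp, info = info,
                 ground_truth_cmi = gt$cmi, noise_sd = noise_sd,
                 tuning = data.frame(neuron = rownames(resp),
                                     preferred_image = pref,
                                     amplitude = amp)),
            class = c("synthetic_population"))
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf(
    "synthetic_population: %d neurons x %d presentations (noise sd %.3g)\n",
    nrow(x$responses), ncol(x$responses), x$noise_sd))
  cat(sprintf("  ground-truth CMI: mean %.3f (%d defined)\n",
              mean(x$ground_truth_cmi, na.rm = TRUE),
              sum(!is.na(x$ground_truth_cmi))))
  invisible(x)
}
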