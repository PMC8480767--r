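#' Generate synthetic image embeddings
#'
#' Emulates the sparse, non-negative feature vectors a pretrained visual
#' encoder produces for the task's image set. Each of the `n_features` input
#' units responds to `k` images (`k` drawn from `tuning_breadth`, a probability
#' vector over breadths 1, 2, ...) with graded positive amplitudes: a peak
#' amplitude for the preferred image and geometrically decaying amplitudes for
#' the others. Per-image total drive is then normalized to a common base level
#' and scaled by a lognormal saliency factor (`sdlog = saliency_spread`), so
#' that images differ in how strongly they drive the population — the
#' substrate of asymmetric detectability. With `saliency_spread = 0` all
#' images have identical total drive.
#'
#' The base level is `amp_scale * n_features * E[k] / n_images`, putting the
#' typical active amplitude at `amp_scale`. The default of 2 drives single
#' units into the depression-dominated regime the synapse defaults target
#' (steady-state resource fraction 0.4 under sustained drive of 2 at
#' `U = 0.5`, `tau_x = 1.5` s), so repeated images produce the substantial
#' repetition suppression the encoder's active units show.
#'
#' @param n_images number of images (rows), default 8
#' @param n_features number of input units (columns), default 64; must be at
#'   least `n_images` so every image can drive at least one unit
#' @param tuning_breadth probability weights over tuning breadths
#'   `1..length(tuning_breadth)`
#' @param saliency_spread lognormal sdlog of the per-image saliency factor
#' @param amp_scale typical active amplitude (base drive per active unit)
#' @param seed optional integer seed
#' @return an `embedding_matrix`: a non-negative `n_images x n_features`
#'   matrix with attribute `saliency` (per-image total drive).
#' @examples
#' e <- generate_embeddings(seed = 1)
#' mean(e == 0)  # sparsity
#' @export
generate_embeddings <- function(n_images = 8, n_features = 64,
                                tuning_breadth = c(0.4, 0.3, 0.2, 0.1),
                                saliency_spread = 0.3, amp_scale = 2,
                                seed = NULL) {
  n_images <- check_count(n_images, "n_images", min = 2L)
  n_features <- check_count(n_features, "n_features", min = 1L)
  stop_if(n_features < n_images,
          "`n_features` (%d) < `n_images` (%d): cannot cover every image",
          n_features, n_images)
  stop_if(!is.numeric(tuning_breadth) || any(tuning_breadth < 0) ||
            sum(tuning_breadth) <= 0, "invalid `tuning_breadth` weights")
  stop_if(length(tuning_breadth) > n_images,
          "tuning breadth exceeds the image count")
  stop_if(!is.numeric(saliency_spread) || saliency_spread < 0,
          "`saliency_spread` must be non-negative")
  check_pos(amp_scale, "amp_scale")
  if (!is.null(seed)) set.seed(seed)

  nb <- length(tuning_breadth)
  vals <- matrix(0, n_images, n_features)
  k_all <- sample.int(nb, n_features, replace = TRUE,
                      prob = tuning_breadth / sum(tuning_breadth))
  for (f in seq_len(n_features)) {
    k <- k_all[f]
    imgs <- sample.int(n_images, k)
    peak <- runif(1, 0.5, 1.5)
    amps <- peak * cumprod(c(1, runif(k - 1L, 0.3, 0.9)))
    vals[imgs, f] <- amps
  }
  # guarantee coverage: an image nobody responds to gets one dedicated unit
  for (i in which(rowSums(vals) == 0)) {
    f <- ((i - 1L) %% n_features) + 1L
    vals[, f] <- 0
    vals[i, f] <- 1
  }
  mean_k <- sum(seq_len(nb) * tuning_breadth / sum(tuning_breadth))
  base <- amp_scale * n_features * mean_k / n_images
  sal <- base * exp(rnorm(n_images, 0, saliency_spread))
  vals <- vals * (sal / rowSums(vals))
  dimnames(vals) <- list(paste0("image_", seq_len(n_images) - 1L),
                         paste0("unit_", seq_len(n_features)))
  structure(vals, saliency = rowSums(vals),
            class = c("embedding_matrix", "matrix", "array"))
}
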