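#' Multiplicative rectified noise
#'
#' Perturbs non-negative activities as `max(0, a * (1 + eps))` with
#' `eps ~ N(0, noise_sd^2)` i.i.d. — the noise model injected at the encoder
#' output and hidden layer of the network models. Multiplicative form
#' preserves zeros (silent units stay silent) and, after rectification,
#' biases the mean by under half a percent at the default sd of 0.5.
#'
#' @param activity non-negative numeric vector
#' @param noise_sd noise standard deviation (0 = identity)
#' @return the perturbed, rectified activity vector
#' @export
apply_noise <- function(activity, noise_sd = 0.5) {
  stop_if(any(!is.finite(activity)) || any(activity < 0),
          "activity must be non-negative and finite")
  stop_if(!is.numeric(noise_sd) || noise_sd < 0, "`noise_sd` must be >= 0")
  if (noise_sd == 0) return(activity)
  pmax(0, activity * (1 + rnorm(length(activity), 0, noise_sd)))
}

# He-uniform weight initialization; recurrent block uses the uniform
# [-1/sqrt(n), 1/sqrt(n)] convention. Hidden units carry a non-positive bias
# (a rectification threshold, h = relu(W u - theta), theta >= 0, enforced by
# projection during training): per-unit thresholds are what let the network
# separate change from repeat magnitudes under noise, while zero input still
# yields exactly zero feedforward activity (silence during gray screens and
# omissions, as observed). Thresholds start at zero.
init_weights <- function(kind, n_input = 64L, n_hidden = 16L) {
  he <- function(nr, nc) {
    a <- sqrt(6 / nc)
    matrix(runif(nr * nc, -a, a), nr, nc)
  }
  none <- matrix(0, 0, 0)
  list(
    W_ad = if (kind %in% c("stpnet", "stprnn")) he(n_hidden, n_input) else none,
    W_pl = if (kind %in% c("rnn", "stprnn")) he(n_hidden, n_input) else none,
    W_rec = if (kind %in% c("rnn", "stprnn")) {
      a <- 1 / sqrt(n_hidden)
      matrix(runif(n_hidden * n_hidden, -a, a), n_hidden, n_hidden)
    } else none,
    b_h = rep(0, n_hidden),
    w_out = he(1, n_hidden)[1, ],
    b_out = runif(1, -1 / sqrt(n_hidden), 1 / sqrt(n_hidden))
  )
}

# timestep-level drive matrix, loss mask and labels for a session
session_inputs <- function(session, embeddings) {
  n_img <- attr(session, "n_images")
  stop_if(nrow(embeddings) != n_img,
          "embedding rows (%d) do not match the session image set (%d)",
          nrow(embeddings), n_img)
  img_steps <- which(session$frame_kind == "image")
  ids <- session$image_id[img_steps]
  stop_if(any(ids < 0 | ids >= n_img), "image id outside the embedding set")
  drive <- matrix(0, nrow(session), ncol(embeddings))
  drive[img_steps, ] <- unclass(embeddings)[ids + 1L, , drop = FALSE]
  mask <- as.integer(session$frame_kind == "image")
  y <- as.numeric(session$is_change)
  list(drive = drive, mask = mask, y = y)
}

#' Run a model over a stimulus sequence
#'
#' Unrolls one of the network models over a session: gray and omitted steps
#' feed zero input, multiplicative noise is drawn for the input and hidden
#' layers (from R's RNG, so runs are reproducible under `set.seed`), the
#' depression state starts at rest (`x = 1`) and the hidden state at zero.
#' Records all per-step activities for the analysis modules.
#'
#' @param par weight list (`W_ad`, `W_pl`, `W_rec`, `b_h`, `w_out`,
#'   `b_out`); absent pathways are 0 x 0 matrices; `b_h` is the (non-positive)
#'   hidden rectification threshold
#' @param kind `"stpnet"`, `"rnn"` or `"stprnn"`
#' @param session a `stim_sequence`
#' @param embeddings an `embedding_matrix`
#' @param noise_sd multiplicative noise sd (0 disables noise)
#' @param stp an [stp_params()] object (ignored by the RNN)
#' @param train_opts list with `pos_weight` and `l2_act` used for the reported
#'   loss
#' @param grad if `TRUE`, also return backpropagated gradients
#' @param record if `FALSE`, skip returning the per-step activity matrices
#'   (training only needs logits and gradients)
#' @return a `changenet_run`: logits, response probabilities `p`, recorded
#'   `hidden`, `input_raw`, `input_gated` and `x` trajectories (steps x
#'   units), the loss components, and the session.
#' @export
run_session <- function(par, kind, session, embeddings,
                        noise_sd = 0.5, stp = stp_params(),
                        train_opts = list(pos_weight = 5, l2_act = 0.001),
                        grad = FALSE, record = TRUE) {
  stop_if(!kind %in% c("stpnet", "rnn", "stprnn"), "unknown model kind")
  inp <- session_inputs(session, embeddings)
  T <- nrow(inp$drive)
  n_in <- ncol(inp$drive)
  n_h <- length(par$w_out)
  if (T == 0L) {
    return(structure(list(logits = numeric(0), p = numeric(0),
                          hidden = matrix(0, 0, n_h), session = session,
                          kind = kind), class = "changenet_run"))
  }
  eps_in <- matrix(0, T, n_in)
  eps_h <- matrix(0, T, n_h)
  if (noise_sd > 0) {
    img <- inp$mask > 0  # input noise is multiplicative: only matters on
    eps_in[img, ] <- rnorm(sum(img) * n_in, 0, noise_sd)  # driven steps
    eps_h[] <- rnorm(T * n_h, 0, noise_sd)
  }
  res <- cpp_session_pass(inp$drive, eps_in, eps_h, inp$mask, inp$y,
                          par$W_ad, par$W_pl, par$W_rec, par$b_h,
                          par$w_out,
                          par$b_out, stp$U, stp$tau_x, attr(session, "dt"),
                          train_opts$pos_weight, train_opts$l2_act,
                          grad, record)
  structure(list(logits = drop(res$logits), p = sigmoid(drop(res$logits)),
                 hidden = res$hidden, input_raw = res$input_raw,
                 input_gated = res$input_gated, x = res$x,
                 loss = res$loss, bce = res$bce,
                 act_penalty = res$act_penalty,
                 grads = res$grads, mask = inp$mask, y = inp$y,
                 session = session, kind = kind),
            class = "changenet_run")
}

#' @export
print.changenet_run <- function(x, ...) {
  cat(sprintf("changenet_run (%s): %d steps, loss %.4f\n",
              x$kind, length(x$logits), x$loss %||% NA))
  invisible(x)
}
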