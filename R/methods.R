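#' @export
print.changenet <- function(x, ...) {
  cat(sprintf("changenet model: %s (%d-%d-1)\n", toupper(x$kind),
              ncol(x$embeddings), x$n_hidden))
  if (x$kind != "rnn")
    cat(sprintf("  depression: U = %.2f, tau_x = %.2f s, dt = %.2f s\n",
                x$stp$U, x$stp$tau_x, x$stp$dt))
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  stopped at epoch %d (%s); final d' = %.2f, loss = %.4f\n",
              x$stop_epoch, x$stop_reason, h$dprime, h$loss))
  invisible(x)
}

#' @export
summary.changenet <- function(object, ...) {
  h <- object$history
  norms <- vapply(object$par, function(p)
    if (length(p)) sqrt(sum(p^2)) else NA_real_, 0)
  out <- list(kind = object$kind, stop_epoch = object$stop_epoch,
              stop_reason = object$stop_reason,
              final = h[nrow(h), ], weight_norms = norms,
              history = h)
  class(out) <- "summary.changenet"
  out
}

#' @export
print.summary.changenet <- function(x, ...) {
  cat(sprintf("Fitted %s model, stopped at epoch %d (%s)\n",
              toupper(x$kind), x$stop_epoch, x$stop_reason))
  cat(sprintf("Final epoch: d' = %.2f, hit = %.3f, fa = %.3f, loss = %.4f\n",
              x$final$dprime, x$final$hit_rate, x$final$fa_rate,
              x$final$loss))
  cat("L2 weight norms:\n")
  print(round(x$weight_norms[!is.na(x$weight_norms)], 3))
  invisible(x)
}

#' Extract model weights
#'
#' @param object a fitted `changenet`
#' @param ... unused
#' @return named list of weight matrices (`W_ad` depressing input block,
#'   `W_pl` non-adapting input block, `W_rec` recurrent block, `b_h`
#'   non-positive hidden thresholds, `w_out`, `b_out`); absent pathways are
#'   0 x 0
#' @export
coef.changenet <- function(object, ...) object$par

#' Run a fitted model on a stimulus sequence
#'
#' @param object a fitted `changenet`
#' @param session a `stim_sequence`, or `NULL` to generate one
#' @param n_trials session length when generating
#' @param p_omit omission probability when generating (`NULL` = task default)
#' @param noise if `FALSE`, run noise-free (deterministic replay)
#' @param seed optional integer seed
#' @param ... unused
#' @return a `changenet_run` (see [run_session()])
#' @export
predict.changenet <- function(object, session = NULL, n_trials = 100,
                              p_omit = NULL, noise = TRUE, seed = NULL,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(session)) {
    tk <- object$task
    session <- generate_session(
      n_trials, n_images = tk$n_images, p_go = tk$p_go,
      p_omit = p_omit %||% tk$p_omit, min_repeats = tk$min_repeats,
      max_repeats = tk$max_repeats, repeat_hazard = tk$repeat_hazard,
      isi_steps = tk$isi_steps, dt = tk$dt)
  }
  run_session(object$par, object$kind, session, object$embeddings,
              noise_sd = if (noise) object$noise_sd else 0,
              stp = object$stp,
              train_opts = list(pos_weight = object$control$pos_weight,
                                l2_act = object$control$l2_act))
}

#' Simulate behavioral sessions from a fitted model
#'
#' Generates `nsim` fresh evaluation sessions, runs the model and samples
#' Bernoulli go/no-go responses.
#'
#' @param object a fitted `changenet`
#' @param nsim number of sessions
#' @param seed optional integer seed
#' @param n_trials trials per session
#' @param p_omit omission probability (`NULL` = task default)
#' @param ... unused
#' @return list of `changenet_eval` objects (length `nsim`)
#' @export
simulate.changenet <- function(object, nsim = 1, seed = NULL,
                               n_trials = 100, p_omit = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    evaluate_model(object, n_trials = n_trials, p_omit = p_omit))
}

#' Training residuals
#'
#' Label minus predicted response probability at the masked-in (image
#' presentation) steps of the final training epoch's session.
#'
#' @param object a fitted `changenet`
#' @param ... unused
#' @return numeric residual vector
#' @export
residuals.changenet <- function(object, ...) {
  fe <- object$final_eval
  stop_if(is.null(fe), "model carries no final-epoch evaluation")
  keep <- fe$mask > 0
  fe$y[keep] - sigmoid(fe$logits[keep])
}

#' Plot the training history
#'
#' Two panels: loss and d-prime per epoch, with the early-stop criterion.
#'
#' @param x a fitted `changenet`
#' @param ... unused
#' @export
plot.changenet <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss",
       main = toupper(x$kind))
  plot(h$epoch, h$dprime, type = "l", xlab = "epoch", ylab = "d-prime",
       main = "sensitivity")
  graphics::abline(h = x$control$dprime_criterion, lty = 2)
  invisible(x)
}
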