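#' Task parameters
#'
#' Generator settings shared by training and evaluation sessions. Training
#' sessions never contain omissions (omissions are a probe shown only at
#' evaluation, as in the imaging sessions); `p_omit` here applies to
#' evaluation sessions.
#'
#' @param n_images image-set size
#' @param p_go probability a scheduled event is a true change
#' @param p_omit omission probability used at evaluation
#' @param min_repeats,max_repeats,repeat_hazard truncated repeat law
#' @param isi_steps gray frames between presentations
#' @param dt seconds per timestep
#' @return a `task_params` list
#' @export
task_params <- function(n_images = 8, p_go = 0.5, p_omit = 0.05,
                        min_repeats = 4, max_repeats = 11,
                        repeat_hazard = 0.3, isi_steps = 2, dt = 0.25) {
  structure(list(n_images = n_images, p_go = p_go, p_omit = p_omit,
                 min_repeats = min_repeats, max_repeats = max_repeats,
                 repeat_hazard = repeat_hazard, isi_steps = isi_steps,
                 dt = dt), class = "task_params")
}

#' Training control parameters
#'
#' ADAM with the framework-default settings, weighted binary cross-entropy
#' (positive class weighted `pos_weight`) masked to image presentations, an L2
#' penalty on hidden activations, and d-prime early stopping: training stops
#' once the epoch d-prime has been at or above `dprime_criterion` for
#' `patience` consecutive epochs. One epoch is one freshly generated session
#' of `trials_per_epoch` trials, unrolled as a single batch.
#'
#' @param lr ADAM learning rate
#' @param beta1,beta2 ADAM moment decays
#' @param pos_weight loss weight on change (label 1) presentations
#' @param l2_act L2 penalty weight on hidden activations
#' @param max_epochs epoch cap
#' @param dprime_criterion early-stop sensitivity criterion
#' @param patience consecutive epochs the criterion must hold
#' @param trials_per_epoch trials per training session
#' @return a `train_control` list
#' @export
train_control <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                          pos_weight = 5, l2_act = 0.001, max_epochs = 5000,
                          dprime_criterion = 1.5, patience = 5,
                          trials_per_epoch = 100) {
  for (nm in c("lr", "beta1", "beta2", "pos_weight", "l2_act"))
    stop_if(get(nm) < 0, "`%s` must be non-negative", nm)
  max_epochs <- check_count(max_epochs, "max_epochs")
  patience <- check_count(patience, "patience")
  trials_per_epoch <- check_count(trials_per_epoch, "trials_per_epoch")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 pos_weight = pos_weight, l2_act = l2_act,
                 max_epochs = max_epochs,
                 dprime_criterion = dprime_criterion, patience = patience,
                 trials_per_epoch = trials_per_epoch),
            class = "train_control")
}

#' Masked, weighted training loss (reference implementation)
#'
#' Mean over masked-in steps of the binary cross-entropy with logits, with
#' label-1 terms multiplied by `pos_weight`, plus `l2_act` times the mean
#' squared hidden activity. With every step masked out the loss is the
#' activity penalty alone. This R implementation mirrors the compiled one
#' used during training and backs the residual/diagnostic methods.
#'
#' @param logits per-step output logits
#' @param labels per-step 0/1 labels
#' @param mask per-step 0/1 loss mask (1 = image presentation)
#' @param hidden hidden-activity matrix (steps x units), or `NULL`
#' @param pos_weight,l2_act see [train_control()]
#' @return scalar loss
#' @export
compute_loss <- function(logits, labels, mask, hidden = NULL,
                         pos_weight = 5, l2_act = 0.001) {
  stop_if(length(logits) != length(labels) || length(labels) != length(mask),
          "logits, labels and mask lengths differ")
  keep <- mask > 0
  bce <- 0
  if (any(keep)) {
    z <- logits[keep]
    y <- labels[keep]
    w <- ifelse(y > 0.5, pos_weight, 1)
    bce <- mean(w * (pmax(z, 0) - z * y + log1p(exp(-abs(z)))))
  }
  pen <- if (!is.null(hidden) && length(hidden)) l2_act * mean(hidden^2) else 0
  bce + pen
}

#' Signal-detection sensitivity (d-prime)
#'
#' `qnorm(hit) - qnorm(fa)` with rates clipped to
#' `[1/(2n), 1 - 1/(2n)]` of the corresponding trial count so perfect rates
#' stay finite.
#'
#' @param hit_rate,fa_rate hit and false-alarm rates in \[0, 1\]
#' @param n_go,n_catch numbers of go and catch trials
#' @return d-prime value
#' @examples
#' dprime(0.9, 0.1, 100, 100)
#' @export
dprime <- function(hit_rate, fa_rate, n_go, n_catch) {
  n_go <- check_count(n_go, "n_go")
  n_catch <- check_count(n_catch, "n_catch")
  stop_if(any(c(hit_rate, fa_rate) < 0) || any(c(hit_rate, fa_rate) > 1),
          "rates must lie in [0, 1]")
  clip <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  qnorm(clip(hit_rate, n_go)) - qnorm(clip(fa_rate, n_catch))
}

# one ADAM update; state carries first/second moments and the step counter
adam_update <- function(par, grads, state, ctrl) {
  state$t <- state$t + 1L
  eps <- 1e-8
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (length(g) == 0L) next
    state$m[[nm]] <- ctrl$beta1 * state$m[[nm]] + (1 - ctrl$beta1) * g
    state$v[[nm]] <- ctrl$beta2 * state$v[[nm]] + (1 - ctrl$beta2) * g^2
    mhat <- state$m[[nm]] / (1 - ctrl$beta1^state$t)
    vhat <- state$v[[nm]] / (1 - ctrl$beta2^state$t)
    par[[nm]] <- par[[nm]] - ctrl$lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

#' Fit a change-detection network model
#'
#' Trains one of three short-term-memory architectures on the simulated
#' change-detection task: `"stpnet"` (feedforward, with Tsodyks-Markram
#' depression on the input synapses), `"rnn"` (recurrent hidden layer, no
#' depression), or `"stprnn"` (both pathways: adapting and non-adapting input
#' blocks plus recurrence; zeroing the adapting block recovers the RNN,
#' zeroing the non-adapting and recurrent blocks recovers STPNet). The
#' network is 64 input units, 16 rectified hidden units and one sigmoid
#' output trained as a binary classifier (change vs repeat) with
#' backpropagation (through time, for the recurrent variants) and ADAM. Each
#' epoch unrolls one freshly generated session; behavioral responses are
#' sampled from a Bernoulli distribution on the output sigmoid and epoch
#' d-prime drives early stopping. Training sessions contain no omissions.
#'
#' @param kind model architecture
#' @param embeddings image embeddings driving the input layer; defaults to
#'   synthetic embeddings generated from `seed`
#' @param n_hidden hidden-layer size
#' @param noise_sd multiplicative noise sd on input and hidden activities
#' @param stp [stp_params()] for the depressing pathway
#' @param control [train_control()] settings
#' @param task [task_params()] settings
#' @param seed integer seed; fixes initialization, sessions and noise, making
#'   the fit fully reproducible
#' @return a `changenet` object with components `par` (weights), `history`
#'   (per-epoch loss, hit/false-alarm rates and d-prime), `stop_epoch`,
#'   `stop_reason` (`"criterion"` or `"max_epochs"`), and the configuration.
#'   Supports `print`, `summary`, `coef`, `predict`, `simulate`, `plot` and
#'   `residuals`.
#' @examples
#' \donttest{
#' fit <- changenet("stpnet", seed = 1,
#'                  control = train_control(max_epochs = 50))
#' fit
#' }
#' @export
changenet <- function(kind = c("stpnet", "rnn", "stprnn"),
                      embeddings = NULL, n_hidden = 16, noise_sd = 0.5,
                      stp = stp_params(), control = train_control(),
                      task = task_params(), seed = 1) {
  kind <- match.arg(kind)
  stop_if(!is.numeric(noise_sd) || noise_sd < 0, "`noise_sd` must be >= 0")
  set.seed(derive_seed(seed, 1L))
  if (is.null(embeddings))
    embeddings <- generate_embeddings(n_images = task$n_images,
                                      seed = derive_seed(seed, 2L))
  set.seed(derive_seed(seed, 3L))
  par <- init_weights(kind, n_input = ncol(embeddings), n_hidden = n_hidden)
  astate <- list(t = 0L,
                 m = lapply(par, function(p) p * 0),
                 v = lapply(par, function(p) p * 0))
  opts <- list(pos_weight = control$pos_weight, l2_act = control$l2_act)

  hist <- vector("list", control$max_epochs)
  streak <- 0L
  stop_reason <- "max_epochs"
  stop_epoch <- control$max_epochs
  final_eval <- NULL
  for (epoch in seq_len(control$max_epochs)) {
    sess <- generate_session(
      control$trials_per_epoch, n_images = task$n_images, p_go = task$p_go,
      p_omit = 0, min_repeats = task$min_repeats,
      max_repeats = task$max_repeats, repeat_hazard = task$repeat_hazard,
      isi_steps = task$isi_steps, dt = task$dt)
    run <- run_session(par, kind, sess, embeddings, noise_sd = noise_sd,
                       stp = stp, train_opts = opts, grad = TRUE,
                       record = FALSE)
    if (!is.finite(run$loss)) {
      h <- do.call(rbind, hist[seq_len(epoch - 1L)])
      cond <- simpleError(sprintf("training diverged at epoch %d", epoch))
      cond$history <- h
      stop(cond)
    }
    info <- presentation_info(sess)
    ev <- info[info$is_change | info$is_sham_change, ]
    resp <- runif(nrow(ev)) < run$p[ev$step]
    hit <- mean(resp[ev$is_change])
    fa <- mean(resp[ev$is_sham_change])
    dp <- dprime(hit, fa, sum(ev$is_change), sum(ev$is_sham_change))
    hist[[epoch]] <- data.frame(epoch = epoch, loss = run$loss,
                                bce = run$bce, hit_rate = hit, fa_rate = fa,
                                dprime = dp)
    streak <- if (dp >= control$dprime_criterion) streak + 1L else 0L
    if (streak >= control$patience) {
      stop_reason <- "criterion"
      stop_epoch <- epoch
      final_eval <- list(logits = run$logits, y = run$y, mask = run$mask)
      break
    }
    upd <- adam_update(par, run$grads, astate, control)
    par <- upd$par
    par$b_h <- pmin(par$b_h, 0)  # hidden biases are thresholds: theta >= 0
    astate <- upd$state
    if (epoch == control$max_epochs)
      final_eval <- list(logits = run$logits, y = run$y, mask = run$mask)
  }
  structure(list(kind = kind, par = par, embeddings = embeddings,
                 n_hidden = n_hidden, noise_sd = noise_sd, stp = stp,
                 control = control, task = task, seed = seed,
                 history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
                 stop_epoch = stop_epoch, stop_reason = stop_reason,
                 final_eval = final_eval, call = match.call()),
            class = "changenet")
}

#' Evaluate a fitted model on a fresh session
#'
#' Generates an evaluation session (by default with the 5% omission probe the
#' models never saw in training), runs the model with noise on, samples
#' Bernoulli responses at every presentation slot, and tabulates trials.
#'
#' @param object a fitted `changenet`
#' @param n_trials evaluation session length
#' @param p_omit omission probability (`NULL` = the task default)
#' @param seed integer seed for the session, noise and response sampling
#' @return a `changenet_eval` list: the `run`, `presentations` (label table
#'   with sampled `response` and response probability `p`), `trials`
#'   (per-event records with transition and outcome), and `hit_rate`,
#'   `fa_rate`, `dprime`.
#' @export
evaluate_model <- function(object, n_trials = 500, p_omit = NULL,
                           seed = NULL) {
  stop_if(!inherits(object, "changenet"), "not a changenet model")
  if (!is.null(seed)) set.seed(seed)
  tk <- object$task
  sess <- generate_session(
    n_trials, n_images = tk$n_images, p_go = tk$p_go,
    p_omit = p_omit %||% tk$p_omit, min_repeats = tk$min_repeats,
    max_repeats = tk$max_repeats, repeat_hazard = tk$repeat_hazard,
    isi_steps = tk$isi_steps, dt = tk$dt)
  run <- run_session(object$par, object$kind, sess, object$embeddings,
                     noise_sd = object$noise_sd, stp = object$stp)
  pres <- presentation_info(sess)
  pres$logit <- run$logits[pres$step]
  pres$p <- run$p[pres$step]
  pres$response <- sample_responses(pres$logit)
  trials <- trial_table(pres)
  ev <- pres[pres$is_change | pres$is_sham_change, ]
  hit <- mean(ev$response[ev$is_change])
  fa <- mean(ev$response[ev$is_sham_change])
  structure(list(run = run, presentations = pres, trials = trials,
                 hit_rate = hit, fa_rate = fa,
                 dprime = dprime(hit, fa, sum(ev$is_change),
                                 sum(ev$is_sham_change))),
            class = "changenet_eval")
}

#' @export
print.changenet_eval <- function(x, ...) {
  cat(sprintf("changenet_eval: %d trials, hit %.3f, fa %.3f, d' %.2f\n",
              max(x$presentations$trial_id), x$hit_rate, x$fa_rate, x$dprime))
  invisible(x)
}

#' Sweep a task or synapse parameter over training runs
#'
#' Re-trains models across a grid of values of either the depression recovery
#' constant `tau_x` or the inter-stimulus delay (`isi_steps`, in 250-ms
#' frames), across seeds, and tabulates when each run reached the d-prime
#' criterion. Per-cell failures are caught and recorded, not propagated.
#'
#' @param parameter `"tau_x"` or `"isi_steps"`
#' @param values numeric vector of parameter values
#' @param kind model architecture
#' @param seeds integer seeds, one run per seed per value
#' @param ... further arguments passed to [changenet()]
#' @return data frame with one row per (value, seed): `stop_epoch`,
#'   `stop_reason`, `final_dprime`, `error`
#' @export
sweep_training <- function(parameter = c("tau_x", "isi_steps"), values,
                           kind = "stpnet", seeds = 1:3, ...) {
  parameter <- match.arg(parameter)
  grid <- expand.grid(value = values, seed = seeds)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- grid$value[i]
    s <- grid$seed[i]
    args <- list(kind = kind, seed = s, ...)
    if (parameter == "tau_x") {
      st <- args$stp %||% stp_params()
      args$stp <- stp_params(U = st$U, tau_x = v, dt = st$dt)
    } else {
      tk <- args$task %||% task_params()
      tk$isi_steps <- as.integer(v)
      args$task <- tk
    }
    res <- tryCatch(do.call(changenet, args), error = identity)
    if (inherits(res, "error")) {
      data.frame(parameter = parameter, value = v, seed = s,
                 stop_epoch = NA_integer_, stop_reason = NA_character_,
                 final_dprime = NA_real_, error = conditionMessage(res))
    } else {
      data.frame(parameter = parameter, value = v, seed = s,
                 stop_epoch = res$stop_epoch, stop_reason = res$stop_reason,
                 final_dprime = res$history$dprime[nrow(res$history)],
                 error = NA_character_)
    }
  })
  do.call(rbind, rows)
}
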