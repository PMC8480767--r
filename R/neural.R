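as_presentation_responses <- function(x, info = NULL) {
  if (inherits(x, "presentation_responses")) return(x)
  if (inherits(x, "synthetic_population"))
    return(structure(list(responses = x$responses, info = x$info),
                     class = "presentation_responses"))
  stop_if(is.null(info), "supply `info` when passing a raw response matrix")
  structure(list(responses = as.matrix(x), info = info),
            class = "presentation_responses")
}

#' Change modulation index per unit
#'
#' For each unit, `CMI = (r_change - r_pre) / (r_change + r_pre)` where
#' `r_change` is its mean response over change presentations (go trials) and
#' `r_pre` its mean over the presentations immediately before a change.
#' Positive values indicate adaptation (stronger responses to novel images),
#' negative values facilitation. Units with a negative mean on either class
#' (possible for dF/F data or noisy traces) are excluded — their index would
#' fall outside \[-1, 1\] — as are units with a zero denominator. The
#' alternative contrast of go-trial versus catch-trial responses is available
#' via `mode = "go-catch"`.
#'
#' @param x a `presentation_responses`, `synthetic_population`, or raw
#'   units x presentations matrix (then supply `info`)
#' @param info presentation label table when `x` is a raw matrix
#' @param mode `"pre-change"` (default) or `"go-catch"`
#' @return a `cmi_table` data frame: `unit`, `r_change`, `r_pre`, `cmi`,
#'   `excluded`, `reason`
#' @export
change_modulation_index <- function(x, info = NULL,
                                    mode = c("pre-change", "go-catch")) {
  mode <- match.arg(mode)
  pr <- as_presentation_responses(x, info)
  info <- pr$info
  if (mode == "pre-change") {
    a <- info$is_change
    b <- info$is_pre_change %||%
      (c(info$is_change[-1L], FALSE) & !info$omitted)
  } else {
    a <- info$is_change
    b <- info$is_sham_change
  }
  stop_if(sum(a) < 1L || sum(b) < 1L,
          "need at least one change and one reference presentation")
  rc <- rowMeans(pr$responses[, a, drop = FALSE])
  rp <- rowMeans(pr$responses[, b, drop = FALSE])
  cmi <- (rc - rp) / (rc + rp)
  neg <- rc < 0 | rp < 0
  zero <- !neg & (rc + rp) == 0
  excluded <- neg | zero
  cmi[excluded] <- NA_real_
  reason <- rep(NA_character_, length(cmi))
  reason[neg] <- "negative mean response"
  reason[zero] <- "zero denominator"
  structure(data.frame(unit = rownames(pr$responses) %||%
                         as.character(seq_along(cmi)),
                       r_change = rc, r_pre = rp, cmi = cmi,
                       excluded = excluded, reason = reason,
                       row.names = NULL),
            class = c("cmi_table", "data.frame"))
}

# stratified fold assignment: each class spread evenly over folds
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    stop_if(length(i) < k,
            "class %s has %d presentations, fewer than %d folds",
            cl, length(i), k)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

# linear hyperplane weights of a binary e1071 svm, oriented so the positive
# class scores positive
svm_weights <- function(fit, X, ypos) {
  w <- drop(t(fit$coefs) %*% fit$SV)
  score <- drop(X %*% w)
  if (mean(score[ypos]) < mean(score[!ypos])) w <- -w
  w
}

#' Decode image identity or image change from population responses
#'
#' Trains linear support-vector machines (cost 1, no internal rescaling) with
#' stratified cross-validation. The identity task is 8-way classification on
#' every non-omitted presentation (chance 1/8); the change task is binary,
#' restricted to change versus pre-change presentations (balanced classes,
#' chance 1/2). For the change task, the separating-hyperplane weight per
#' unit (from a fit on all included presentations, oriented so change scores
#' positive) is returned, along with a predictor usable on held-out trials.
#'
#' @param x a `presentation_responses`, `synthetic_population`, or raw matrix
#'   (with `info`)
#' @param target `"change"` or `"identity"`
#' @param info labels when `x` is a raw matrix
#' @param n_folds cross-validation folds
#' @param cost SVM regularization constant
#' @param seed optional integer seed for the fold assignment
#' @return a `decoding_result` list: `task`, `fold_accuracy`, `accuracy`,
#'   `weights` (change task), `fit` (full-data svm), `units`
#' @export
decode_population <- function(x, target = c("change", "identity"),
                              info = NULL, n_folds = 3, cost = 1,
                              seed = NULL) {
  target <- match.arg(target)
  pr <- as_presentation_responses(x, info)
  if (!is.null(seed)) set.seed(seed)
  info <- pr$info
  if (target == "identity") {
    keep <- !info$omitted
    y <- factor(info$image_id[keep])
  } else {
    pre <- info$is_pre_change %||%
      (c(info$is_change[-1L], FALSE) & !info$omitted)
    keep <- info$is_change | pre
    y <- factor(ifelse(info$is_change[keep], "change", "pre"),
                levels = c("pre", "change"))
  }
  X <- t(pr$responses[, keep, drop = FALSE])
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  fold <- stratified_folds(y, n_folds)
  acc <- vapply(seq_len(n_folds), function(f) {
    fit <- e1071::svm(X[fold != f, , drop = FALSE], y[fold != f],
                      kernel = "linear", cost = cost, scale = FALSE)
    mean(predict(fit, X[fold == f, , drop = FALSE]) == y[fold == f])
  }, 0)
  full <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- if (target == "change") svm_weights(full, X, y == "change") else NULL
  structure(list(task = target, fold_accuracy = acc, accuracy = mean(acc),
                 weights = w, fit = full,
                 units = rownames(pr$responses)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding_result (%s): accuracy %.3f (folds: %s)\n", x$task,
              x$accuracy, paste(round(x$fold_accuracy, 3), collapse = ", ")))
  invisible(x)
}

#' Decoding accuracy as a function of population size
#'
#' Repeatedly subsamples a fixed number of units and re-runs the decoder,
#' tracing how accuracy grows (and saturates) with population size.
#'
#' @inheritParams decode_population
#' @param unit_counts vector of population sizes to test
#' @param n_samples random subsets per size
#' @return data frame: `n_units`, `mean_accuracy`, `sd_accuracy`
#' @export
subsample_accuracy_curve <- function(x, target = c("change", "identity"),
                                     unit_counts, n_samples = 10,
                                     info = NULL, n_folds = 3, seed = NULL) {
  target <- match.arg(target)
  pr <- as_presentation_responses(x, info)
  if (!is.null(seed)) set.seed(seed)
  n_units <- nrow(pr$responses)
  rows <- lapply(unit_counts, function(k) {
    k <- check_count(k, "unit_counts")
    stop_if(k > n_units, "requested %d units of %d available", k, n_units)
    accs <- vapply(seq_len(n_samples), function(s) {
      sub <- sample.int(n_units, k)
      decode_population(
        structure(list(responses = pr$responses[sub, , drop = FALSE],
                       info = pr$info), class = "presentation_responses"),
        target = target, n_folds = n_folds)$accuracy
    }, 0)
    data.frame(n_units = k, mean_accuracy = mean(accs),
               sd_accuracy = sd(accs))
  })
  do.call(rbind, rows)
}

#' Correlation between decoder weights and change modulation
#'
#' Pearson correlation, over the units retained by both analyses, between a
#' unit's change-decoder weight and its change modulation index — a positive
#' value says adapting units carry the change signal.
#'
#' @param weights a `decoding_result` (change task) or numeric weight vector
#' @param cmi a `cmi_table`
#' @return Pearson r
#' @export
weight_cmi_correlation <- function(weights, cmi) {
  if (inherits(weights, "decoding_result")) {
    stop_if(is.null(weights$weights), "decoding result has no weights")
    weights <- weights$weights
  }
  stop_if(!inherits(cmi, "cmi_table"), "`cmi` must be a cmi_table")
  stop_if(length(weights) != nrow(cmi),
          "weights (%d) and CMI table (%d) sizes differ",
          length(weights), nrow(cmi))
  keep <- !cmi$excluded
  stop_if(sum(keep) < 3L, "fewer than 3 retained units")
  cor(weights[keep], cmi$cmi[keep])
}

#' Jaccard agreement between predictions and behavior, with shuffle null
#'
#' `|A & B| / (|A| + |B| - |A & B|)` over the positive (respond) indices of
#' two equal-length binary vectors, plus a null distribution obtained by
#' shuffling the predictions.
#'
#' @param predictions,choices logical/0-1 vectors of equal length
#' @param n_shuffles shuffle count for the null
#' @param seed optional integer seed
#' @return a list: `score`, `null_mean`, `null_ci` (2.5/97.5 percentiles)
#' @export
jaccard_agreement <- function(predictions, choices, n_shuffles = 1000,
                              seed = NULL) {
  a <- as.logical(predictions)
  b <- as.logical(choices)
  stop_if(length(a) != length(b), "vector lengths differ")
  stop_if(any(is.na(a)) || any(is.na(b)), "NA in inputs")
  stop_if(!any(a) && !any(b), "both vectors all-zero: Jaccard undefined")
  if (!is.null(seed)) set.seed(seed)
  jac <- function(u, v) sum(u & v) / sum(u | v)
  null <- vapply(seq_len(n_shuffles), function(i) jac(sample(a), b), 0)
  list(score = jac(a, b), null_mean = mean(null),
       null_ci = unname(quantile(null, c(0.025, 0.975))))
}
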