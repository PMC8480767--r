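#' Sample binary behavioral responses from output logits
#'
#' One Bernoulli draw per logit with success probability `sigmoid(logit)` —
#' the stochastic readout that turns the model's decision variable into
#' go/no-go behavior. Infinite logits give deterministic responses.
#'
#' @param logits numeric vector of output logits (may contain +/-Inf)
#' @param seed optional integer seed; if `NULL` the current RNG stream is used
#' @return logical response vector
#' @export
sample_responses <- function(logits, seed = NULL) {
  stop_if(any(is.na(logits)), "logits contain NA")
  if (!is.null(seed)) set.seed(seed)
  runif(length(logits)) < sigmoid(logits)
}

#' Trial records from labeled presentations
#'
#' One record per scheduled event (change or sham change): the image
#' transition, whether it was a go trial, and whether the model responded.
#'
#' @param presentations presentation table with sampled `response` column
#'   (see [evaluate_model()])
#' @return data frame of trial records
#' @export
trial_table <- function(presentations) {
  p <- presentations
  stop_if(is.null(p$response), "presentations lack a `response` column")
  ev <- which(p$is_change | p$is_sham_change)
  ev <- ev[ev > 1L]
  data.frame(trial_id = p$trial_id[ev],
             from_image = p$image_id[ev - 1L],
             to_image = p$image_id[ev],
             is_go = p$is_change[ev],
             responded = p$response[ev],
             preceded_by_omission = p$preceded_by_omission[ev])
}

#' Response-probability matrix over image transitions
#'
#' `M[i, j]` is the fraction of trials with transition image i -> image j on
#' which the subject responded; catch trials populate the diagonal, go trials
#' the off-diagonal. Cells with no trials are `NA` (missing), never 0.
#'
#' @param trials a trial table from [trial_table()]
#' @param n_images image-set size
#' @return a `response_matrix` list with `M` (probabilities) and `counts`
#' @export
response_matrix <- function(trials, n_images = 8) {
  n_images <- check_count(n_images, "n_images", min = 2L)
  stop_if(!all(c("from_image", "to_image", "responded") %in% names(trials)),
          "trial table lacks from_image/to_image/responded")
  idx <- cbind(trials$from_image + 1L, trials$to_image + 1L)
  counts <- matrix(0L, n_images, n_images)
  hits <- matrix(0, n_images, n_images)
  for (r in seq_len(nrow(trials))) {
    counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] + 1L
    hits[idx[r, 1L], idx[r, 2L]] <-
      hits[idx[r, 1L], idx[r, 2L]] + trials$responded[r]
  }
  M <- ifelse(counts > 0, hits / pmax(counts, 1L), NA_real_)
  dimnames(M) <- dimnames(counts) <-
    list(from = paste0("image_", seq_len(n_images) - 1L),
         to = paste0("image_", seq_len(n_images) - 1L))
  structure(list(M = M, counts = counts), class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("response_matrix: %d x %d, %d trials\n",
              nrow(x$M), ncol(x$M), sum(x$counts)))
  print(round(x$M, digits))
  invisible(x)
}

as_prob_matrix <- function(M) {
  if (inherits(M, "response_matrix")) M <- M$M
  M <- as.matrix(M)
  stop_if(nrow(M) != ncol(M), "matrix must be square")
  M
}

#' Symmetry metric Q of a response-probability matrix
#'
#' Quantifies how symmetric the transition response probabilities are about
#' the diagonal. The off-diagonal entries are centered on their mean (the
#' diagonal is ignored throughout), the matrix is split into its symmetric
#' and anti-symmetric parts `(M + t(M))/2` and `(M - t(M))/2`, and
#' `Q = (|Msym| - |Manti|) / (|Msym| + |Manti|)` with Frobenius norms taken
#' over off-diagonal entries. `Q` is 1 for a symmetric, -1 for an
#' anti-symmetric (after centering) pattern, and is invariant to relabeling
#' the images.
#'
#' @param M a `response_matrix` or plain square matrix; all off-diagonal
#'   cells must be populated
#' @return Q in \[-1, 1\]
#' @examples
#' M <- matrix(c(0, .7, .7, .5, 0, .3, .7, .3, 0), 3, byrow = TRUE)
#' matrix_symmetry(M)  # ~ 0.493
#' @export
matrix_symmetry <- function(M) {
  M <- as_prob_matrix(M)
  off <- row(M) != col(M)
  stop_if(any(is.na(M[off])), "off-diagonal cells missing (no trials)")
  C <- M
  C[off] <- M[off] - mean(M[off])
  diag(C) <- 0
  S <- (C + t(C)) / 2
  A <- (C - t(C)) / 2
  ns <- sqrt(sum(S[off]^2))
  na <- sqrt(sum(A[off]^2))
  stop_if(ns + na == 0,
          "degenerate matrix: constant off-diagonal, Q undefined")
  (ns - na) / (ns + na)
}

#' Pearson similarity between two response matrices
#'
#' Correlation over the off-diagonal (go-trial) cells of two
#' response-probability matrices of equal size.
#'
#' @param Ma,Mb `response_matrix` objects or plain square matrices
#' @return Pearson r
#' @export
compare_matrices <- function(Ma, Mb) {
  Ma <- as_prob_matrix(Ma)
  Mb <- as_prob_matrix(Mb)
  stop_if(!all(dim(Ma) == dim(Mb)), "matrix sizes differ")
  off <- row(Ma) != col(Ma)
  stop_if(any(is.na(Ma[off])) || any(is.na(Mb[off])),
          "off-diagonal cells missing")
  cor(Ma[off], Mb[off])
}
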