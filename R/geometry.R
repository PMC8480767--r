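#' Population distance from origin as a function of image repeats
#'
#' PCA-based view of how the population response collapses (or not) with
#' stimulus repetition. Presentation vectors are centered on the mean across
#' all image presentations — that mean defines the origin of the space — and
#' a PCA is fit per dataset. Distances from the origin are then averaged by
#' repeat index (1 = the change/sham presentation itself) for two metrics:
#' the full Euclidean distance (equivalently the root-sum-square over all
#' PCs) and the absolute projection on the first component. Adapting
#' populations show decreasing curves; persistent-activity populations stay
#' flat. Components are retained up to the variance threshold (rank-deficient
#' data simply retain all available components).
#'
#' @param x a `presentation_responses`, `synthetic_population`, or raw
#'   units x presentations matrix (with `info`)
#' @param info labels when `x` is a raw matrix
#' @param variance_threshold cumulative variance the retained PCs must reach
#' @param max_repeat largest repeat index tabulated
#' @return a `repeat_distance_curve` list: `curve` (data frame
#'   `repeat_index`, `metric`, `mean_distance`, `n`), `n_components`,
#'   `var_explained`
#' @export
repeat_distance <- function(x, info = NULL, variance_threshold = 0.95,
                            max_repeat = 11) {
  pr <- as_presentation_responses(x, info)
  check_prob(variance_threshold, "variance_threshold", allow_one = TRUE)
  info <- pr$info
  keep <- !info$omitted
  stop_if(sum(keep) < 2L, "need at least two presentations")
  X <- t(pr$responses[, keep, drop = FALSE])   # presentations x units
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  if (all(is.nan(ve))) ve <- rep(0, length(pca$sdev))  # all-identical input
  n_comp <- if (sum(ve) == 0) length(ve) else
    which(cumsum(ve) >= variance_threshold - 1e-12)[1L]
  centered <- sweep(X, 2L, colMeans(X))
  full <- sqrt(rowSums(centered^2))
  pc1 <- abs(pca$x[, 1L])
  rep_idx <- pmin(info$repeat_index[keep], max_repeat)
  agg <- function(d, name) {
    m <- tapply(d, rep_idx, mean)
    data.frame(repeat_index = as.integer(names(m)), metric = name,
               mean_distance = as.numeric(m),
               n = as.integer(table(rep_idx)))
  }
  structure(list(curve = rbind(agg(full, "full"), agg(pc1, "pc1")),
                 n_components = n_comp, var_explained = ve),
            class = "repeat_distance_curve")
}

#' @export
print.repeat_distance_curve <- function(x, ...) {
  cat(sprintf("repeat_distance_curve: %d PCs retain %.0f%% variance\n",
              x$n_components,
              100 * sum(x$var_explained[seq_len(x$n_components)])))
  print(x$curve)
  invisible(x)
}
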