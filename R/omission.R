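#' Response probabilities around stimulus omissions
#'
#' The perturbation analysis that separates the two memory mechanisms:
#' response probability on go trials, catch trials, all (non-omitted)
#' stimulus presentations, omitted presentations, and post-omitted
#' presentations (the presentation following an omission). A response during
#' the omission forces that trial's post-omitted contribution to zero —
#' mirroring the task logic that aborts a trial on a premature lick.
#' Consecutive double omissions are excluded from both omission categories.
#' A depression-based memory stays silent during the omission (nothing
#' drives it) but responds more afterwards (synapses recovered); a
#' persistent-activity memory does the opposite.
#'
#' @param presentations presentation table with a sampled `response` column
#' @return an `omission_table` data frame: `category`, `probability`, `n`
#' @export
omission_response_probabilities <- function(presentations) {
  p <- presentations
  stop_if(is.null(p$response), "presentations lack a `response` column")
  n <- nrow(p)
  om <- p$omitted
  dbl <- om & (c(om[-1L], FALSE) | c(FALSE, om[-n]))  # runs of >= 2
  om_ok <- om & !dbl
  post <- c(FALSE, om_ok[-n]) & !om
  post_val <- ifelse(p$response[which(post) - 1L], 0, p$response[post])
  cats <- list(
    go = p$response[p$is_change],
    catch = p$response[p$is_sham_change],
    all_presentations = p$response[!om],
    omitted = p$response[om_ok],
    post_omitted = post_val)
  structure(data.frame(
    category = names(cats),
    probability = vapply(cats, function(v)
      if (length(v)) mean(v) else NA_real_, 0),
    n = vapply(cats, length, 0L),
    row.names = NULL), class = c("omission_table", "data.frame"))
}
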