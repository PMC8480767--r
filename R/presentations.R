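#' Per-presentation labels of a stimulus sequence
#'
#' Collapses a timestep-level sequence to one row per presentation slot
#' (flashed or omitted image), adding the derived labels the analysis modules
#' need: `is_pre_change` marks the presentation immediately before a change
#' presentation (the generator guarantees it is not omitted), and
#' `preceded_by_omission` marks presentations whose preceding slot was
#' omitted.
#'
#' @param session a `stim_sequence`
#' @return a data frame with one row per presentation slot
#' @export
presentation_info <- function(session) {
  stop_if(!inherits(session, "stim_sequence"), "not a stim_sequence")
  p <- session[session$frame_kind != "gray",
               c("presentation_id", "step", "frame_kind", "image_id",
                 "is_change", "is_sham_change", "repeat_index", "trial_id")]
  rownames(p) <- NULL
  p$omitted <- p$frame_kind == "omitted"
  n <- nrow(p)
  p$is_pre_change <- c(p$is_change[-1L], FALSE) & !p$omitted
  p$preceded_by_omission <- c(FALSE, p$omitted[-n])
  p
}

#' Per-presentation unit responses from a model run
#'
#' Extracts the activity of one model layer at each presentation timestep,
#' giving a units x presentations response table plus the presentation labels
#' — the common container consumed by the change-modulation, decoding and
#' population-geometry analyses. For adapting models the input layer is read
#' post-depression (`x * r`), matching what a downstream neuron sees; for the
#' RNN the input layer is the (noised) embedding activity itself.
#'
#' @param run a `changenet_run` from [predict.changenet()] or [run_session()]
#' @param layer `"input"` or `"hidden"`
#' @return a `presentation_responses` list with elements `responses`
#'   (units x presentations matrix) and `info` (presentation label table)
#' @export
presentation_responses <- function(run, layer = c("input", "hidden")) {
  layer <- match.arg(layer)
  stop_if(!inherits(run, "changenet_run"), "not a changenet_run")
  info <- presentation_info(run$session)
  act <- switch(layer,
                input = if (run$kind == "rnn") run$input_raw else
                  run$input_gated,
                hidden = run$hidden)
  resp <- t(act[info$step, , drop = FALSE])
  rownames(resp) <- paste0(substr(layer, 1, 1), seq_len(nrow(resp)))
  structure(list(responses = resp, info = info, layer = layer),
            class = "presentation_responses")
}

#' @export
print.presentation_responses <- function(x, ...) {
  cat(sprintf("presentation_responses: %d %s units x %d presentations\n",
              nrow(x$responses), x$layer %||% "?", ncol(x$responses)))
  invisible(x)
}
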