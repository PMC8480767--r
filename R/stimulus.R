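#' Generate a change-detection task session
#'
#' Builds the per-timestep stimulus schedule of the go/no-go visual
#' change-detection task. Images are flashed for one timestep (250 ms) and
#' followed by `isi_steps` gray timesteps (500 ms at the default). An image is
#' repeated a number of times drawn from a truncated geometric law (the
#' discrete analogue of a truncated exponential) on
#' `[min_repeats, max_repeats]` with per-presentation hazard `repeat_hazard`
#' (the change is forced at `max_repeats`); the sequence then either changes
#' to a new image drawn uniformly from the others (go trial, probability
#' `p_go`) or repeats once more as a sham change (catch trial). A fraction
#' `p_omit` of ordinary presentations is replaced by gray (omitted), with the
#' constraint that an omission never immediately precedes a change or sham
#' change presentation, and that change/sham presentations themselves are
#' never omitted.
#'
#' `repeat_index` counts presentations since the most recent scheduled event
#' (change or sham change), starting at 1 on the event presentation itself.
#' After a catch trial the physical run of identical images continues, but the
#' scheduler's repeat draw restarts, as in the task.
#'
#' @param n_trials number of trials (scheduled change/sham events is
#'   `n_trials - 1`; the first trial has no event)
#' @param n_images size of the image set (default 8)
#' @param p_go probability that a scheduled event is a true image change
#' @param p_omit probability that an eligible presentation is omitted
#' @param min_repeats,max_repeats bounds of the truncated repeat distribution
#' @param repeat_hazard per-presentation change hazard beyond `min_repeats`
#' @param isi_steps gray timesteps between presentations (default 2)
#' @param dt seconds per timestep
#' @param seed optional integer seed; if `NULL` the current RNG stream is used
#' @return a `stim_sequence` data frame with one row per timestep and columns
#'   `step`, `frame_kind` (`"image"`, `"gray"`, `"omitted"`), `image_id`
#'   (0-based; the scheduled image on omitted steps), `is_change`,
#'   `is_sham_change`, `repeat_index`, `trial_id`, `presentation_id`.
#'   Attributes `dt`, `n_images` and `task_params` record the generator
#'   settings.
#' @examples
#' s <- generate_session(20, seed = 1)
#' table(s$frame_kind)
#' @export
generate_session <- function(n_trials, n_images = 8, p_go = 0.5,
                             p_omit = 0.05, min_repeats = 4, max_repeats = 11,
                             repeat_hazard = 0.3, isi_steps = 2, dt = 0.25,
                             seed = NULL) {
  n_trials <- check_count(n_trials, "n_trials")
  n_images <- check_count(n_images, "n_images", min = 2L)
  check_prob(p_go, "p_go", allow_one = TRUE)
  check_prob(p_omit, "p_omit")
  min_repeats <- check_count(min_repeats, "min_repeats")
  max_repeats <- check_count(max_repeats, "max_repeats")
  stop_if(max_repeats < min_repeats,
          "`max_repeats` (%d) < `min_repeats` (%d)", max_repeats, min_repeats)
  check_prob(repeat_hazard, "repeat_hazard", allow_one = TRUE)
  isi_steps <- check_count(isi_steps, "isi_steps", min = 0L)
  check_pos(dt, "dt")
  if (!is.null(seed)) set.seed(seed)

  # block lengths: presentations between scheduled events
  ks <- min_repeats:max_repeats
  pk <- repeat_hazard * (1 - repeat_hazard)^(ks - min_repeats)
  pk[length(pk)] <- (1 - repeat_hazard)^(max_repeats - min_repeats)
  if (repeat_hazard == 0) pk <- c(rep(0, length(ks) - 1L), 1)
  len <- sample(ks, n_trials, replace = TRUE, prob = pk)

  # image per block: cumulative uniform jumps on the change events
  go <- c(FALSE, runif(n_trials - 1L) < p_go)
  jump <- ifelse(go, sample.int(n_images - 1L, n_trials, replace = TRUE), 0L)
  img <- (sample.int(n_images, 1L) - 1L + cumsum(jump)) %% n_images

  p_total <- sum(len)
  block <- rep.int(seq_len(n_trials), len)
  within <- sequence(len)
  image_id <- img[block]
  is_event <- within == 1L & block > 1L
  is_change <- is_event & go[block]
  is_sham <- is_event & !go[block]

  # omissions: never on an event presentation, never right before one
  next_event <- c(is_event[-1L], FALSE)
  eligible <- !is_event & !next_event
  omitted <- eligible & runif(p_total) < p_omit

  # expand presentations to timesteps: 1 stimulus frame + isi gray frames
  cyc <- 1L + isi_steps
  n_steps <- p_total * cyc
  pres_row <- seq.int(1L, n_steps, by = cyc)
  frame_kind <- rep("gray", n_steps)
  frame_kind[pres_row] <- ifelse(omitted, "omitted", "image")
  out <- data.frame(
    step = seq_len(n_steps),
    frame_kind = frame_kind,
    image_id = NA_integer_,
    is_change = FALSE,
    is_sham_change = FALSE,
    repeat_index = NA_integer_,
    trial_id = rep.int(block, rep.int(cyc, p_total)),
    presentation_id = NA_integer_,
    stringsAsFactors = FALSE
  )
  out$image_id[pres_row] <- image_id
  out$is_change[pres_row] <- is_change
  out$is_sham_change[pres_row] <- is_sham
  out$repeat_index[pres_row] <- within
  out$presentation_id[pres_row] <- seq_len(p_total)

  attr(out, "dt") <- dt
  attr(out, "n_images") <- n_images
  attr(out, "task_params") <- list(
    n_trials = n_trials, n_images = n_images, p_go = p_go, p_omit = p_omit,
    min_repeats = min_repeats, max_repeats = max_repeats,
    repeat_hazard = repeat_hazard, isi_steps = isi_steps, dt = dt)
  class(out) <- c("stim_sequence", "data.frame")
  out
}

#' Check the structural invariants of a stimulus sequence
#'
#' Verifies, exhaustively over the whole sequence, that every image
#' presentation is followed by the inter-stimulus gray frames, that omissions
#' never immediately precede a change or sham-change presentation, that repeat
#' counts between scheduled events stay within the configured bounds, and that
#' change (sham) presentations differ from (equal) the preceding presented
#' image. Errors on the first violation.
#'
#' @param x a `stim_sequence`
#' @return `x`, invisibly
#' @export
validate_session <- function(x) {
  stop_if(!inherits(x, "stim_sequence"), "not a stim_sequence")
  tp <- attr(x, "task_params")
  pres <- x[x$frame_kind != "gray", ]
  cyc <- 1L + tp$isi_steps
  stop_if(any(diff(pres$step) != cyc),
          "presentations are not spaced by %d steps", cyc)
  ev <- which(pres$is_change | pres$is_sham_change)
  stop_if(any(pres$frame_kind[ev] == "omitted"), "omitted event presentation")
  before <- ev[ev > 1L] - 1L
  stop_if(any(pres$frame_kind[before] == "omitted"),
          "omission immediately precedes a (sham) change")
  gaps <- diff(c(ev, nrow(pres) + 1L))
  stop_if(length(ev) > 0L && any(gaps[-length(gaps)] < tp$min_repeats |
                                   gaps[-length(gaps)] > tp$max_repeats),
          "repeat count outside [%d, %d]", tp$min_repeats, tp$max_repeats)
  chg <- which(pres$is_change)
  chg <- chg[chg > 1L]
  stop_if(any(pres$image_id[chg] == pres$image_id[chg - 1L]),
          "change presentation repeats the previous image")
  shm <- which(pres$is_sham_change)
  shm <- shm[shm > 1L]
  stop_if(any(pres$image_id[shm] != pres$image_id[shm - 1L]),
          "sham change presentation differs from the previous image")
  invisible(x)
}

#' Write / read a stimulus sequence as a delimited table
#'
#' One row per timestep, tab-separated, with the generator settings stored in
#' `#key=value` comment lines ahead of the header (schema version 1).
#'
#' @param x a `stim_sequence`
#' @param path file path
#' @return `write_session`: `path` invisibly; `read_session`: the sequence.
#' @export
write_session <- function(x, path) {
  stop_if(!inherits(x, "stim_sequence"), "not a stim_sequence")
  tp <- attr(x, "task_params")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#changenet_stim_sequence_v1",
               paste0("#", names(tp), "=", unlist(tp))), con)
  write.table(as.data.frame(x), con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  hdr <- readLines(path, n = 20L)
  stop_if(hdr[1L] != "#changenet_stim_sequence_v1",
          "%s: not a stimulus-sequence file (bad magic line)", path)
  meta <- grep("^#.+=", hdr, value = TRUE)
  kv <- strsplit(sub("^#", "", meta), "=", fixed = TRUE)
  tp <- lapply(kv, function(p) {
    v <- suppressWarnings(as.numeric(p[2L]))
    if (is.na(v)) p[2L] else v
  })
  names(tp) <- vapply(kv, `[[`, "", 1L)
  out <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("step", "frame_kind", "image_id", "is_change", "is_sham_change",
            "repeat_index", "trial_id", "presentation_id")
  miss <- setdiff(need, names(out))
  stop_if(length(miss) > 0L, "%s: missing columns: %s", path,
          paste(miss, collapse = ", "))
  attr(out, "dt") <- tp$dt
  attr(out, "n_images") <- as.integer(tp$n_images)
  attr(out, "task_params") <- tp
  class(out) <- c("stim_sequence", "data.frame")
  out
}
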