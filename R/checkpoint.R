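#' Save / load a fitted model checkpoint
#'
#' Serializes everything needed to re-run a fitted model — weights,
#' architecture, synapse and task settings, embeddings, seed and training
#' history — as JSON (schema `changenet_model_v1`). Numbers are written at
#' full double precision, so a load/save round trip reproduces the model
#' bit-exactly; `predict()` on a reloaded model with the same seed yields
#' identical logits. The final-epoch evaluation used by
#' [residuals.changenet()] is not stored.
#'
#' @param object a fitted `changenet`
#' @param path file path (conventionally `.json`)
#' @return `write_model`: `path`, invisibly. `read_model`: a `changenet`.
#' @export
write_model <- function(object, path) {
  stop_if(!inherits(object, "changenet"), "not a changenet model")
  pack <- function(p) list(dim = dim(p), values = as.vector(p))
  payload <- list(
    schema = "changenet_model_v1",
    kind = object$kind, n_hidden = object$n_hidden,
    noise_sd = object$noise_sd, seed = object$seed,
    stp = unclass(object$stp), task = unclass(object$task),
    control = unclass(object$control),
    stop_epoch = object$stop_epoch, stop_reason = object$stop_reason,
    par = lapply(object$par, pack),
    embeddings = c(pack(unclass(object$embeddings)),
                   list(saliency = attr(object$embeddings, "saliency"))),
    history = object$history)
  # I(17) significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  stop_if(!identical(p$schema, "changenet_model_v1"),
          "%s: not a changenet model checkpoint", path)
  unpack <- function(x) {
    v <- as.numeric(x$values)
    if (length(x$dim)) array(v, dim = as.integer(x$dim)) else v
  }
  par <- lapply(p$par, unpack)
  par$W_ad <- as.matrix(par$W_ad)
  par$W_pl <- as.matrix(par$W_pl)
  par$W_rec <- as.matrix(par$W_rec)
  if (!nrow(par$W_ad)) par$W_ad <- matrix(0, 0, 0)
  if (!nrow(par$W_pl)) par$W_pl <- matrix(0, 0, 0)
  if (!nrow(par$W_rec)) par$W_rec <- matrix(0, 0, 0)
  emb <- unpack(p$embeddings)
  dimnames(emb) <- list(paste0("image_", seq_len(nrow(emb)) - 1L),
                        paste0("unit_", seq_len(ncol(emb))))
  sal <- as.numeric(p$embeddings$saliency)
  names(sal) <- rownames(emb)
  emb <- structure(emb, saliency = sal,
                   class = c("embedding_matrix", "matrix", "array"))
  structure(list(kind = p$kind, par = par, embeddings = emb,
                 n_hidden = as.integer(p$n_hidden), noise_sd = p$noise_sd,
                 stp = structure(p$stp, class = "stp_params"),
                 control = structure(p$control, class = "train_control"),
                 task = structure(p$task, class = "task_params"),
                 seed = p$seed, history = p$history,
                 stop_epoch = as.integer(p$stop_epoch),
                 stop_reason = p$stop_reason,
                 final_eval = NULL, call = NULL),
            class = "changenet")
}
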