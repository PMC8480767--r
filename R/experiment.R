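#' Write / read external response tables
#'
#' Serializes a units x presentations response table plus its presentation
#' labels as a pair of tab-separated files (`<prefix>_traces.tsv`,
#' `<prefix>_labels.tsv`), the documented schema for analyzing externally
#' recorded populations (e.g. per-presentation dF/F means) with the same code
#' paths as model activities. `read_traces` validates the schema and reports
#' the offending columns on mismatch.
#'
#' @param x a `presentation_responses` or `synthetic_population`
#' @param prefix path prefix for the two files
#' @return `write_traces`: the prefix, invisibly. `read_traces`: a
#'   `presentation_responses`.
#' @export
write_traces <- function(x, prefix) {
  pr <- as_presentation_responses(x)
  tr <- data.frame(unit = rownames(pr$responses) %||%
                     as.character(seq_len(nrow(pr$responses))),
                   pr$responses, check.names = FALSE)
  colnames(tr)[-1L] <- paste0("p", seq_len(ncol(pr$responses)))
  write.table(tr, paste0(prefix, "_traces.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(pr$info, paste0(prefix, "_labels.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_traces
#' @export
read_traces <- function(prefix) {
  tpath <- paste0(prefix, "_traces.tsv")
  lpath <- paste0(prefix, "_labels.tsv")
  stop_if(!file.exists(tpath) || !file.exists(lpath),
          "missing %s_traces.tsv / %s_labels.tsv", prefix, prefix)
  tr <- read.delim(tpath, check.names = FALSE)
  stop_if(names(tr)[1L] != "unit",
          "%s: first column must be `unit`, found `%s`", tpath, names(tr)[1L])
  info <- read.delim(lpath)
  need <- c("presentation_id", "image_id", "is_change", "is_sham_change",
            "repeat_index", "omitted")
  miss <- setdiff(need, names(info))
  stop_if(length(miss) > 0L, "%s: missing label columns: %s", lpath,
          paste(miss, collapse = ", "))
  resp <- as.matrix(tr[, -1L, drop = FALSE])
  stop_if(ncol(resp) != nrow(info),
          "trace columns (%d) do not match label rows (%d)",
          ncol(resp), nrow(info))
  stop_if(any(!is.finite(resp)), "%s: non-finite response values", tpath)
  rownames(resp) <- tr$unit
  if (is.null(info$is_pre_change))
    info$is_pre_change <- c(info$is_change[-1L], FALSE) & !info$omitted
  structure(list(responses = resp, info = info),
            class = "presentation_responses")
}

default_experiment_config <- function() {
  list(kinds = c("stpnet", "rnn"), seeds = 1:10, n_hidden = 16,
       noise_sd = 0.5, U = 0.5, tau_x = 1.5,
       trials_per_epoch = 100, max_epochs = 5000, dprime_criterion = 1.5,
       patience = 5, eval_trials = 2000, p_omit = 0.05,
       out_dir = "changenet_results")
}

read_experiment_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      stop_if(!requireNamespace("yaml", quietly = TRUE),
              "yaml package required for YAML configs")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stop_if(!is.list(config), "config must be a list or a JSON/YAML path")
  def <- default_experiment_config()
  unknown <- setdiff(names(config), names(def))
  stop_if(length(unknown) > 0L, "unknown config keys: %s",
          paste(unknown, collapse = ", "))
  modifyList(def, config)
}

#' Run the full model-comparison experiment
#'
#' End-to-end driver: trains every requested model kind across seeds, then
#' runs the analysis battery on a fresh evaluation session per model (with
#' omissions, which training never contains) and writes all artifacts to
#' `out_dir` as delimited tables — training histories, response-probability
#' matrices with Q values, input-unit change-modulation tables, omission
#' tables, repeat-distance curves, hidden-layer decoding accuracies — plus a
#' `manifest.json` recording the
#' package version, expanded configuration and seeds, from which any single
#' artifact can be regenerated in isolation.
#'
#' @param config a named list (or path to a JSON/YAML file) overriding the
#'   defaults: `kinds`, `seeds`, `n_hidden`, `noise_sd`, `U`, `tau_x`,
#'   `trials_per_epoch`, `max_epochs`, `dprime_criterion`, `patience`,
#'   `eval_trials`, `p_omit`, `out_dir`. Unknown keys are rejected.
#' @return invisibly, a list with a per-model summary data frame and the
#'   expanded config
#' @export
run_experiment <- function(config = list()) {
  cfg <- read_experiment_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) write.table(d, file.path(cfg$out_dir, f), sep = "\t",
                                    row.names = FALSE, quote = FALSE)
  rows <- list()
  for (kind in cfg$kinds) {
    for (seed in cfg$seeds) {
      fit <- changenet(
        kind, seed = seed, n_hidden = cfg$n_hidden, noise_sd = cfg$noise_sd,
        stp = stp_params(U = cfg$U, tau_x = cfg$tau_x),
        control = train_control(trials_per_epoch = cfg$trials_per_epoch,
                                max_epochs = cfg$max_epochs,
                                dprime_criterion = cfg$dprime_criterion,
                                patience = cfg$patience))
      tag <- sprintf("%s_seed%d", kind, seed)
      tsv(fit$history, paste0("history_", tag, ".tsv"))
      ev <- evaluate_model(fit, n_trials = cfg$eval_trials,
                           p_omit = cfg$p_omit,
                           seed = derive_seed(seed, 101L))
      rm <- response_matrix(ev$trials, n_images = fit$task$n_images)
      tsv(data.frame(from = rownames(rm$M), rm$M, check.names = FALSE),
          paste0("response_matrix_", tag, ".tsv"))
      cmi <- change_modulation_index(
        presentation_responses(ev$run, "input"))
      tsv(cmi, paste0("cmi_input_", tag, ".tsv"))
      om <- omission_response_probabilities(ev$presentations)
      tsv(om, paste0("omission_", tag, ".tsv"))
      rd <- repeat_distance(presentation_responses(ev$run, "hidden"))
      tsv(rd$curve, paste0("repeat_distance_", tag, ".tsv"))
      hid <- presentation_responses(ev$run, "hidden")
      dec <- decode_population(hid, "change",
                               seed = derive_seed(seed, 102L))
      dec_id <- decode_population(hid, "identity",
                                  seed = derive_seed(seed, 103L))
      hcmi <- change_modulation_index(hid)
      tsv(data.frame(task = c("change", "identity"),
                     accuracy = c(dec$accuracy, dec_id$accuracy),
                     folds = c(paste(round(dec$fold_accuracy, 4),
                                     collapse = ","),
                               paste(round(dec_id$fold_accuracy, 4),
                                     collapse = ","))),
          paste0("decoding_", tag, ".tsv"))
      rows[[tag]] <- data.frame(
        kind = kind, seed = seed, stop_epoch = fit$stop_epoch,
        stop_reason = fit$stop_reason, dprime = ev$dprime,
        hit_rate = ev$hit_rate, fa_rate = ev$fa_rate,
        Q = tryCatch(matrix_symmetry(rm), error = function(e) NA_real_),
        mean_input_cmi = mean(cmi$cmi, na.rm = TRUE),
        p_omitted = om$probability[om$category == "omitted"],
        p_post_omitted = om$probability[om$category == "post_omitted"],
        change_acc = dec$accuracy, identity_acc = dec_id$accuracy,
        # change information in hidden units: readout weight vs modulation
        wout_cmi_r = tryCatch(
          weight_cmi_correlation(fit$par$w_out, hcmi),
          error = function(e) NA_real_))
    }
  }
  summary_df <- do.call(rbind, c(rows, make.row.names = FALSE))
  tsv(summary_df, "summary.tsv")
  manifest <- list(package = "changenet",
                   version = as.character(utils::packageVersion("changenet")),
                   r_version = R.version.string,
                   config = cfg, created = format(Sys.time(), "%Y-%m-%d"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summary = summary_df, config = cfg))
}
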