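# shared fixtures; heavy objects are trained once per test run and cached

.cn_cache <- new.env(parent = emptyenv())

cn_cached <- function(key, expr) {
  if (is.null(.cn_cache[[key]])) .cn_cache[[key]] <- expr
  .cn_cache[[key]]
}

# fast training configuration for structural tests (not the study conditions)
quick_control <- function(...) {
  train_control(trials_per_epoch = 20, max_epochs = 30, ...)
}

quick_fit <- function(kind = "stpnet", seed = 1, ...) {
  cn_cached(paste0("quick_", kind, "_", seed),
            changenet(kind, seed = seed, control = quick_control(), ...))
}

# study-condition ensembles: 10 seeds per model kind, defaults throughout
ensemble_fit <- function(kind, seeds = 1:10) {
  cn_cached(paste0("ens_", kind),
            lapply(seeds, function(s) changenet(kind, seed = s)))
}

# per-model evaluation sessions (5% omissions, 2000 trials for stable
# transition-matrix cells)
ensemble_eval <- function(kind, n_trials = 2000) {
  cn_cached(paste0("eval_", kind), {
    fits <- ensemble_fit(kind)
    lapply(fits, function(f)
      evaluate_model(f, n_trials = n_trials,
                     seed = derive_seed(f$seed, 101L)))
  })
}

ci95 <- function(v) mean(v) + c(-1, 1) * 1.96 * sd(v) / sqrt(length(v))
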