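# Shared trained-network cache: the heavier tests (replication cells,
# trend properties, training contract) reuse one ensemble per context
# span rather than retraining per test block. Networks are trained
# lazily, one at a time, with the same per-network seed derivation as
# train_ensemble(seed = ENSEMBLE_SEED), so cached_ensemble(span, n) is
# identical to train_ensemble(span, n, seed = ENSEMBLE_SEED).

ENSEMBLE_SEED <- 42L

.ensemble_cache <- new.env(parent = emptyenv())

cached_ensemble <- function(span, n_networks) {
  key <- paste0("span", span)
  nets <- .ensemble_cache[[key]]
  if (is.null(nets)) nets <- list()
  spec <- context_net_spec(span)
  cfg <- train_config()
  while (length(nets) < n_networks) {
    k <- length(nets) + 1L
    net_seed <- ctxnet:::derive_seed(ENSEMBLE_SEED, "ensemble", span, k)
    ts <- ctxnet:::build_training_set(span, cfg$samples_per_class,
                                      cfg$train_noise_variance, seed = net_seed)
    cfg_k <- cfg
    cfg_k$seed <- net_seed
    nets[[k]] <- train_network(spec, ts$inputs, ts$labels, cfg_k)
  }
  .ensemble_cache[[key]] <- nets
  nets[seq_len(n_networks)]
}

run_cell <- function(set_id, center, sigma2, n_networks, n_samples) {
  spec <- experiment_spec(set_id, center, n_networks = n_networks,
                          n_samples = n_samples, noise_grid = sigma2,
                          seed = ENSEMBLE_SEED)
  run_set(spec, networks = cached_ensemble(spec$span, n_networks))
}
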