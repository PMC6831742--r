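## Shared synthetic corpora, built once per test run and cached.

.corpus_cache <- new.env(parent = emptyenv())

## 1,000 generated molecules used by the encoding / charge-conservation
## sweeps and the fingerprint property tests.
corpus_molecules <- function(n = 1000, seed = 20240901) {
  key <- sprintf("mols_%d_%d", n, seed)
  if (is.null(.corpus_cache[[key]])) {
    spec <- synth_spec(seed = seed)
    .corpus_cache[[key]] <- lapply(seq_len(n), function(i)
      generate_molecule(spec, i))
  }
  .corpus_cache[[key]]
}

## Labeled training corpus for the model-recovery test: batches of
## molecules until nitrogen reaches the target row count, so every one of
## C, H, N, O trains on >= 4,000 atoms under the 1:4 split.
corpus_training_table <- function(seed = 20240901, n_target = 20000) {
  key <- sprintf("table_%d_%d", seed, n_target)
  if (is.null(.corpus_cache[[key]])) {
    spec <- synth_spec(seed = seed)
    tabs <- list(); n_count <- 0; idx0 <- 1L
    while (n_count < n_target) {
      tb <- make_dataset(spec, 1000, start_index = idx0)
      tabs[[length(tabs) + 1]] <- tb
      idx0 <- idx0 + 1000L
      n_count <- n_count + sum(tb$element == "N")
    }
    .corpus_cache[[key]] <- do.call(rbind, tabs)
    rm(tabs); invisible(gc())
  }
  .corpus_cache[[key]]
}
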