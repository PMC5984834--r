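# Memoized default-condition datasets shared across test files, so seed
# sweeps do not regenerate the same genomes repeatedly.
.dataset_cache <- new.env(parent = emptyenv())

default_dataset <- function(seed) {
  key <- as.character(seed)
  if (is.null(.dataset_cache[[key]]))
    .dataset_cache[[key]] <- generate_dataset(simulation_params(seed = seed))
  .dataset_cache[[key]]
}
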