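# Shared fixtures: a small config factory and the drug-like SMILES set used
# for parser-oracle and finiteness checks.

tiny_config <- function(d = 4L, depth = 2L, seed = 7L, ...) {
  rxn_config(hidden_size = d, depth = depth, seed = seed, ...)
}

tiny_params <- function(config, n_components = 1L,
                        vocab_width = 0L) {
  graph_part <- if (config$aggregation == "concat") {
    config$hidden_size * n_components
  } else {
    config$hidden_size
  }
  rxngraph:::init_params(config, head_input = graph_part + vocab_width)
}

fixture_smiles <- function() {
  readLines(system.file("extdata", "fixture_smiles.txt",
                        package = "rxngraph"))
}

small_molecules <- c("C", "CC", "CCO", "C=O", "CCN", "O", "C#N")
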