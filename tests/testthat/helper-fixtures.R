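# small builders shared across test files

two_ont_net <- function() {
  bmkn(c("DO", "SYMP")) |>
    add_concepts(tibble::tibble(
      id = c("lung_cancer", "respiratory_system_cancer", "cough"),
      ontology = c("DO", "DO", "SYMP")
    ))
}

# random graphs for property tests; seeds below 2^31
random_net <- function(seed, random_weights = FALSE) {
  simulate_bmkn(
    n_ontologies = 3, concepts_per_ontology = sample(c(8, 12, 16), 1),
    extra_intra_rate = 0.06, inter_rate = 0.05,
    random_weights = random_weights, seed = seed
  )
}

random_anchor <- function(net, seed) {
  with_seed_local(seed, sample(net$concepts$id, 1))
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
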