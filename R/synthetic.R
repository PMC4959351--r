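# run expr with a private, restored RNG stream seeded from `seed`
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Worked-example two-ontology network
#'
#' A small disease/symptom network used throughout the documentation and
#' tests: a disease ontology `D` (anchor `D0`, labelled Lupus, plus
#' `D1`--`D4` and `D9`--`D12`) and a symptom ontology `S` (`S1`--`S5`),
#' wired so that expansion around `D0` exercises every branch of the
#' recursion. The only route from `D0` to `D11` (Rheumatoid Arthritis) runs
#' through the similar symptoms `S2` (Painful Swollen Joint) and `S3`
#' (Joint Swelling) — the pattern of a plausible misdiagnosis that
#' intra-ontology search alone cannot surface.
#'
#' All edges carry the structured-source default weights (1.0, 1.0).
#' Disease-to-symptom edges are typed `has_symptom`, symptom-to-disease
#' edges `suggests`, intra edges `is_a`.
#'
#' @return A [bmkn()] object.
#' @examples
#' net <- toy_disease_symptom_network()
#' initial_sets(net, "D0")
#' interesting_set(net, "D0", 2, "D")
#' @export
toy_disease_symptom_network <- function() {
  labels <- c(
    D0 = "Lupus", S2 = "Painful Swollen Joint", S3 = "Joint Swelling",
    D11 = "Rheumatoid Arthritis"
  )
  d_ids <- c("D0", paste0("D", 1:4), paste0("D", 9:12))
  s_ids <- paste0("S", 1:5)
  concepts <- tibble::tibble(
    id = c(d_ids, s_ids),
    ontology = c(rep("D", length(d_ids)), rep("S", length(s_ids)))
  )
  concepts$label <- ifelse(concepts$id %in% names(labels),
                           labels[concepts$id], concepts$id)
  intra <- tibble::tribble(
    ~source, ~target,
    "D0", "D1", "D0", "D2", "D1", "D3", "D2", "D4",
    "S2", "S3", "S1", "S4", "S2", "S5"
  )
  intra$rel <- "is_a"
  inter <- tibble::tribble(
    ~source, ~target, ~rel,
    "D0", "S1", "has_symptom",
    "D0", "S2", "has_symptom",
    "D2", "S3", "has_symptom",
    "S1", "D9", "suggests",
    "S2", "D10", "suggests",
    "S3", "D11", "suggests",
    "S4", "D12", "suggests"
  )
  bmkn(c("D", "S")) |>
    add_concepts(concepts) |>
    add_edges(dplyr::bind_rows(intra, inter))
}

#' Simulate a random multi-ontology knowledge network
#'
#' Each ontology's intra structure is a random rooted tree (edges directed
#' root-to-leaf, mimicking hierarchies materialised in the parent-to-child
#' direction) plus optional extra intra edges; ontologies are cross-linked
#' by random directed inter edges. Generation is a pure function of the
#' arguments and `seed`.
#'
#' @param n_ontologies Number of ontologies (named `O1`, `O2`, ...).
#' @param concepts_per_ontology Concepts in each ontology (recycled).
#' @param extra_intra_rate Probability of each additional ordered
#'   same-ontology pair receiving a `related_to` edge.
#' @param inter_rate Probability of each ordered cross-ontology pair
#'   receiving a `linked_to` edge.
#' @param random_weights If `TRUE`, confidence and significance are drawn
#'   from Uniform(0, 1); otherwise all edges get the structured-source
#'   default 1.0.
#' @param seed Integer seed (required).
#' @return A [bmkn()] object that passes [validate_bmkn()].
#' @export
simulate_bmkn <- function(n_ontologies = 3, concepts_per_ontology = 20,
                          extra_intra_rate = 0.05, inter_rate = 0.02,
                          random_weights = FALSE, seed) {
  stopifnot(n_ontologies >= 1, all(concepts_per_ontology >= 1),
            extra_intra_rate >= 0, extra_intra_rate <= 1,
            inter_rate >= 0, inter_rate <= 1)
  sizes <- rep_len(concepts_per_ontology, n_ontologies)
  onts <- paste0("O", seq_len(n_ontologies))
  with_seed(seed, {
    concepts <- dplyr::bind_rows(lapply(seq_len(n_ontologies), function(k) {
      tibble::tibble(
        id = sprintf("%s_c%03d", onts[k], seq_len(sizes[k])),
        ontology = onts[k]
      )
    }))
    edges <- list()
    for (k in seq_len(n_ontologies)) {
      ids <- concepts$id[concepts$ontology == onts[k]]
      n <- length(ids)
      if (n >= 2) {
        parent <- vapply(2:n, function(m) sample.int(m - 1L, 1L), integer(1))
        tree <- tibble::tibble(source = ids[parent], target = ids[2:n],
                               rel = "father_to_son")
        edges <- c(edges, list(tree))
        # extra non-tree intra edges
        pairs <- expand.grid(source = ids, target = ids,
                             stringsAsFactors = FALSE)
        pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
        key <- paste(pairs$source, pairs$target)
        tkey <- paste(tree$source, tree$target)
        pairs <- pairs[!key %in% tkey, , drop = FALSE]
        hit <- stats::runif(nrow(pairs)) < extra_intra_rate
        if (any(hit)) {
          ex <- pairs[hit, , drop = FALSE]
          ex$rel <- "related_to"
          edges <- c(edges, list(tibble::as_tibble(ex)))
        }
      }
    }
    if (n_ontologies >= 2 && inter_rate > 0) {
      pairs <- expand.grid(source = concepts$id, target = concepts$id,
                           stringsAsFactors = FALSE)
      so <- concepts$ontology[match(pairs$source, concepts$id)]
      to <- concepts$ontology[match(pairs$target, concepts$id)]
      pairs <- pairs[so != to, , drop = FALSE]
      hit <- stats::runif(nrow(pairs)) < inter_rate
      if (any(hit)) {
        ie <- pairs[hit, , drop = FALSE]
        ie$rel <- "linked_to"
        edges <- c(edges, list(tibble::as_tibble(ie)))
      }
    }
    edges <- if (length(edges)) dplyr::bind_rows(edges) else
      tibble::tibble(source = character(), target = character(),
                     rel = character())
    if (nrow(edges)) {
      if (random_weights) {
        edges$confidence <- stats::runif(nrow(edges))
        edges$significance <- stats::runif(nrow(edges))
      } else {
        edges$confidence <- 1
        edges$significance <- 1
      }
    }
    net <- bmkn(onts) |> add_concepts(concepts)
    if (nrow(edges)) net <- add_edges(net, edges)
    net
  })
}

#' Simulate a disease/symptom network with planted implicit relatedness
#'
#' Builds a two-ontology network (`DIS` diseases, `SYM` symptoms) in which
#' a known set of "planted" diseases is related to the anchor only through
#' shared symptoms: each planted disease lies outside the anchor's forward
#' intra-reach (it sits in another branch of the disease hierarchy) but
#' shares at least one symptom with the anchor via a
#' `has_symptom`/`suggests` edge pair. The returned reference list records
#' exactly the planted diseases, giving evaluation harnesses a ground
#' truth: symptom-mediated expansion should recover them, intra-only
#' search cannot.
#'
#' @param n_diseases,n_symptoms Ontology sizes (anchor and its local
#'   neighbourhood are added on top of `n_diseases`).
#' @param n_planted Number of diseases wired to share a symptom with the
#'   anchor.
#' @param inter_noise Probability of each ordered disease/symptom pair
#'   receiving a spurious inter edge (background clutter producing chance
#'   candidates).
#' @param seed Integer seed (required).
#' @return List with `net` (a [bmkn()]), `anchor` (its id), and
#'   `reference` (tibble `anchor`, `id` listing the planted diseases).
#' @export
simulate_planted_bmkn <- function(n_diseases = 40, n_symptoms = 30,
                                  n_planted = 4, inter_noise = 0.005, seed) {
  stopifnot(n_diseases >= n_planted + 2, n_symptoms >= n_planted + 2,
            n_planted >= 1, inter_noise >= 0, inter_noise <= 1)
  with_seed(seed, {
    d_ids <- sprintf("DIS_c%03d", seq_len(n_diseases))
    s_ids <- sprintf("SYM_c%03d", seq_len(n_symptoms))
    anchor <- "DIS_anchor"
    local <- c("DIS_sib1", "DIS_sib2", "DIS_kid1", "DIS_kid2")
    concepts <- tibble::tibble(
      id = c(d_ids, anchor, local, s_ids),
      ontology = c(rep("DIS", n_diseases + 5L), rep("SYM", n_symptoms))
    )
    # disease hierarchy: random tree over d_ids, root d_ids[1]
    d_parent <- vapply(2:n_diseases, function(m) sample.int(m - 1L, 1L),
                       integer(1))
    d_tree <- tibble::tibble(source = d_ids[d_parent],
                             target = d_ids[2:n_diseases])
    # anchor hangs off the root with its own small subtree; nothing in the
    # main tree is forward-reachable from the anchor
    anchor_part <- tibble::tibble(
      source = c(d_ids[1], anchor, anchor, "DIS_sib1", "DIS_sib2"),
      target = c(anchor, "DIS_sib1", "DIS_sib2", "DIS_kid1", "DIS_kid2")
    )
    s_parent <- vapply(2:n_symptoms, function(m) sample.int(m - 1L, 1L),
                       integer(1))
    s_tree <- tibble::tibble(source = s_ids[s_parent],
                             target = s_ids[2:n_symptoms])
    intra <- dplyr::bind_rows(d_tree, anchor_part, s_tree)
    intra$rel <- "father_to_son"

    planted <- sample(d_ids[-1], n_planted)
    shared <- sample(s_ids, n_planted)
    plant_edges <- dplyr::bind_rows(
      tibble::tibble(source = anchor, target = shared, rel = "has_symptom"),
      tibble::tibble(source = shared, target = planted, rel = "suggests")
    )
    pairs <- expand.grid(source = c(d_ids, anchor, local), target = s_ids,
                         stringsAsFactors = FALSE)
    noise_ds <- pairs[stats::runif(nrow(pairs)) < inter_noise, , drop = FALSE]
    noise_ds$rel <- "has_symptom"
    pairs2 <- expand.grid(source = s_ids, target = c(d_ids, local),
                          stringsAsFactors = FALSE)
    noise_sd <- pairs2[stats::runif(nrow(pairs2)) < inter_noise, , drop = FALSE]
    noise_sd$rel <- "suggests"
    edges <- dplyr::bind_rows(intra, plant_edges,
                              tibble::as_tibble(noise_ds),
                              tibble::as_tibble(noise_sd)) |>
      dplyr::distinct(.data$source, .data$target, .data$rel)
    net <- bmkn(c("DIS", "SYM")) |>
      add_concepts(concepts) |>
      add_edges(edges)
    list(net = net, anchor = anchor,
         reference = tibble::tibble(anchor = anchor, id = sort(planted)))
  })
}

#' Simulate an annotated document corpus
#'
#' Documents carry a set of annotated concept ids and a journal impact
#' factor drawn from LogNormal(meanlog = 1, sdlog = 0.5). Designated pairs
#' co-occur at a boosted rate: with probability `pair_bias` a document has
#' one boosted pair injected into its concept set, so boosted pairs
#' accumulate co-occurrence counts far above the uniform background.
#'
#' @param n_docs Number of documents.
#' @param concept_pool Character vector of concept ids to sample from.
#' @param boosted_pairs Optional two-column data frame (`u`, `v`) of pairs
#'   to over-represent.
#' @param pair_bias Probability that a document receives a boosted pair.
#' @param seed Integer seed (required).
#' @return Tibble with columns `doc_id`, `concepts` (list of character),
#'   `impact_factor`.
#' @export
simulate_corpus <- function(n_docs = 100, concept_pool,
                            boosted_pairs = NULL, pair_bias = 0,
                            seed) {
  stopifnot(length(concept_pool) >= 2, n_docs >= 1,
            pair_bias >= 0, pair_bias <= 1)
  if (!is.null(boosted_pairs)) {
    stopifnot(is.data.frame(boosted_pairs),
              all(c("u", "v") %in% names(boosted_pairs)),
              all(unlist(boosted_pairs[c("u", "v")]) %in% concept_pool))
  }
  with_seed(seed, {
    docs <- lapply(seq_len(n_docs), function(i) {
      m <- sample(2:min(5, length(concept_pool)), 1L)
      ids <- sample(concept_pool, m)
      if (!is.null(boosted_pairs) && nrow(boosted_pairs) > 0 &&
          stats::runif(1) < pair_bias) {
        r <- sample.int(nrow(boosted_pairs), 1L)
        ids <- unique(c(ids, boosted_pairs$u[r], boosted_pairs$v[r]))
      }
      sort(ids)
    })
    tibble::tibble(
      doc_id = sprintf("doc%04d", seq_len(n_docs)),
      concepts = docs,
      impact_factor = stats::rlnorm(n_docs, meanlog = 1, sdlog = 0.5)
    )
  })
}
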