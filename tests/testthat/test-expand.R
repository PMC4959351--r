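toy <- toy_disease_symptom_network()

test_that("initial sets are the anchor's forward intra and inter neighbours", {
  init <- initial_sets(toy, "D0")
  expect_equal(init$D, c("D1", "D2"))
  expect_equal(init$S, c("S1", "S2"))

  # an anchor with no edges yields empty sets for every ontology
  iso <- add_concepts(toy, tibble::tibble(id = "D99", ontology = "D"))
  init_iso <- initial_sets(iso, "D99")
  expect_equal(lengths(init_iso), c(D = 0L, S = 0L))

  # three-ontology graph: one set per registered ontology, matching a
  # direct neighbour scan
  net3 <- random_net(101)
  a <- random_anchor(net3, 1)
  init3 <- initial_sets(net3, a)
  expect_named(init3, net3$ontologies)
  a_ont <- unname(concept_ontology(net3, a))
  for (t in net3$ontologies) {
    direct <- if (t == a_ont) {
      neighbors_out(net3, a, class = "intra")
    } else {
      neighbors_out(net3, a, class = "inter", target_ontology = t)
    }
    expect_equal(init3[[t]], setdiff(direct, a))
  }
})

test_that("every printed set identity of the worked example reproduces", {
  expect_equal(expand_set(toy, "D0", 0, 0, "D"), c("D1", "D2"))
  expect_equal(expand_set(toy, "D0", 0, 0, "S"), c("S1", "S2"))
  expect_equal(expand_set(toy, "D0", 0, 1, "D"), c("D1", "D2", "D3", "D4"))
  expect_equal(expand_set(toy, "D0", 1, 0, "D"),
               sort(c("D1", "D2", "D9", "D10")))
  expect_equal(expand_set(toy, "D0", 1, 1, "D"),
               sort(c("D1", "D2", "D3", "D4", "D9", "D10")))
  expect_equal(expand_set(toy, "D0", 0, 1, "S"), paste0("S", 1:5))
  expect_equal(expand_set(toy, "D0", 1, 0, "S"), c("S1", "S2", "S3"))
  expect_equal(expand_set(toy, "D0", 1, 1, "S"), paste0("S", 1:5))
  expect_equal(interesting_set(toy, "D0", 2, "D"),
               sort(c("D9", "D10", "D11", "D12")))
})

test_that("expansion indices must be non-negative and ontology known", {
  expect_error(expand_set(toy, "D0", -1, 0, "D"))
  expect_error(expand_set(toy, "D0", 0, 0, "GO"), "unknown ontology")
  expect_error(expand_set(toy, "nope", 0, 0, "D"), "unknown anchor")
})

test_that("memoized engine equals the naive uncached recursion", {
  for (seed in 1:25) {
    net <- random_net(seed)
    a <- random_anchor(net, seed)
    for (t in net$ontologies) {
      for (i in 0:4) {
        for (j in 0:4) {
          expect_equal(
            expand_set(net, a, i, j, t),
            naive_cell(net, a, i, j, t),
            info = sprintf("seed %d cell (%d,%d,%s)", seed, i, j, t)
          )
        }
      }
    }
  }
})

test_that("diagonal sets grow monotonically and contain the initial sets", {
  for (seed in 26:45) {
    net <- random_net(seed)
    a <- random_anchor(net, seed)
    init <- initial_sets(net, a)
    for (t in net$ontologies) {
      prev <- character()
      for (s in 0:4) {
        cur <- expand_set(net, a, s, s, t)
        expect_true(all(prev %in% cur))
        expect_true(all(init[[t]] %in% cur))
        prev <- cur
      }
      # containment of the initial set in off-diagonal cells too
      expect_true(all(init[[t]] %in% expand_set(net, a, 1, 3, t)))
      expect_true(all(init[[t]] %in% expand_set(net, a, 3, 1, t)))
    }
  }
})

test_that("the anchor never appears in any expansion cell or RN node list", {
  for (seed in 46:55) {
    net <- random_net(seed)
    a <- random_anchor(net, seed)
    for (t in net$ontologies) {
      for (i in 0:3) {
        expect_false(a %in% expand_set(net, a, i, 3, t))
        expect_false(a %in% expand_set(net, a, 3, i, t))
      }
    }
    rn <- relatedness_network(net, a, steps = 2)
    expect_false(a %in% rn$nodes$id)
    expect_equal(rn$anchor, a)
  }
})

test_that("with no inter edges, cells reduce to forward intra reachability", {
  skip_if_not_installed("igraph")
  for (seed in 56:70) {
    net <- simulate_bmkn(n_ontologies = 2, concepts_per_ontology = 15,
                         extra_intra_rate = 0.08, inter_rate = 0,
                         seed = seed)
    a <- random_anchor(net, seed)
    s <- unname(concept_ontology(net, a))
    other <- setdiff(net$ontologies, s)
    for (i in 0:4) {
      for (j in 0:3) {
        # O[0,0] is the 1-hop intra ball, so O[i,j] reaches depth j+1;
        # the inter branch has nothing to add at any i
        expect_equal(expand_set(net, a, i, j, s),
                     bfs_within(net, a, j + 1, "intra", s))
        for (t in other) {
          expect_equal(expand_set(net, a, i, j, t), character())
        }
      }
    }
  }
})

test_that("with no intra edges, growth comes from the inter branch alone", {
  skip_if_not_installed("igraph")
  for (seed in 71:80) {
    net <- simulate_bmkn(n_ontologies = 3, concepts_per_ontology = 10,
                         extra_intra_rate = 0, inter_rate = 0.08,
                         seed = seed)
    net$edges <- net$edges[edge_class(net) == "inter", , drop = FALSE]
    a <- random_anchor(net, seed)
    for (t in net$ontologies) {
      for (i in 0:4) {
        for (j in c(0L, i, 4L)) {
          # cells depend on i only: ontology-t concepts at the end of a
          # forward inter walk of length at most i + 1
          expect_equal(expand_set(net, a, i, j, t),
                       bfs_within(net, a, i + 1, "inter", t))
        }
      }
    }
  }
})

test_that("relatedness network collects the diagonal union with annotations", {
  rn <- relatedness_network(toy, "D0", steps = 2)
  expect_setequal(rn$nodes$id[rn$nodes$ontology == "D"],
                  c("D1", "D2", "D3", "D4", "D9", "D10", "D11", "D12"))
  expect_setequal(rn$nodes$id[rn$nodes$ontology == "S"], paste0("S", 1:5))
  # first-collection index of the initial sets is (0,0)
  d0 <- rn$nodes[rn$nodes$id %in% c("D1", "D2", "S1", "S2"), ]
  expect_true(all(d0$first_i == 0 & d0$first_j == 0))
  # D11 is only reachable through the symptom chain, collected at i = 2
  expect_equal(rn$nodes$first_i[rn$nodes$id == "D11"], 2)
  # steps = 0 keeps only the initial sets
  rn0 <- relatedness_network(toy, "D0", steps = 0)
  expect_setequal(rn0$nodes$id, c("D1", "D2", "S1", "S2"))
  # an isolated anchor gives an empty network
  iso <- add_concepts(toy, tibble::tibble(id = "D99", ontology = "D"))
  expect_equal(nrow(relatedness_network(iso, "D99", steps = 2)$nodes), 0)
})

test_that("the symptom-mediated misdiagnosis chain is an RN path", {
  rn <- relatedness_network(toy, "D0", steps = 2)
  key <- paste(rn$edges$source, rn$edges$target)
  expect_true(all(c("D0 S2", "S2 S3", "S3 D11") %in% key))
  expect_equal(rn$nodes$label[rn$nodes$id == "D11"], "Rheumatoid Arthritis")
})

test_that("tidy, glance and autoplot expose the RN result", {
  rn <- relatedness_network(toy, "D0", steps = 2)
  td <- tidy(rn)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("id", "label", "ontology", "first_i", "first_j"))
  gl <- glance(rn)
  expect_equal(gl$n_nodes, nrow(td))
  expect_equal(gl$anchor, "D0")
  expect_s3_class(ggplot2::autoplot(rn), "ggplot")
})

test_that("diagonal profile reports sizes and detects the fixpoint", {
  prof <- diagonal_profile(toy, "D0", 3)
  d1 <- prof$size[prof$step == 1 & prof$ontology == "D"]
  d2 <- prof$size[prof$step == 2 & prof$ontology == "D"]
  expect_equal(d1, 6)  # D1-D4, D9, D10
  expect_equal(d2, 8)  # adds D11, D12
  expect_equal(attr(prof, "fixpoint"), 3)

  # a pure intra chain a->b->c->d exhausts after enough steps
  chain <- bmkn("O") |>
    add_concepts(tibble::tibble(id = letters[1:4], ontology = "O")) |>
    add_edges(tibble::tibble(source = letters[1:3], target = letters[2:4],
                             rel = "is_a"))
  pc <- diagonal_profile(chain, "a", 4)
  expect_equal(max(pc$size), 3)
  expect_equal(attr(pc, "fixpoint"), 3)

  # an edgeless graph is at a fixpoint from the start
  iso <- bmkn("O") |> add_concepts(tibble::tibble(id = "x", ontology = "O"))
  expect_equal(attr(diagonal_profile(iso, "x", 2), "fixpoint"), 0)
})

test_that("a graph with no inter edges makes i irrelevant", {
  net <- simulate_bmkn(n_ontologies = 2, concepts_per_ontology = 12,
                       extra_intra_rate = 0.1, inter_rate = 0, seed = 7)
  a <- random_anchor(net, 7)
  s <- unname(concept_ontology(net, a))
  for (j in 0:3) {
    base <- expand_set(net, a, 0, j, s)
    for (i in 1:3) expect_equal(expand_set(net, a, i, j, s), base)
  }
})
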