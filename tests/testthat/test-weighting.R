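# five-document corpus small enough to weight by hand
toy_corpus <- function() {
  tibble::tibble(
    doc_id = paste0("d", 1:5),
    concepts = list(c("a", "b"), c("a", "b"), c("a", "c"),
                    c("b", "c", "d"), c("a", "b", "d")),
    impact_factor = c(2, 4, 6, 1, 3)
  )
}

test_that("co-occurrence counts each pair once per document", {
  counts <- cooccurrence_counts(tibble::tibble(
    doc_id = c("1", "2", "3"),
    concepts = list(c("a", "b"), c("a", "b"), c("a", "c")),
    impact_factor = c(0, 0, 0)
  ))
  expect_equal(counts$n[counts$u == "a" & counts$v == "b"], 2L)
  expect_equal(counts$n[counts$u == "a" & counts$v == "c"], 1L)
  # a single-concept document contributes no pairs
  one <- tibble::tibble(doc_id = "1", concepts = list("a"),
                        impact_factor = 1)
  expect_equal(nrow(cooccurrence_counts(one)), 0)
  expect_error(cooccurrence_counts(one[0, ]), "empty")
})

test_that("counts agree with a brute-force double loop on random corpora", {
  corpus <- simulate_corpus(50, paste0("c", 1:12), seed = 401)
  expect_equal(
    as.data.frame(cooccurrence_counts(corpus)),
    as.data.frame(brute_pair_counts(corpus))
  )
})

test_that("TF-IDF confidences match the hand-computed table", {
  conf <- tfidf_confidence(toy_corpus())
  key <- paste0(conf$u, conf$v)
  got <- stats::setNames(conf$confidence, key)
  # frozen from independent arithmetic: w(n) = n*(log(6/(n+1)) + 1) over
  # counts ab=3, bd=2, singles=1; normalised by w(3)
  expect_equal(got[["ab"]], 1)
  expect_equal(got[["bd"]], 0.8031254426, tolerance = 1e-9)
  for (k in c("ac", "ad", "bc", "cd")) {
    expect_equal(got[[k]], 0.4977266426, tolerance = 1e-9)
  }
  expect_true(all(conf$weight > 0))
})

test_that("TF-IDF normalisation and ties behave at the boundaries", {
  single <- tibble::tibble(doc_id = "1", concepts = list(c("a", "b")),
                           impact_factor = 1)
  expect_equal(tfidf_confidence(single)$confidence, 1)
  tied <- tibble::tibble(
    doc_id = c("1", "2"),
    concepts = list(c("a", "b"), c("c", "d")), impact_factor = c(1, 1)
  )
  expect_equal(tfidf_confidence(tied)$confidence, c(1, 1))
  expect_error(tfidf_confidence(toy_corpus(), min_count = 10), "min_count")
  # permutation invariance over document order
  sh <- toy_corpus()[c(4, 2, 5, 1, 3), ]
  expect_equal(tfidf_confidence(sh), tfidf_confidence(toy_corpus()))
})

test_that("significance is the max-normalised mean impact factor", {
  sig <- significance_scores(toy_corpus())
  got <- stats::setNames(sig$significance, paste0(sig$u, sig$v))
  expect_equal(got[["ab"]], 0.5)           # mean(2,4,3)/6
  expect_equal(got[["ac"]], 1)             # 6/6
  expect_equal(got[["bd"]], 1 / 3)         # mean(1,3)/6
  expect_equal(got[["bc"]], 1 / 6)
  # pair A in docs IF {2,4} vs pair B in one doc IF 6
  two <- tibble::tibble(
    doc_id = c("1", "2", "3"),
    concepts = list(c("a", "b"), c("a", "b"), c("c", "d")),
    impact_factor = c(2, 4, 6)
  )
  s2 <- significance_scores(two)
  g2 <- stats::setNames(s2$significance, paste0(s2$u, s2$v))
  expect_equal(g2[["ab"]], 0.5)
  expect_equal(g2[["cd"]], 1)
  # all equal impact factors give all significances 1
  eq <- toy_corpus()
  eq$impact_factor <- rep(2, 5)
  expect_true(all(significance_scores(eq)$significance == 1))
  zero <- toy_corpus()
  zero$impact_factor <- rep(0, 5)
  expect_error(significance_scores(zero), "undefined")
})

test_that("significance is invariant under impact-factor rescaling", {
  base <- significance_scores(toy_corpus())
  scaled <- toy_corpus()
  scaled$impact_factor <- scaled$impact_factor * 73.5
  expect_equal(significance_scores(scaled)$significance, base$significance)
})

test_that("weight maps lie in (0, 1] and attain 1", {
  for (seed in 402:406) {
    corpus <- simulate_corpus(60, paste0("c", 1:10), seed = seed)
    conf <- tfidf_confidence(corpus)
    expect_true(all(conf$confidence > 0 & conf$confidence <= 1))
    expect_equal(max(conf$confidence), 1)
    sig <- significance_scores(corpus)
    expect_true(all(sig$significance > 0 & sig$significance <= 1))
    expect_equal(max(sig$significance), 1)
  }
})

test_that("corpus extraction materialises cross-ontology pairs both ways", {
  net <- bmkn(c("DO", "SYMP")) |>
    add_concepts(tibble::tibble(id = c("d1", "d2", "s1"),
                                ontology = c("DO", "DO", "SYMP")))
  corpus <- tibble::tibble(
    doc_id = paste0("x", 1:3),
    concepts = list(c("d1", "s1"), c("d1", "s1"), c("d1", "s1", "d2")),
    impact_factor = c(1, 2, 3)
  )
  edges <- extract_cooccurrence_edges(corpus, net, rel = "has_symptom",
                                      min_count = 2)
  # d1-s1 (n=3) and d2-s1 (n=1, dropped); d1-d2 same-ontology, skipped
  expect_equal(nrow(edges), 2)
  expect_setequal(paste(edges$source, edges$target),
                  c("d1 s1", "s1 d1"))
  expect_equal(edges$confidence[1], edges$confidence[2])
  expect_error(
    extract_cooccurrence_edges(corpus, net, min_count = 5),
    "min_count"
  )
  bad <- corpus
  bad$concepts[[1]] <- c("d1", "ghost")
  expect_error(extract_cooccurrence_edges(bad, net), "ghost")
})

test_that("attach_weights updates matched pairs in both directions only", {
  net <- bmkn(c("DO", "SYMP")) |>
    add_concepts(tibble::tibble(id = c("d1", "d2", "s1"),
                                ontology = c("DO", "DO", "SYMP"))) |>
    add_edges(tibble::tribble(
      ~source, ~target, ~rel,
      "d1", "d2", "is_a",
      "d1", "s1", "has_symptom",
      "s1", "d1", "suggests"
    ))
  w <- tibble::tibble(u = "s1", v = "d1", confidence = 0.4,
                      significance = 0.7)
  out <- attach_weights(net, w)
  expect_equal(out$edges$confidence, c(1, 0.4, 0.4))
  expect_equal(out$edges$significance, c(1, 0.7, 0.7))
  # empty weights are the identity
  expect_equal(attach_weights(net, w[0, ]), net)
})
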