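# Independent oracles the engine is checked against. These deliberately
# avoid the package's expansion code path: plain recursion straight off the
# set identities, with no memoization and its own edge scans.

naive_cell <- function(net, anchor, i, j, t) {
  onts <- net$ontologies
  ont_of <- stats::setNames(net$concepts$ontology, net$concepts$id)
  e <- net$edges
  e_src_ont <- unname(ont_of[e$source])
  e_tgt_ont <- unname(ont_of[e$target])
  a_ont <- unname(ont_of[anchor])

  intra_of <- function(set, ont) {
    hit <- e$source %in% set & e_src_ont == ont & e_tgt_ont == ont
    unique(e$target[hit])
  }
  inter_into <- function(set, from, to) {
    hit <- e$source %in% set & e_src_ont == from & e_tgt_ont == to &
      e_src_ont != e_tgt_ont
    unique(e$target[hit])
  }
  rec <- function(i, j, t) {
    val <- if (i == 0 && j == 0) {
      if (t == a_ont) intra_of(anchor, t) else inter_into(anchor, a_ont, t)
    } else if (i == j) {
      union(rec(i - 1, j, t), rec(i, j - 1, t))
    } else if (i < j) {
      prev <- rec(i, j - 1, t)
      union(intra_of(prev, t), prev)
    } else {
      acc <- rec(i - 1, j, t)
      for (k in setdiff(onts, t)) {
        acc <- union(acc, inter_into(rec(i - 1, i - 1, k), k, t))
      }
      acc
    }
    sort(setdiff(val, anchor))
  }
  rec(i, j, t)
}

# forward reachability oracle over one edge class, via igraph BFS
bfs_within <- function(net, anchor, max_edges, class = c("intra", "inter"),
                       ontology = NULL) {
  class <- match.arg(class)
  cls <- edge_class(net)
  e <- net$edges[cls == class, c("source", "target"), drop = FALSE]
  ids <- net$concepts$id
  g <- igraph::graph_from_data_frame(e, vertices = ids, directed = TRUE)
  d <- igraph::distances(g, v = anchor, mode = "out")[1, ]
  reach <- names(d)[is.finite(d) & d >= 1 & d <= max_edges]
  if (!is.null(ontology)) {
    ont_of <- stats::setNames(net$concepts$ontology, net$concepts$id)
    reach <- reach[unname(ont_of[reach]) == ontology]
  }
  sort(reach)
}

# brute-force pair counting with an explicit double loop over documents
brute_pair_counts <- function(corpus) {
  acc <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(corpus))) {
    ids <- sort(unique(corpus$concepts[[r]]))
    if (length(ids) < 2) next
    for (a in seq_along(ids)) {
      for (b in seq_along(ids)) {
        if (a < b) {
          k <- paste(ids[a], ids[b], sep = "|")
          acc[[k]] <- (acc[[k]] %||% 0L) + 1L
        }
      }
    }
  }
  keys <- ls(acc)
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- tibble::tibble(
    u = vapply(parts, `[`, "", 1),
    v = vapply(parts, `[`, "", 2),
    n = vapply(keys, function(k) acc[[k]], integer(1), USE.NAMES = FALSE)
  )
  dplyr::arrange(out, u, v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
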