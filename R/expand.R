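#' @keywords internal
#' @noRd
new_expand_state <- function(net, anchor, mask = NULL) {
  stopifnot(inherits(net, "bmkn"))
  if (!is.character(anchor) || length(anchor) != 1L ||
      !anchor %in% net$concepts$id) {
    stop(sprintf("unknown anchor concept '%s'", anchor), call. = FALSE)
  }
  if (!is.null(mask) && !inherits(mask, "mask_set")) mask <- parse_mask(mask)
  e <- net$edges[edge_passes(mask, net$edges), , drop = FALSE]
  ont <- stats::setNames(net$concepts$ontology, net$concepts$id)
  src_ont <- unname(ont[e$source])
  tgt_ont <- unname(ont[e$target])
  list(
    anchor = anchor,
    anchor_ont = unname(ont[anchor]),
    onts = net$ontologies,
    src = e$source, tgt = e$target,
    src_ont = src_ont, tgt_ont = tgt_ont,
    intra = src_ont == tgt_ont,
    cache = new.env(parent = emptyenv())
  )
}

# forward intra-neighbours of `set` inside ontology `t`, anchor excluded
st_intra <- function(state, set, t) {
  hit <- state$intra & state$src_ont == t & (state$src %in% set)
  setdiff(unique(state$tgt[hit]), state$anchor)
}

# forward inter-neighbours of `set` (ontology k) landing in ontology `t`
st_inter <- function(state, set, k, t) {
  hit <- !state$intra & state$src_ont == k & state$tgt_ont == t &
    (state$src %in% set)
  setdiff(unique(state$tgt[hit]), state$anchor)
}

# the recursive cell computation; memoized, anchor always excluded
st_cell <- function(state, i, j, t) {
  if (i < 0 || j < 0) stop("expansion indices must be non-negative",
                           call. = FALSE)
  key <- paste(i, j, t, sep = "|")
  if (!is.null(state$cache[[key]])) return(state$cache[[key]])
  val <- if (i == 0L && j == 0L) {
    if (t == state$anchor_ont) {
      st_intra(state, state$anchor, t)
    } else {
      st_inter(state, state$anchor, state$anchor_ont, t)
    }
  } else if (i == j) {
    union(st_cell(state, i - 1L, j, t), st_cell(state, i, j - 1L, t))
  } else if (i < j) {
    prev <- st_cell(state, i, j - 1L, t)
    union(st_intra(state, prev, t), prev)
  } else {
    acc <- st_cell(state, i - 1L, j, t)
    for (k in setdiff(state$onts, t)) {
      acc <- union(acc, st_inter(state, st_cell(state, i - 1L, i - 1L, k),
                                 k, t))
    }
    acc
  }
  val <- sort(setdiff(val, state$anchor))
  state$cache[[key]] <- val
  val
}

#' Initial related-concept sets around an anchor
#'
#' Expansion starts from the concepts explicitly linked to the anchor: for
#' the anchor's own ontology the forward intra-neighbours, and for every
#' other registered ontology the forward inter-neighbours landing there.
#' The anchor itself is never a member of any set.
#'
#' @param net A [bmkn()] object.
#' @param anchor Concept id of the anchor.
#' @param mask Optional mask set from [parse_mask()].
#' @return Named list, one sorted character vector per registered ontology.
#' @export
initial_sets <- function(net, anchor, mask = NULL) {
  state <- new_expand_state(net, anchor, mask)
  out <- lapply(state$onts, function(t) st_cell(state, 0L, 0L, t))
  stats::setNames(out, state$onts)
}

#' One indexed cell of the set-theoretic expansion
#'
#' `expand_set(net, anchor, i, j, t)` computes the concept set of ontology
#' `t` collected after `j` intra-relationship expansion steps and `i`
#' inter-relationship expansion steps from the anchor. The three-branch
#' recursion is, with `O[i,j,t]` denoting the cell:
#'
#' * `i = j`: `O[i-1, j, t] ∪ O[i, j-1, t]`
#' * `i < j`: `intra(O[i, j-1, t]) ∪ O[i, j-1, t]`
#' * `i > j`: `⋃_{k ≠ t} inter_t(O[i-1, i-1, k]) ∪ O[i-1, j, t]`
#'
#' grounded at the initial sets of [initial_sets()]. `intra()` and
#' `inter_t()` are the forward neighbour operators; they do not union their
#' input — the recursion adds the previous cell explicitly. Cells are pure
#' functions of `(i, j, t)` and are memoized per call.
#'
#' @inheritParams initial_sets
#' @param i,j Non-negative expansion indices (inter and intra step counts).
#' @param ontology Ontology id of the cell.
#' @return Sorted character vector of concept ids; never contains the anchor.
#' @examples
#' net <- toy_disease_symptom_network()
#' expand_set(net, "D0", 1, 1, "D")  # D1 D2 D3 D4 D9 D10
#' @export
expand_set <- function(net, anchor, i, j, ontology, mask = NULL) {
  stopifnot(i >= 0, j >= 0)
  state <- new_expand_state(net, anchor, mask)
  if (!ontology %in% state$onts) {
    stop(sprintf("unknown ontology '%s'", ontology), call. = FALSE)
  }
  st_cell(state, as.integer(i), as.integer(j), ontology)
}

#' Interesting set reachable only through inter-relationships
#'
#' The pruning rule `F(i)` removes, from the full `i`-step expansion, every
#' concept that intra-relationship expansion alone would reach:
#' `F(i) = O[i, i, t] - O[0, i, t]`. What remains are concepts of ontology
#' `t` related to the anchor only via paths that cross ontologies — the
#' candidates for implicit relatedness (e.g. possible misdiagnoses sharing
#' symptoms, or diseases sharing gene product properties).
#'
#' @inheritParams expand_set
#' @return Sorted character vector of concept ids.
#' @examples
#' net <- toy_disease_symptom_network()
#' interesting_set(net, "D0", 2, "D")  # D9 D10 D11 D12
#' @export
interesting_set <- function(net, anchor, i, ontology, mask = NULL) {
  stopifnot(i >= 0)
  state <- new_expand_state(net, anchor, mask)
  if (!ontology %in% state$onts) {
    stop(sprintf("unknown ontology '%s'", ontology), call. = FALSE)
  }
  i <- as.integer(i)
  sort(setdiff(st_cell(state, i, i, ontology),
               st_cell(state, 0L, i, ontology)))
}

#' Compute the relatedness network around an anchor concept
#'
#' Runs the expansion to the diagonal cell `O[steps, steps, t]` in every
#' registered ontology and assembles the induced subgraph: all collected
#' concepts (annotated with the smallest index pair at which each was first
#' collected) plus every mask-passing edge among them. The anchor is not a
#' node of the result, but edges incident to it are retained so that paths
#' from the anchor into the network stay traceable.
#'
#' @inheritParams initial_sets
#' @param steps Number of expansion steps (the shared diagonal index).
#' @return A `relatedness_network` object: list with `anchor`, `steps`,
#'   `nodes` (tibble `id`, `label`, `ontology`, `first_i`, `first_j`) and
#'   `edges` (tibble `source`, `target`, `rel`, `confidence`,
#'   `significance`, `class`). Use [generics::tidy()], [generics::glance()]
#'   or [ggplot2::autoplot()] on it.
#' @examples
#' net <- toy_disease_symptom_network()
#' rn <- relatedness_network(net, "D0", steps = 2)
#' glance(rn)
#' @export
relatedness_network <- function(net, anchor, steps = 2, mask = NULL) {
  stopifnot(steps >= 0)
  if (!is.null(mask) && !inherits(mask, "mask_set")) mask <- parse_mask(mask)
  state <- new_expand_state(net, anchor, mask)
  steps <- as.integer(steps)

  # first-collection annotation: scan cells in increasing (i + j), then i
  idx <- expand.grid(i = 0:steps, j = 0:steps)
  idx <- idx[order(idx$i + idx$j, idx$i), , drop = FALSE]
  first <- list()
  for (r in seq_len(nrow(idx))) {
    for (t in state$onts) {
      for (id in st_cell(state, idx$i[r], idx$j[r], t)) {
        if (is.null(first[[id]])) first[[id]] <- c(idx$i[r], idx$j[r])
      }
    }
  }
  collected <- sort(names(first))
  nodes <- net$concepts[match(collected, net$concepts$id), , drop = FALSE]
  nodes$first_i <- unname(vapply(first[collected], `[`, numeric(1), 1))
  nodes$first_j <- unname(vapply(first[collected], `[`, numeric(1), 2))
  nodes <- tibble::as_tibble(nodes)

  keep_ids <- c(collected, anchor)
  e <- net$edges[edge_passes(mask, net$edges), , drop = FALSE]
  e <- e[e$source %in% keep_ids & e$target %in% keep_ids, , drop = FALSE]
  e$class <- edge_class(net, e)
  e <- dplyr::arrange(e, .data$source, .data$target, .data$rel)

  structure(
    list(anchor = anchor, anchor_ontology = state$anchor_ont,
         steps = steps, nodes = nodes, edges = tibble::as_tibble(e)),
    class = "relatedness_network"
  )
}

#' @export
print.relatedness_network <- function(x, ...) {
  cat(sprintf(
    "<relatedness_network> anchor '%s' (%s), %d steps: %d concepts, %d edges\n",
    x$anchor, x$anchor_ontology, x$steps, nrow(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Diagonal growth profile of an expansion
#'
#' Computes the diagonal cells `O[s, s, t]` for `s = 0 .. max_steps` and
#' reports their sizes, which are nondecreasing in `s`. The profile helps
#' choose a step count: expansion has converged at the first step where no
#' ontology's set grows.
#'
#' @inheritParams initial_sets
#' @param max_steps Largest diagonal index to evaluate.
#' @return Tibble with columns `step`, `ontology`, `size` and list-column
#'   `ids`; attribute `fixpoint` holds the first step at which no set grew
#'   (`NA` if growth continues through `max_steps`).
#' @export
diagonal_profile <- function(net, anchor, max_steps, mask = NULL) {
  stopifnot(max_steps >= 0)
  state <- new_expand_state(net, anchor, mask)
  rows <- list()
  fixpoint <- NA_integer_
  prev_total <- -1L
  for (s in 0:max_steps) {
    sets <- lapply(state$onts, function(t) st_cell(state, s, s, t))
    total <- sum(lengths(sets))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      step = s, ontology = state$onts, size = lengths(sets), ids = sets
    )
    if (is.na(fixpoint) && s == 0L && total == 0L) fixpoint <- 0L
    if (is.na(fixpoint) && total == prev_total) fixpoint <- s
    prev_total <- total
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fixpoint") <- fixpoint
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a relatedness network into its node table
#'
#' @param x A `relatedness_network`.
#' @param ... Unused.
#' @return Tibble of collected concepts with ontology and first-collection
#'   indices.
#' @export
tidy.relatedness_network <- function(x, ...) x$nodes

#' One-row summary of a relatedness network
#'
#' @param x A `relatedness_network`.
#' @param ... Unused.
#' @export
glance.relatedness_network <- function(x, ...) {
  tibble::tibble(
    anchor = x$anchor,
    anchor_ontology = x$anchor_ontology,
    steps = x$steps,
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_intra_edges = sum(x$edges$class == "intra"),
    n_inter_edges = sum(x$edges$class == "inter")
  )
}

#' Plot a relatedness network
#'
#' Draws collected concepts (plus the anchor, marked distinctly) with edges
#' coloured by intra/inter class. Layout uses igraph when available and a
#' deterministic circular layout otherwise.
#'
#' @param object A `relatedness_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.relatedness_network <- function(object, ...) {
  ids <- c(object$anchor, object$nodes$id)
  if (requireNamespace("igraph", quietly = TRUE) && nrow(object$edges) > 0) {
    g <- igraph::graph_from_data_frame(
      object$edges[, c("source", "target")], vertices = ids
    )
    set.seed(1L)
    xy <- igraph::layout_with_fr(g)
  } else {
    th <- seq(0, 2 * pi, length.out = length(ids) + 1L)[seq_along(ids)]
    xy <- cbind(cos(th), sin(th))
  }
  lay <- tibble::tibble(
    id = ids, x = xy[, 1], y = xy[, 2],
    role = c("anchor", rep("collected", nrow(object$nodes))),
    ontology = c(object$anchor_ontology, object$nodes$ontology)
  )
  seg <- dplyr::left_join(object$edges, lay[, c("id", "x", "y")],
                          by = c(source = "id")) |>
    dplyr::left_join(lay[, c("id", "x", "y")], by = c(target = "id"),
                     suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$class),
      colour = "grey50"
    ) +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$ontology,
                   shape = .data$role),
      size = 3
    ) +
    ggplot2::geom_text(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
      vjust = -1, size = 3
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(
      title = sprintf("Relatedness network around '%s' (%d steps)",
                      object$anchor, object$steps)
    )
}

#' @export
plot.relatedness_network <- function(x, ...) print(autoplot(x, ...))
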