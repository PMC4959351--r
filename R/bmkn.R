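#' Create an empty biomedical knowledge network
#'
#' A biomedical knowledge network (BMKN) is a directed graph
#' `G = (V, E, C, S)` whose nodes are concepts drawn from one or more
#' ontologies and whose edges carry a relation type, a confidence weight
#' `C(e)` and a significance weight `S(e)`, both in `[0, 1]`. Every concept
#' belongs to exactly one registered ontology; an edge is *intra* when both
#' endpoints share an ontology and *inter* otherwise.
#'
#' The object is a light S3 wrapper around two tibbles so that it composes
#' with dplyr verbs: `$concepts` with columns `id`, `label`, `ontology`, and
#' `$edges` with columns `source`, `target`, `rel`, `confidence`,
#' `significance`.
#'
#' @param ontologies Character vector of ontology identifiers to register
#'   immediately (e.g. `c("DO", "SYMP")`).
#' @return A `bmkn` object.
#' @examples
#' net <- bmkn(c("DO", "SYMP")) |>
#'   add_concepts(data.frame(
#'     id = c("lupus", "joint_pain"),
#'     ontology = c("DO", "SYMP")
#'   )) |>
#'   add_edges(data.frame(
#'     source = "lupus", target = "joint_pain", rel = "has_symptom"
#'   ))
#' edge_class(net)
#' @export
bmkn <- function(ontologies = character()) {
  net <- structure(
    list(
      ontologies = character(),
      concepts = tibble::tibble(
        id = character(), label = character(), ontology = character()
      ),
      edges = tibble::tibble(
        source = character(), target = character(), rel = character(),
        confidence = double(), significance = double()
      )
    ),
    class = "bmkn"
  )
  for (o in ontologies) net <- add_ontology(net, o)
  net
}

#' @export
print.bmkn <- function(x, ...) {
  cls <- edge_class(x)
  cat(sprintf(
    "<bmkn> %d ontologies (%s), %d concepts, %d edges (%d intra, %d inter)\n",
    length(x$ontologies), paste(x$ontologies, collapse = ", "),
    nrow(x$concepts), nrow(x$edges),
    sum(cls == "intra"), sum(cls == "inter")
  ))
  invisible(x)
}

#' Register an ontology in a knowledge network
#'
#' @param net A [bmkn()] object.
#' @param id Single non-empty ontology identifier, unique within the network.
#' @return The updated network.
#' @export
add_ontology <- function(net, id) {
  stopifnot(inherits(net, "bmkn"))
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("ontology id must be a single non-empty string", call. = FALSE)
  }
  if (id %in% net$ontologies) {
    stop(sprintf("ontology '%s' is already registered", id), call. = FALSE)
  }
  net$ontologies <- c(net$ontologies, id)
  net
}

#' Add concepts to a knowledge network
#'
#' @param net A [bmkn()] object.
#' @param concepts Data frame with columns `id` and `ontology`, optionally
#'   `label` (defaults to the id). Each concept's ontology must already be
#'   registered and its id must be new.
#' @return The updated network.
#' @export
add_concepts <- function(net, concepts) {
  stopifnot(inherits(net, "bmkn"), is.data.frame(concepts))
  req <- c("id", "ontology")
  if (!all(req %in% names(concepts))) {
    stop("`concepts` needs columns id, ontology", call. = FALSE)
  }
  concepts <- tibble::as_tibble(concepts)
  if (!"label" %in% names(concepts)) concepts$label <- concepts$id
  concepts <- dplyr::select(concepts, "id", "label", "ontology")
  concepts$id <- as.character(concepts$id)
  concepts$label <- as.character(concepts$label)
  concepts$ontology <- as.character(concepts$ontology)
  if (anyNA(concepts$id) || any(!nzchar(concepts$id))) {
    stop("concept ids must be non-empty strings", call. = FALSE)
  }
  bad_ont <- setdiff(unique(concepts$ontology), net$ontologies)
  if (length(bad_ont)) {
    stop(sprintf("unregistered ontology: %s", paste(bad_ont, collapse = ", ")),
         call. = FALSE)
  }
  all_ids <- c(net$concepts$id, concepts$id)
  if (anyDuplicated(all_ids)) {
    dup <- unique(all_ids[duplicated(all_ids)])
    stop(sprintf("duplicate concept id: %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  net$concepts <- dplyr::bind_rows(net$concepts, concepts)
  net
}

#' Add typed weighted edges to a knowledge network
#'
#' Edges are directed; traversal in the inference engine is strictly
#' forward. Missing `confidence`/`significance` columns default to 1.0, the
#' convention for edges taken from structured sources such as ontologies.
#' Parallel edges between the same pair are allowed when their relation
#' types differ; exact `(source, target, rel)` duplicates are rejected.
#'
#' @param net A [bmkn()] object.
#' @param edges Data frame with columns `source`, `target`, `rel` and
#'   optionally `confidence` and `significance` (each in `[0, 1]`).
#' @return The updated network.
#' @export
add_edges <- function(net, edges) {
  stopifnot(inherits(net, "bmkn"), is.data.frame(edges))
  req <- c("source", "target", "rel")
  if (!all(req %in% names(edges))) {
    stop("`edges` needs columns source, target, rel", call. = FALSE)
  }
  edges <- tibble::as_tibble(edges)
  if (!"confidence" %in% names(edges)) edges$confidence <- 1
  if (!"significance" %in% names(edges)) edges$significance <- 1
  edges$confidence[is.na(edges$confidence)] <- 1
  edges$significance[is.na(edges$significance)] <- 1
  edges <- dplyr::select(edges, "source", "target", "rel",
                         "confidence", "significance")
  for (col in c("source", "target", "rel")) {
    edges[[col]] <- as.character(edges[[col]])
  }
  known <- net$concepts$id
  missing <- setdiff(c(edges$source, edges$target), known)
  if (length(missing)) {
    stop(sprintf("edge endpoint not in network: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(edges$source == edges$target)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  w <- c(edges$confidence, edges$significance)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    stop("confidence and significance must lie in [0, 1]", call. = FALSE)
  }
  key <- paste(edges$source, edges$target, edges$rel, sep = "\r")
  old_key <- paste(net$edges$source, net$edges$target, net$edges$rel,
                   sep = "\r")
  if (anyDuplicated(c(old_key, key))) {
    stop("duplicate (source, target, rel) edge", call. = FALSE)
  }
  net$edges <- dplyr::bind_rows(net$edges, edges)
  net
}

#' Ontology membership of concepts
#'
#' @param net A [bmkn()] object.
#' @param ids Concept ids; all must exist.
#' @return Character vector of ontology ids, named by concept id.
#' @export
concept_ontology <- function(net, ids) {
  stopifnot(inherits(net, "bmkn"))
  idx <- match(ids, net$concepts$id)
  if (anyNA(idx)) {
    stop(sprintf("unknown concept id: %s",
                 paste(ids[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  stats::setNames(net$concepts$ontology[idx], ids)
}

#' Classify edges as intra- or inter-ontology
#'
#' An edge is `"intra"` when source and target belong to the same ontology
#' and `"inter"` otherwise.
#'
#' @param net A [bmkn()] object.
#' @param edges Data frame of edges (default: all edges of `net`).
#' @return Character vector, one of `"intra"`/`"inter"` per edge row.
#' @export
edge_class <- function(net, edges = net$edges) {
  if (nrow(edges) == 0L) return(character())
  src <- concept_ontology(net, edges$source)
  tgt <- concept_ontology(net, edges$target)
  ifelse(unname(src) == unname(tgt), "intra", "inter")
}

#' Forward neighbours of a set of concepts
#'
#' Returns the targets of stored directed edges leaving `nodes`, optionally
#' restricted to intra or inter edges, to a target ontology, and to edges
#' passing a link mask. Traversal never follows an edge backwards.
#'
#' @param net A [bmkn()] object.
#' @param nodes Character vector of concept ids (all must exist).
#' @param class `"any"`, `"intra"` or `"inter"`.
#' @param target_ontology Optional ontology id the neighbours must belong to.
#' @param mask Optional mask set from [parse_mask()].
#' @return Sorted character vector of neighbour ids (a set).
#' @export
neighbors_out <- function(net, nodes, class = c("any", "intra", "inter"),
                          target_ontology = NULL, mask = NULL) {
  class <- match.arg(class)
  concept_ontology(net, nodes)  # validates existence
  e <- net$edges
  keep <- e$source %in% nodes
  if (class != "any") keep <- keep & (edge_class(net) == class)
  if (!is.null(mask)) keep <- keep & edge_passes(mask, e)
  out <- unique(e$target[keep])
  if (!is.null(target_ontology)) {
    out <- out[unname(concept_ontology(net, out)) == target_ontology]
  }
  sort(out)
}

#' Check the structural invariants of a knowledge network
#'
#' Reports, rather than throws: every violated invariant (dangling edge
#' endpoint, unregistered concept ontology, out-of-range weight, duplicate
#' concept id or edge triple, self-loop) yields one row.
#'
#' @param net A [bmkn()] object.
#' @return Tibble with columns `kind`, `id`, `message`; zero rows when the
#'   network is valid.
#' @export
validate_bmkn <- function(net) {
  stopifnot(inherits(net, "bmkn"))
  v <- list()
  bad <- function(kind, id, message) {
    tibble::tibble(kind = kind, id = id, message = message)
  }
  dup_c <- unique(net$concepts$id[duplicated(net$concepts$id)])
  for (id in dup_c) v <- c(v, list(bad("concept", id, "duplicate concept id")))
  unreg <- net$concepts[!net$concepts$ontology %in% net$ontologies, ]
  for (i in seq_len(nrow(unreg))) {
    v <- c(v, list(bad("concept", unreg$id[i],
                       sprintf("ontology '%s' not registered",
                               unreg$ontology[i]))))
  }
  e <- net$edges
  known <- net$concepts$id
  dangling <- !(e$source %in% known) | !(e$target %in% known)
  for (i in which(dangling)) {
    v <- c(v, list(bad("edge", paste(e$source[i], e$target[i], sep = "->"),
                       "endpoint missing from concept table")))
  }
  badw <- !is.finite(e$confidence) | e$confidence < 0 | e$confidence > 1 |
    !is.finite(e$significance) | e$significance < 0 | e$significance > 1
  for (i in which(badw)) {
    v <- c(v, list(bad("edge", paste(e$source[i], e$target[i], sep = "->"),
                       "confidence/significance outside [0, 1]")))
  }
  for (i in which(e$source == e$target)) {
    v <- c(v, list(bad("edge", e$source[i], "self-loop")))
  }
  key <- paste(e$source, e$target, e$rel, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    v <- c(v, list(bad("edge", gsub("\r", "->", k),
                       "duplicate (source, target, rel)")))
  }
  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(kind = character(), id = character(), message = character())
}
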