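#' Read an OBO flat file
#'
#' A minimal reader for the OBO 1.2/1.4 dialect used by disease, symptom
#' and gene ontologies: only `[Term]` stanzas are honoured, with tags
#' `id`, `name`, `is_a`, `relationship` and `is_obsolete`; obsolete terms
#' are skipped, everything else is ignored. Each `is_a: PARENT` line
#' yields a directed edge `term -> parent` typed `is_a`; each
#' `relationship: TYPE TARGET` line an edge typed `TYPE`. An inverse map
#' can additionally materialise the opposite direction under its own
#' relation name (hierarchies are often stored in both the
#' parent-to-child and child-to-parent directions as distinct types).
#'
#' @param path Path to an OBO file.
#' @param ontology_id Ontology identifier for the parsed concepts; default
#'   is the `ontology:` header tag, falling back to the file base name.
#' @param inverse_map Optional named character vector mapping a relation
#'   type to the name under which its reversed edges are also emitted,
#'   e.g. `c(is_a = "father_to_son")`.
#' @return List with `ontology` (id), `concepts` (tibble `id`, `label`)
#'   and `edges` (tibble `source`, `target`, `rel`), edges restricted to
#'   parsed terms.
#' @export
read_obo <- function(path, ontology_id = NULL, inverse_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  header_ont <- sub("^ontology:\\s*", "",
                    grep("^ontology:", lines, value = TRUE)[1])
  if (is.null(ontology_id)) {
    ontology_id <- if (!is.na(header_ont) && length(header_ont)) header_ont
      else sub("\\.[^.]*$", "", basename(path))
  }
  stanza_starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", trimws(lines))
  concepts <- list(); edges <- list()
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):end]
    tagval <- function(tag) {
      v <- sub(paste0("^", tag, ":\\s*"), "",
               grep(paste0("^", tag, ":"), block, value = TRUE))
      sub("\\s*!.*$", "", v)  # strip trailing comments
    }
    id <- tagval("id")
    if (length(id) == 0L) stop("[Term] stanza without id", call. = FALSE)
    if (length(id) > 1L) stop("multiple ids in one stanza", call. = FALSE)
    if (any(grepl("true", tagval("is_obsolete")))) next
    name <- tagval("name")
    concepts[[length(concepts) + 1L]] <- tibble::tibble(
      id = id, label = if (length(name)) name[1] else id
    )
    for (p in tagval("is_a")) {
      edges[[length(edges) + 1L]] <- tibble::tibble(
        source = id, target = trimws(p), rel = "is_a"
      )
    }
    for (r in tagval("relationship")) {
      f <- strsplit(trimws(r), "\\s+")[[1]]
      if (length(f) < 2L) stop(sprintf("malformed relationship line '%s'", r),
                               call. = FALSE)
      edges[[length(edges) + 1L]] <- tibble::tibble(
        source = id, target = f[2], rel = f[1]
      )
    }
  }
  concepts <- if (length(concepts)) dplyr::bind_rows(concepts) else
    tibble::tibble(id = character(), label = character())
  if (anyDuplicated(concepts$id)) {
    stop(sprintf("duplicate term id: %s",
                 paste(unique(concepts$id[duplicated(concepts$id)]),
                       collapse = ", ")), call. = FALSE)
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(source = character(), target = character(),
                   rel = character())
  # drop edges pointing outside the parsed (non-obsolete) term set
  edges <- edges[edges$source %in% concepts$id &
                   edges$target %in% concepts$id, , drop = FALSE]
  if (!is.null(inverse_map) && nrow(edges)) {
    inv <- edges[edges$rel %in% names(inverse_map), , drop = FALSE]
    if (nrow(inv)) {
      inv <- tibble::tibble(source = inv$target, target = inv$source,
                            rel = unname(inverse_map[inv$rel]))
      edges <- dplyr::bind_rows(edges, inv)
    }
  }
  list(ontology = ontology_id, concepts = concepts,
       edges = dplyr::distinct(edges))
}

#' Read a TSV edge table
#'
#' Expects 3 to 5 tab-separated columns: source id, target id, relation
#' type, and optionally confidence and significance. A header row naming
#' the first column `source` is recognised and skipped. Missing weights
#' take the supplied defaults.
#'
#' @param path Path to the TSV file.
#' @param default_confidence,default_significance Values filled in for
#'   absent weight columns or empty cells.
#' @return Tibble with columns `source`, `target`, `rel`, `confidence`,
#'   `significance`.
#' @export
read_edge_table <- function(path, default_confidence = 1,
                            default_significance = 1) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^source\t", lines[1])) lines <- lines[-1]
  if (!length(lines)) {
    return(tibble::tibble(source = character(), target = character(),
                          rel = character(), confidence = double(),
                          significance = double()))
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L || length(f) > 5L) {
      stop(sprintf("row %d: expected 3-5 columns, got %d", i, length(f)),
           call. = FALSE)
    }
    num <- function(x, default) {
      if (is.na(x) || !nzchar(x)) return(default)
      v <- suppressWarnings(as.numeric(x))
      if (is.na(v)) stop(sprintf("row %d: bad number '%s'", i, x),
                         call. = FALSE)
      v
    }
    tibble::tibble(
      source = f[1], target = f[2], rel = f[3],
      confidence = num(if (length(f) >= 4) f[4] else NA_character_,
                       default_confidence),
      significance = num(if (length(f) >= 5) f[5] else NA_character_,
                         default_significance)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write an edge table as TSV
#'
#' @param edges Edge data frame (`source`, `target`, `rel`, optional
#'   weights).
#' @param path Output path.
#' @return `path`, invisibly. Rows are written sorted for diffability.
#' @export
write_edge_table <- function(edges, path) {
  cols <- intersect(c("source", "target", "rel", "confidence",
                      "significance"), names(edges))
  out <- dplyr::arrange(edges[, cols, drop = FALSE],
                        dplyr::across(dplyr::all_of(cols)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Export a relatedness network
#'
#' JSON export carries the anchor, the annotated node table and the edge
#' table and round-trips through [read_rn()]; TSV export writes the edge
#' list only. Records are sorted, so two exports of the same network are
#' byte-identical.
#'
#' @param rn A `relatedness_network` from [relatedness_network()].
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_rn <- function(rn, path, format = c("json", "tsv")) {
  stopifnot(inherits(rn, "relatedness_network"))
  format <- match.arg(format)
  nodes <- dplyr::arrange(rn$nodes, .data$id)
  edges <- dplyr::arrange(rn$edges, .data$source, .data$target, .data$rel)
  if (format == "json") {
    obj <- list(
      anchor = rn$anchor, anchor_ontology = rn$anchor_ontology,
      steps = rn$steps, nodes = nodes, edges = edges
    )
    jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    readr::write_tsv(edges, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a relatedness network from its JSON export
#'
#' @param path Path written by [write_rn()] with `format = "json"`.
#' @return A `relatedness_network` object equal to the exported one.
#' @export
read_rn <- function(path) {
  obj <- jsonlite::fromJSON(path)
  as_chr <- function(x) if (length(x)) as.character(x) else character()
  nodes <- tibble::tibble(
    id = as_chr(obj$nodes$id), label = as_chr(obj$nodes$label),
    ontology = as_chr(obj$nodes$ontology),
    first_i = as.numeric(obj$nodes$first_i %||% numeric()),
    first_j = as.numeric(obj$nodes$first_j %||% numeric())
  )
  edges <- tibble::tibble(
    source = as_chr(obj$edges$source), target = as_chr(obj$edges$target),
    rel = as_chr(obj$edges$rel),
    confidence = as.numeric(obj$edges$confidence %||% numeric()),
    significance = as.numeric(obj$edges$significance %||% numeric()),
    class = as_chr(obj$edges$class)
  )
  structure(
    list(anchor = obj$anchor, anchor_ontology = obj$anchor_ontology,
         steps = as.integer(obj$steps), nodes = nodes, edges = edges),
    class = "relatedness_network"
  )
}

#' Serialize a knowledge network to JSON
#'
#' Ontology registry, concept table and edge table, with records sorted so
#' identical networks serialize to identical bytes. [read_bmkn()] inverts.
#'
#' @param net A [bmkn()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bmkn <- function(net, path) {
  stopifnot(inherits(net, "bmkn"))
  obj <- list(
    ontologies = sort(net$ontologies),
    concepts = dplyr::arrange(net$concepts, .data$id),
    edges = dplyr::arrange(net$edges, .data$source, .data$target, .data$rel)
  )
  jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read a knowledge network from its JSON serialization
#'
#' @param path Path written by [write_bmkn()].
#' @return A [bmkn()] object.
#' @export
read_bmkn <- function(path) {
  obj <- jsonlite::fromJSON(path)
  net <- bmkn(as.character(obj$ontologies))
  cc <- tibble::as_tibble(obj$concepts)
  if (nrow(cc)) net <- add_concepts(net, cc)
  ee <- tibble::as_tibble(obj$edges)
  if (nrow(ee)) net <- add_edges(net, ee)
  net
}

#' Assemble a knowledge network from a configuration
#'
#' The configuration (a YAML file or an equivalent list) names the inputs
#' of the construction pipeline: OBO ontologies supplying concepts and
#' intra edges, TSV edge tables supplying typed inter edges, and
#' optionally a JSONL corpus whose co-occurrence statistics either create
#' new inter edges or re-weight existing ones.
#'
#' ```yaml
#' ontologies:
#'   - path: do.obo
#'     id: DO
#'     inverse_map: {is_a: father_to_son}
#'   - path: symp.obo
#' edge_tables:
#'   - path: has_symptom.tsv
#' corpus:
#'   path: corpus.jsonl
#'   rel: cooccurs_with      # create edges; omit to only re-weight
#'   min_count: 1
#' ```
#'
#' @param config Path to a YAML file, or a list with the same shape.
#' @return A validated [bmkn()] object.
#' @export
load_bmkn <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), length(config$ontologies) >= 1)
  net <- bmkn()
  for (oc in config$ontologies) {
    inv <- if (!is.null(oc$inverse_map)) unlist(oc$inverse_map)
    ob <- read_obo(oc$path, ontology_id = oc$id, inverse_map = inv)
    net <- add_ontology(net, ob$ontology)
    if (nrow(ob$concepts)) {
      ob$concepts$ontology <- ob$ontology
      net <- add_concepts(net, ob$concepts)
    }
    if (nrow(ob$edges)) net <- add_edges(net, ob$edges)
  }
  for (et in config$edge_tables %||% list()) {
    rows <- read_edge_table(
      et$path,
      default_confidence = et$default_confidence %||% 1,
      default_significance = et$default_significance %||% 1
    )
    missing <- setdiff(c(rows$source, rows$target), net$concepts$id)
    if (length(missing)) {
      stop(sprintf("edge table '%s' references unknown concept: %s",
                   et$path, paste(missing, collapse = ", ")), call. = FALSE)
    }
    if (nrow(rows)) net <- add_edges(net, rows)
  }
  if (!is.null(config$corpus)) {
    cc <- config$corpus
    corpus <- read_corpus(cc$path)
    if (!is.null(cc$rel)) {
      new_edges <- extract_cooccurrence_edges(
        corpus, net, rel = cc$rel, min_count = cc$min_count %||% 1
      )
      key <- paste(new_edges$source, new_edges$target, new_edges$rel)
      old <- paste(net$edges$source, net$edges$target, net$edges$rel)
      new_edges <- new_edges[!key %in% old, , drop = FALSE]
      if (nrow(new_edges)) net <- add_edges(net, new_edges)
    } else {
      conf <- tfidf_confidence(corpus, min_count = cc$min_count %||% 1)
      sig <- tryCatch(significance_scores(corpus), error = function(e) NULL)
      w <- conf[, c("u", "v", "confidence")]
      w$significance <- if (is.null(sig)) 1 else
        sig$significance[match(paste(w$u, w$v), paste(sig$u, sig$v))]
      net <- attach_weights(net, w)
    }
  }
  issues <- validate_bmkn(net)
  if (nrow(issues)) {
    stop(sprintf("assembled network fails validation (%d issue(s)); first: %s",
                 nrow(issues), issues$message[1]), call. = FALSE)
  }
  net
}
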