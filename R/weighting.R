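#' Read an annotated corpus from JSONL
#'
#' One document per line with fields `doc_id`, `concepts` (array of concept
#' ids) and `impact_factor`. Documents are the evidence base for
#' corpus-derived edge weights: confidence comes from concept-pair
#' co-occurrence (TF-IDF) and significance from publication impact
#' factors.
#'
#' @param path Path to a JSONL file.
#' @return Tibble with columns `doc_id`, `concepts` (list of character),
#'   `impact_factor`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty corpus file", call. = FALSE)
  rows <- lapply(lines, function(l) {
    d <- jsonlite::fromJSON(l)
    if (is.null(d$doc_id) || is.null(d$concepts)) {
      stop("corpus line missing doc_id or concepts", call. = FALSE)
    }
    tibble::tibble(
      doc_id = as.character(d$doc_id),
      concepts = list(sort(unique(as.character(d$concepts)))),
      impact_factor = if (is.null(d$impact_factor)) 0 else
        as.numeric(d$impact_factor)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$impact_factor < 0)) {
    stop("impact factors must be non-negative", call. = FALSE)
  }
  out
}

# unordered pair table: one row per document per unordered concept pair
corpus_pairs <- function(corpus) {
  stopifnot(is.data.frame(corpus), all(c("concepts") %in% names(corpus)))
  if (nrow(corpus) == 0L) stop("empty corpus", call. = FALSE)
  rows <- lapply(seq_len(nrow(corpus)), function(r) {
    ids <- sort(unique(corpus$concepts[[r]]))
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(ids, 2)
    tibble::tibble(u = cmb[1, ], v = cmb[2, ], row = r)
  })
  dplyr::bind_rows(rows)
}

#' Concept-pair co-occurrence counts
#'
#' Counts, for every unordered concept pair, the number of documents in
#' which both concepts are annotated. A pair contributes at most once per
#' document, so the count equals the pair's document frequency.
#'
#' @param corpus Corpus tibble as from [read_corpus()] or
#'   [simulate_corpus()].
#' @return Tibble with columns `u`, `v` (with `u < v`) and `n`, sorted.
#' @export
cooccurrence_counts <- function(corpus) {
  p <- corpus_pairs(corpus)
  if (nrow(p) == 0L) {
    return(tibble::tibble(u = character(), v = character(), n = integer()))
  }
  p |>
    dplyr::count(.data$u, .data$v, name = "n") |>
    dplyr::arrange(.data$u, .data$v)
}

#' TF-IDF confidence weights for concept pairs
#'
#' For each pair co-occurring in at least `min_count` documents, the raw
#' weight is `n(u,v) * (log((N+1)/(df(u,v)+1)) + 1)` — term frequency is
#' the pair's co-occurrence count, the inverse document frequency uses
#' add-one smoothing plus a unit shift so every weight is strictly
#' positive (a pair present in every document still carries its count).
#' Weights are normalised by the corpus-wide maximum, so confidences lie
#' in `(0, 1]` and the strongest pair scores exactly 1.
#'
#' @inheritParams cooccurrence_counts
#' @param min_count Minimum co-occurrence count for a pair to be weighted.
#' @return Tibble with columns `u`, `v`, `n`, `df`, `weight`, `confidence`.
#' @export
tfidf_confidence <- function(corpus, min_count = 1) {
  stopifnot(min_count >= 1)
  counts <- cooccurrence_counts(corpus)
  n_docs <- nrow(corpus)
  counts <- counts[counts$n >= min_count, , drop = FALSE]
  if (nrow(counts) == 0L) {
    stop("no concept pair reaches min_count", call. = FALSE)
  }
  counts$df <- counts$n  # a pair occurs at most once per document
  counts$weight <- counts$n * (log((n_docs + 1) / (counts$df + 1)) + 1)
  counts$confidence <- counts$weight / max(counts$weight)
  counts
}

#' Impact-factor significance weights for concept pairs
#'
#' The significance of a pair is the mean impact factor of the documents
#' supporting it, normalised by the maximum such mean, giving values in
#' `(0, 1]` that are invariant under rescaling all impact factors by a
#' positive constant.
#'
#' @inheritParams cooccurrence_counts
#' @return Tibble with columns `u`, `v`, `mean_if`, `significance`.
#' @export
significance_scores <- function(corpus) {
  if (all(corpus$impact_factor == 0)) {
    stop("all impact factors are zero: significance undefined, use defaults",
         call. = FALSE)
  }
  p <- corpus_pairs(corpus)
  p$impact_factor <- corpus$impact_factor[p$row]
  out <- p |>
    dplyr::group_by(.data$u, .data$v) |>
    dplyr::summarise(mean_if = mean(.data$impact_factor), .groups = "drop") |>
    dplyr::arrange(.data$u, .data$v)
  out$significance <- out$mean_if / max(out$mean_if)
  out
}

#' Extract weighted cross-ontology edges from a corpus
#'
#' Surviving pairs (co-occurring at least `min_count` times) whose two
#' concepts belong to different registered ontologies are materialised as
#' a pair of directed edges (both directions) of type `rel`, carrying the
#' pair's TF-IDF confidence and impact-factor significance (1.0 when all
#' impact factors are zero).
#'
#' @inheritParams cooccurrence_counts
#' @param net A [bmkn()] object; every corpus concept id must resolve.
#' @param rel Relation type for the created edges.
#' @param min_count Minimum co-occurrence count.
#' @return Edge tibble (`source`, `target`, `rel`, `confidence`,
#'   `significance`) ready for [add_edges()].
#' @export
extract_cooccurrence_edges <- function(corpus, net, rel = "cooccurs_with",
                                       min_count = 1) {
  stopifnot(inherits(net, "bmkn"))
  ids <- unique(unlist(corpus$concepts))
  missing <- setdiff(ids, net$concepts$id)
  if (length(missing)) {
    stop(sprintf("corpus concept id not in network: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  conf <- tfidf_confidence(corpus, min_count = min_count)
  sig <- tryCatch(significance_scores(corpus), error = function(e) NULL)
  w <- conf[, c("u", "v", "confidence")]
  if (is.null(sig)) {
    w$significance <- 1
  } else {
    w <- dplyr::left_join(w, sig[, c("u", "v", "significance")],
                          by = c("u", "v"))
  }
  ont <- stats::setNames(net$concepts$ontology, net$concepts$id)
  w <- w[unname(ont[w$u]) != unname(ont[w$v]), , drop = FALSE]
  dplyr::bind_rows(
    tibble::tibble(source = w$u, target = w$v, rel = rel,
                   confidence = w$confidence, significance = w$significance),
    tibble::tibble(source = w$v, target = w$u, rel = rel,
                   confidence = w$confidence, significance = w$significance)
  ) |>
    dplyr::arrange(.data$source, .data$target)
}

#' Attach corpus-derived weights to existing edges
#'
#' Edges whose unordered endpoint pair appears in `weights` get that pair's
#' confidence and significance (both directions of the pair are updated);
#' all other edges keep their current values — ontology-derived edges
#' retain the structured-source default of 1.0.
#'
#' @param net A [bmkn()] object.
#' @param weights Data frame with columns `u`, `v`, `confidence`,
#'   `significance`.
#' @return The updated network.
#' @export
attach_weights <- function(net, weights) {
  stopifnot(inherits(net, "bmkn"))
  if (is.null(weights) || nrow(weights) == 0L) return(net)
  stopifnot(all(c("u", "v", "confidence", "significance") %in% names(weights)))
  wkey <- paste(pmin(weights$u, weights$v), pmax(weights$u, weights$v))
  ekey <- paste(pmin(net$edges$source, net$edges$target),
                pmax(net$edges$source, net$edges$target))
  idx <- match(ekey, wkey)
  hit <- !is.na(idx)
  net$edges$confidence[hit] <- weights$confidence[idx[hit]]
  net$edges$significance[hit] <- weights$significance[idx[hit]]
  net
}
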