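#' Candidate diseases discoverable only through cross-ontology paths
#'
#' The differential-diagnosis use case: starting from a diagnosed disease,
#' expand through shared symptoms (or genes) and keep only concepts that
#' intra-ontology search cannot reach — the interesting set `F(steps)`
#' restricted to the anchor's own ontology. These are the diseases a
#' clinician might confuse with the anchor because they present the same
#' way while sitting in a different branch of the disease hierarchy.
#'
#' @param net A [bmkn()] object.
#' @param anchor Disease concept id.
#' @param steps Expansion step count (diagonal index), default 2.
#' @param mask Optional link mask.
#' @return Sorted character vector of candidate ids.
#' @export
misdiagnosis_candidates <- function(net, anchor, steps = 2, mask = NULL) {
  ont <- unname(concept_ontology(net, anchor))
  interesting_set(net, anchor, steps, ont, mask = mask)
}

#' Intra-ontology-only comparison baseline
#'
#' Similar diseases found using the disease ontology alone: the forward
#' intra-expansion `O[0, radius, t]` of the anchor's ontology, ignoring
#' every cross-ontology link. The contrast between this ball and
#' [misdiagnosis_candidates()] measures what the multi-ontology expansion
#' adds.
#'
#' @inheritParams misdiagnosis_candidates
#' @param radius Number of intra expansion steps, default 2.
#' @return Sorted character vector of concept ids.
#' @export
intra_only_baseline <- function(net, anchor, radius = 2, mask = NULL) {
  ont <- unname(concept_ontology(net, anchor))
  expand_set(net, anchor, 0, radius, ont, mask = mask)
}

#' Recall of a candidate set against a reference list
#'
#' @param candidates Character vector of discovered concept ids.
#' @param reference Character vector of reference ids (e.g. the
#'   differential diagnoses listed for the anchor), or a data frame with
#'   an `id` column. Must be non-empty.
#' @return Tibble with `n_candidates`, `n_reference`, `matched` and
#'   `percentage` (to one decimal).
#' @examples
#' recall_report(c("a", "b", "c"), c("a", "b", "d", "e", "f", "g"))
#' @export
recall_report <- function(candidates, reference) {
  if (is.data.frame(reference)) reference <- reference$id
  reference <- unique(reference)
  if (!length(reference)) stop("empty reference list", call. = FALSE)
  matched <- length(intersect(unique(candidates), reference))
  tibble::tibble(
    n_candidates = length(unique(candidates)),
    n_reference = length(reference),
    matched = matched,
    percentage = round(100 * matched / length(reference), 1)
  )
}

#' Form anchor-candidate disease pairs
#'
#' Pairs the anchor with every member of its interesting set, the unit of
#' the disease-pair discovery evaluation (each pair is checked against a
#' confirmation list of published co-reports).
#'
#' @inheritParams misdiagnosis_candidates
#' @return Tibble with columns `anchor`, `partner`, one row per candidate.
#' @export
disease_pair_candidates <- function(net, anchor, steps = 2, mask = NULL) {
  partners <- misdiagnosis_candidates(net, anchor, steps = steps, mask = mask)
  tibble::tibble(anchor = anchor, partner = partners)
}

#' Hit ratio of discovered pairs against a confirmation list
#'
#' The fraction of discovered pairs whose partner appears in the
#' confirmation list, reported to two decimals: 6 pairs with 4 confirmed
#' give 0.67.
#'
#' @param pairs Tibble from [disease_pair_candidates()] (or any data frame
#'   with a `partner` column).
#' @param confirmations Character vector of confirmed partner ids, or a
#'   data frame with an `id` column.
#' @return Single numeric in `[0, 1]`.
#' @export
hit_ratio <- function(pairs, confirmations) {
  if (is.data.frame(confirmations)) confirmations <- confirmations$id
  n <- nrow(pairs)
  if (n == 0L) stop("no pairs to score", call. = FALSE)
  round(sum(pairs$partner %in% confirmations) / n, 2)
}

#' Random-pairing baseline
#'
#' Pairs the anchor with `n` partners drawn uniformly without replacement
#' from the universe (anchor excluded); the comparison baseline for
#' [hit_ratio()]. Deterministic for a given seed.
#'
#' @param universe Character vector of eligible partner ids.
#' @param anchor Anchor id (never sampled).
#' @param n Number of pairs to draw.
#' @param seed Integer seed (required).
#' @return Tibble with columns `anchor`, `partner`.
#' @export
random_pair_baseline <- function(universe, anchor, n, seed) {
  pool <- sort(setdiff(unique(universe), anchor))
  if (n > length(pool)) {
    stop(sprintf("cannot draw %d partners from a pool of %d", n,
                 length(pool)), call. = FALSE)
  }
  partners <- with_seed(seed, sample(pool, n))
  tibble::tibble(anchor = anchor, partner = sort(partners))
}

#' Sweep link masks and measure search-space reduction
#'
#' Applies each mask to the network, recomputes the interesting set
#' `F(steps)` for every anchor on the pruned network, and tabulates the
#' surviving edge count, the mean candidate count over anchors, and that
#' mean as a percentage of the unmasked run (the no-mask row is 100% by
#' convention). A reference row named `no_mask` is always included.
#'
#' @param net A [bmkn()] object.
#' @param masks Named list of mask specifications ([parse_mask()] strings
#'   or mask sets); names label the report rows.
#' @param anchors Non-empty character vector of anchor ids.
#' @param steps Expansion step count, default 2.
#' @param target_ontology Ontology in which candidates are counted;
#'   default: each anchor's own ontology.
#' @return Tibble with columns `mask`, `edges`, `mean_count`,
#'   `percentage`.
#' @export
mask_sweep <- function(net, masks, anchors, steps = 2,
                       target_ontology = NULL) {
  stopifnot(length(anchors) >= 1)
  count_for <- function(pruned) {
    mean(vapply(anchors, function(a) {
      t <- target_ontology %||% unname(concept_ontology(pruned, a))
      length(interesting_set(pruned, a, steps, t))
    }, numeric(1)))
  }
  base_count <- count_for(net)
  rows <- list(tibble::tibble(
    mask = "no_mask", edges = nrow(net$edges), mean_count = base_count,
    percentage = 100
  ))
  nm <- names(masks) %||% paste0("mask_", seq_along(masks))
  for (i in seq_along(masks)) {
    pruned <- apply_masks(net, masks[[i]])$net
    mc <- count_for(pruned)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      mask = nm[i], edges = nrow(pruned$edges), mean_count = mc,
      percentage = if (base_count > 0) round(100 * mc / base_count, 2)
        else NA_real_
    )
  }
  dplyr::bind_rows(rows)
}
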