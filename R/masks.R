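#' Parse a link-mask specification
#'
#' A link mask controls which edges the relatedness-network expansion may
#' traverse. Each entry is a triplet `R(t, c, s)` attached to a relation
#' type: `t` is an include flag (1 = follow links of this type when both
#' thresholds are cleared, 0 = block the type outright), `c` a confidence
#' threshold and `s` a significance threshold, both in `[0, 1]` and compared
#' strictly (an edge passes only when `confidence > c` and
#' `significance > s`). The wildcard entry `all`/`rest` applies to every
#' relation type without its own entry; relation types matching neither a
#' typed entry nor a wildcard pass unconditionally.
#'
#' The textual grammar is comma-separated `rel:t:c:s` entries, e.g.
#' `"R1:0:0:0,rest:1:0.2:0.35"` (block every `R1` edge; follow any other
#' edge whose confidence exceeds 0.2 and significance exceeds 0.35).
#'
#' @param spec Mask string, or a data frame with columns `rel`, `t`, `c`,
#'   `s` (passed through after validation).
#' @return A `mask_set` tibble with columns `rel`, `t`, `c`, `s`, typed
#'   entries first, wildcard (stored as `"rest"`) last.
#' @examples
#' parse_mask("has_symptom:1:0.25:0.5")
#' parse_mask("R2:0:0:0,rest:1:0:0")
#' @export
parse_mask <- function(spec) {
  if (is.data.frame(spec)) {
    m <- tibble::as_tibble(spec)
  } else {
    stopifnot(is.character(spec), length(spec) == 1L)
    parts <- strsplit(trimws(spec), ",", fixed = TRUE)[[1]]
    parts <- parts[nzchar(trimws(parts))]
    if (!length(parts)) stop("empty mask specification", call. = FALSE)
    rows <- lapply(parts, function(p) {
      f <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
      if (length(f) != 4L) {
        stop(sprintf("malformed mask entry '%s' (want rel:t:c:s)", p),
             call. = FALSE)
      }
      num <- suppressWarnings(as.numeric(f[2:4]))
      if (anyNA(num)) {
        stop(sprintf("non-numeric field in mask entry '%s'", p),
             call. = FALSE)
      }
      tibble::tibble(rel = f[1], t = num[1], c = num[2], s = num[3])
    })
    m <- dplyr::bind_rows(rows)
  }
  if (!all(c("rel", "t", "c", "s") %in% names(m))) {
    stop("mask needs columns rel, t, c, s", call. = FALSE)
  }
  m$rel <- ifelse(m$rel %in% c("all", "rest"), "rest", m$rel)
  if (!all(m$t %in% c(0, 1))) stop("mask flag t must be 0 or 1", call. = FALSE)
  if (any(m$c < 0 | m$c > 1 | m$s < 0 | m$s > 1)) {
    stop("mask thresholds must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(m$rel)) {
    stop("at most one mask entry per relation type (plus one wildcard)",
         call. = FALSE)
  }
  m <- dplyr::arrange(m, .data$rel == "rest")
  structure(dplyr::select(m, "rel", "t", "c", "s"),
            class = c("mask_set", class(tibble::tibble())))
}

#' Does each edge pass a mask?
#'
#' The first matching entry decides (a typed entry beats the wildcard):
#' the edge passes iff that entry has `t = 1`, `confidence > c` and
#' `significance > s` — strict inequalities, so boundary equality blocks.
#' Edges whose relation type matches no entry pass.
#'
#' @param mask A mask set from [parse_mask()], or `NULL` (everything passes).
#' @param edges Data frame with columns `rel`, `confidence`, `significance`.
#' @return Logical vector, one element per edge row.
#' @export
edge_passes <- function(mask, edges) {
  n <- nrow(edges)
  if (is.null(mask) || nrow(mask) == 0L) return(rep(TRUE, n))
  if (!inherits(mask, "mask_set")) mask <- parse_mask(mask)
  typed <- mask[mask$rel != "rest", , drop = FALSE]
  idx <- match(edges$rel, typed$rel)
  wc <- which(mask$rel == "rest")
  has_wc <- length(wc) == 1L
  pass <- rep(TRUE, n)
  use_typed <- !is.na(idx)
  if (any(use_typed)) {
    i <- idx[use_typed]
    pass[use_typed] <- typed$t[i] == 1 &
      edges$confidence[use_typed] > typed$c[i] &
      edges$significance[use_typed] > typed$s[i]
  }
  if (has_wc && any(!use_typed)) {
    j <- which(!use_typed)
    pass[j] <- mask$t[wc] == 1 &
      edges$confidence[j] > mask$c[wc] &
      edges$significance[j] > mask$s[wc]
  }
  pass
}

#' Prune a whole network with a link mask
#'
#' Removes every edge the mask blocks, keeping all concepts. Traversal-time
#' masking inside the expansion engine and whole-graph pruning with the
#' same mask produce identical relatedness networks; pruning once is the
#' cheaper choice when many anchors share a mask.
#'
#' @param net A [bmkn()] object.
#' @param mask A mask set from [parse_mask()] (or its string form).
#' @return List with `net` (the pruned network) and `summary` (tibble with
#'   per-relation-type `kept` and `removed` counts).
#' @export
apply_masks <- function(net, mask) {
  stopifnot(inherits(net, "bmkn"))
  if (!is.null(mask) && !inherits(mask, "mask_set")) mask <- parse_mask(mask)
  pass <- edge_passes(mask, net$edges)
  summary <- net$edges |>
    dplyr::mutate(.pass = pass) |>
    dplyr::group_by(.data$rel) |>
    dplyr::summarise(kept = sum(.data$.pass), removed = sum(!.data$.pass),
                     .groups = "drop") |>
    dplyr::arrange(.data$rel)
  net$edges <- net$edges[pass, , drop = FALSE]
  list(net = net, summary = summary)
}

#' Remove high-degree hub concepts
#'
#' Concepts connected to very many others (e.g. gene product properties
#' required by most biological processes) flood a relatedness network with
#' uninformative links; excluding them before expansion keeps candidate
#' sets interpretable. Degree counts both in- and out-edges of the selected
#' class.
#'
#' @param net A [bmkn()] object.
#' @param class Which edges count towards the degree: `"any"`, `"intra"`,
#'   `"inter"`.
#' @param max_degree Concepts with degree strictly above this are removed
#'   together with all their incident edges. No default: the cut-off is a
#'   modelling decision.
#' @return List with `net` (pruned network, all ontologies and surviving
#'   concepts intact) and `removed` (character vector of removed ids).
#' @export
exclude_hubs <- function(net, class = c("any", "intra", "inter"), max_degree) {
  stopifnot(inherits(net, "bmkn"))
  class <- match.arg(class)
  if (missing(max_degree)) stop("max_degree is required", call. = FALSE)
  stopifnot(is.numeric(max_degree), length(max_degree) == 1L, max_degree >= 0)
  e <- net$edges
  if (class != "any") e <- e[edge_class(net) == class, , drop = FALSE]
  deg <- table(c(e$source, e$target))
  hubs <- names(deg)[deg > max_degree]
  net$concepts <- net$concepts[!net$concepts$id %in% hubs, , drop = FALSE]
  keep <- !(net$edges$source %in% hubs) & !(net$edges$target %in% hubs)
  net$edges <- net$edges[keep, , drop = FALSE]
  list(net = net, removed = sort(hubs))
}
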