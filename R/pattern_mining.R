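#' Grow significant high-order patterns inside a sub-pattern group
#'
#' Levelwise search over AV subsets of one SubPG (one AV per attribute,
#' order >= 2). A candidate is extended only while its EID-intersection
#' keeps enough support; significance is never used to prune supersets (the
#' compound residual is not anti-monotone). Every qualifying subset is kept
#' — the comprehensive view — not only maximal ones.
#'
#' A subset qualifies as a pattern when its compound residual is >=
#' \code{threshold} and its EID-intersection has at least
#' \code{min_occurrence} entities. Repulsive subsets (compound residual <=
#' -threshold) are returned separately under \code{negative}.
#'
#' @param subpg integer vector of catalog AV indices forming the SubPG.
#' @param catalog a \code{pdd_catalog}.
#' @param dsu DSU code string addressing the SubPG.
#' @param threshold SR significance threshold (default 1.96).
#' @param min_occurrence minimum EID-intersection size (default 2; a pattern
#'   seen once has no intersection evidence).
#' @param max_order cap on pattern order (default 8) guarding the
#'   exponential worst case; exceeding it logs a warning.
#' @return list with \code{patterns} and \code{negative}, each a list of
#'   pattern records (fields: avs, av_labels, eids, order, significance,
#'   dsu).
#' @export
grow_patterns <- function(subpg, catalog, dsu = "[1 1 1]", threshold = 1.96,
                          min_occurrence = 2L, max_order = 8L) {
  stopifnot(inherits(catalog, "pdd_catalog"))
  subpg <- sort(subpg)
  out <- list(); neg <- list()
  if (length(subpg) < 2L) return(list(patterns = out, negative = neg))
  attrs <- catalog$av$attr[subpg]
  if (length(unique(attrs)) > max_order) {
    warning("SubPG spans ", length(unique(attrs)), " attributes; search capped at order ",
            max_order)
  }
  # frontier of order-1 candidates
  frontier <- lapply(seq_along(subpg), function(i) {
    list(avs = subpg[i], eids = catalog$eids[[subpg[i]]])
  })
  frontier <- Filter(function(c) length(c$eids) >= min_occurrence, frontier)
  order_k <- 1L
  while (length(frontier) > 0L && order_k < max_order) {
    nxt <- list()
    for (cand in frontier) {
      last <- max(match(cand$avs, subpg))
      used_attrs <- catalog$av$attr[cand$avs]
      for (i in seq_along(subpg)) {
        if (i <= last) next
        k <- subpg[i]
        if (catalog$av$attr[k] %in% used_attrs) next
        eids <- intersect(cand$eids, catalog$eids[[k]])
        if (length(eids) < min_occurrence) next
        avs <- c(cand$avs, k)
        d <- compound_residual_stat(length(eids), catalog$av$n[avs], catalog$N)
        rec <- list(avs = avs, av_labels = catalog$av$label[avs],
                    eids = sort(eids), order = length(avs),
                    significance = d, dsu = dsu)
        if (d >= threshold) out[[length(out) + 1L]] <- rec
        else if (d <= -threshold) neg[[length(neg) + 1L]] <- rec
        nxt[[length(nxt) + 1L]] <- list(avs = avs, eids = eids)
      }
    }
    frontier <- nxt
    order_k <- order_k + 1L
  }
  list(patterns = out, negative = neg)
}

#' Summarize a DSU's patterns as a union super-pattern
#'
#' The summary pattern of a disentangled unit is the union of its member
#' patterns' AV sets, together with a per-entity count: how many member
#' patterns each entity contains. Entities containing none are omitted from
#' the count map.
#'
#' @param patterns list of pattern records sharing one DSU.
#' @param dsu the DSU code all patterns must carry.
#' @param n_entities total entity count (for validation of EIDs).
#' @return list with \code{dsu}, \code{av_union} (sorted AV indices),
#'   \code{av_labels}, \code{counts} (named integer vector, entity index ->
#'   pattern count, zero-count entities omitted).
#' @export
summarize_patterns <- function(patterns, dsu, n_entities) {
  if (length(patterns) == 0L) {
    return(list(dsu = dsu, av_union = integer(0), av_labels = character(0),
                counts = integer(0)))
  }
  dsus <- vapply(patterns, function(p) p$dsu, character(1))
  if (any(dsus != dsu)) stop("mixed-DSU input: expected ", dsu)
  av_union <- sort(unique(unlist(lapply(patterns, function(p) p$avs))))
  labs <- unlist(lapply(patterns, function(p) p$av_labels))
  avs <- unlist(lapply(patterns, function(p) p$avs))
  cnt <- integer(n_entities)
  for (p in patterns) cnt[p$eids] <- cnt[p$eids] + 1L
  nz <- which(cnt > 0L)
  counts <- cnt[nz]; names(counts) <- as.character(nz)
  list(dsu = dsu, av_union = av_union,
       av_labels = labs[match(av_union, avs)], counts = counts)
}

#' Associate a pattern with a class label
#'
#' The class of a pattern is the majority class among the labeled entities
#' in its EID-intersection; confidence is that majority fraction. Ties break
#' by class-name lexicographic order and are flagged. Class labels never
#' participate in residual computation, decomposition or pattern growth;
#' they are reference-only.
#'
#' @param pattern a pattern record from \code{\link{grow_patterns}}.
#' @param labels per-entity class vector (NA = unlabeled), indexed by entity.
#' @return list(class, confidence, tie) or NULL when no covered entity is
#'   labeled.
#' @export
associate_class <- function(pattern, labels) {
  lab <- labels[pattern$eids]
  lab <- lab[!is.na(lab)]
  if (length(lab) == 0L) return(NULL)
  tab <- table(lab)
  top <- max(tab)
  winners <- sort(names(tab)[tab == top])
  list(class = winners[1],
       confidence = top / length(pattern$eids),
       tie = length(winners) > 1L)
}
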