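#' Decompose the SR matrix into disentangled spaces
#'
#' Full eigendecomposition of the symmetric SR matrix. Each eigenpair
#' (lambda, v) defines one Disentangled Space (DS): the principal component
#' v over the catalog AVs together with its re-projected residual space
#' (RSRV), the rank-one matrix lambda v v'. Summed over all spaces the RSRVs
#' reconstruct SR exactly, so each space isolates the share of every AV-pair
#' residual attributable to one statistical source.
#'
#' Spaces are ordered by |lambda| descending (negative eigenvalues are kept
#' and ranked by magnitude); the eigenvector sign is fixed so the
#' largest-magnitude loading is positive, which makes pattern-group
#' numbering deterministic across platforms.
#'
#' @param sr SR matrix from \code{\link{build_sr_matrix}}.
#' @return list of \code{pdd_ds} objects, each with \code{ordinal},
#'   \code{lambda}, \code{v} (named loadings), \code{attr} (attribute index
#'   per AV).
#' @export
decompose <- function(sr) {
  if (!isSymmetric(unname(sr), tol = 1e-8)) stop("SR matrix must be symmetric")
  attrs <- attr(sr, "attr")
  if (is.null(attrs)) stop("SR matrix lacks the attribute-index attribute")
  eig <- eigen(sr, symmetric = TRUE)
  k <- length(eig$values)
  # stable order: |lambda| desc, ties by index of the largest loading asc
  peak <- vapply(seq_len(k), function(i) which.max(abs(eig$vectors[, i])), integer(1))
  ord <- order(-abs(eig$values), peak)
  spaces <- vector("list", k)
  for (r in seq_len(k)) {
    i <- ord[r]
    v <- eig$vectors[, i]
    if (v[which.max(abs(v))] < 0) v <- -v
    names(v) <- rownames(sr)
    spaces[[r]] <- structure(
      list(ordinal = r, lambda = eig$values[i], v = v, attr = attrs,
           retained = NA, significant_avs = integer(0)),
      class = "pdd_ds")
  }
  spaces
}

#' Rank-one re-projected residual space (RSRV) of a disentangled space
#'
#' @param space a \code{pdd_ds}.
#' @return the K x K matrix lambda v v'.
#' @export
ds_rsrv <- function(space) {
  stopifnot(inherits(space, "pdd_ds"))
  m <- space$lambda * tcrossprod(space$v)
  dimnames(m) <- list(names(space$v), names(space$v))
  m
}

#' @export
print.pdd_ds <- function(x, ...) {
  cat("DS", x$ordinal, ": lambda = ", signif(x$lambda, 5),
      if (isTRUE(x$retained)) " [retained]" else "",
      ", ", length(x$significant_avs), " significant AV(s)\n", sep = "")
  invisible(x)
}

#' Select statistically significant disentangled spaces
#'
#' A space is retained iff its RSRV contains at least one cross-attribute
#' entry of magnitude >= threshold and at least two significant AVs spanning
#' at least two attributes, where an AV is significant when it has at least
#' one cross-attribute RSRV entry of magnitude >= threshold. Retention is
#' evaluated per space, so non-contiguous retention (e.g. keeping DS5 while
#' dropping DS4) is representable.
#'
#' @param spaces list from \code{\link{decompose}}.
#' @param threshold SR significance threshold (default 1.96, the two-sided
#'   95\% normal bound).
#' @return the input list with \code{retained} and \code{significant_avs}
#'   filled in on every space.
#' @export
select_spaces <- function(spaces, threshold = 1.96) {
  lapply(spaces, function(sp) {
    R <- abs(ds_rsrv(sp))
    cross <- outer(sp$attr, sp$attr, "!=")
    hit <- R >= threshold & cross
    sig <- which(rowSums(hit) > 0)
    sp$significant_avs <- sig
    sp$retained <- length(sig) >= 2L && length(unique(sp$attr[sig])) >= 2L
    sp
  })
}

#' Split a disentangled space into its two pattern groups
#'
#' The significant AVs of a retained space are partitioned by the sign of
#' their principal-component loading: PG1 holds positive loadings, PG2
#' negative; zero loadings are excluded. Opposite PC sides carry patterns of
#' opposing sources (e.g. the two classes of a binary outcome).
#'
#' @param space a retained \code{pdd_ds}.
#' @return list of two \code{pdd_pg} objects (side "positive"/"negative");
#'   empty groups carry no members.
#' @export
form_pattern_groups <- function(space) {
  stopifnot(inherits(space, "pdd_ds"))
  sig <- space$significant_avs
  mk <- function(side, members) {
    structure(list(ds_ordinal = space$ordinal, side = side, pg_ordinal =
                     if (side == "positive") 1L else 2L,
                   members = members, subpgs = list()),
              class = "pdd_pg")
  }
  list(mk("positive", sig[space$v[sig] > 0]),
       mk("negative", sig[space$v[sig] < 0]))
}

#' Partition a pattern group into sub-pattern groups
#'
#' SubPGs group the PG's member AVs so that mutually positively associated
#' AVs belong together while members linked only through negative or weak
#' residuals stay apart. Grouping is average-linkage agglomeration on the
#' pairwise residuals: two groups merge while the average residual between
#' them is >= +threshold. Average linkage (rather than single-link
#' connectivity) keeps two distinct co-occurring blocks apart even when an
#' entangled AV shared by both sources bridges them pairwise — the bridge
#' cannot outvote the block-to-block negative associations. The residuals
#' are read from the full SR matrix when supplied; without \code{sr} the
#' space's rank-one RSRV is used. Groups are ordered by size descending,
#' ties by smallest AV index; singletons are allowed.
#'
#' @param pg a \code{pdd_pg}.
#' @param space its parent \code{pdd_ds}.
#' @param threshold SR significance threshold.
#' @param sr optional full SR matrix providing the association strengths.
#' @return the \code{pdd_pg} with \code{subpgs} filled (list of integer AV
#'   index vectors).
#' @export
form_subpgs <- function(pg, space, threshold = 1.96, sr = NULL) {
  stopifnot(inherits(pg, "pdd_pg"), inherits(space, "pdd_ds"))
  m <- pg$members
  if (length(m) == 0L) { pg$subpgs <- list(); return(pg) }
  if (length(m) == 1L) { pg$subpgs <- list(m); return(pg) }
  R <- if (is.null(sr)) ds_rsrv(space)[m, m, drop = FALSE] else sr[m, m, drop = FALSE]
  same <- outer(space$attr[m], space$attr[m], "==")
  R[same] <- 0   # mutually exclusive events carry no positive association
  # average linkage on dissimilarity -SR; cutting at height -threshold keeps
  # exactly the merges whose average association is >= +threshold
  hc <- stats::hclust(stats::as.dist(-R), method = "average")
  # UPGMA merge heights are monotone in exact arithmetic; clamp the
  # floating-point dips that make cutree refuse the tree
  hc$height <- cummax(hc$height)
  comp <- stats::cutree(hc, h = -threshold)
  groups <- split(m, comp)
  ord <- order(-lengths(groups), vapply(groups, min, numeric(1)))
  pg$subpgs <- unname(groups[ord])
  pg
}

# connected components of an undirected adjacency matrix (BFS)
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(adj[i, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Render a DSU code
#'
#' A disentangled unit (DSU) is addressed by the triple
#' [DS ordinal, PG ordinal, SubPG ordinal], rendered e.g. "[2 1 2]".
#'
#' @param ds,pg,subpg positive integer ordinals.
#' @return character scalar.
#' @export
dsu_code <- function(ds, pg, subpg) sprintf("[%d %d %d]", ds, pg, subpg)

#' Parse a rendered DSU code back to its triple
#' @param code character like "[2 1 2]".
#' @return integer vector of length 3.
#' @export
parse_dsu <- function(code) {
  as.integer(strsplit(gsub("\\[|\\]", "", code), " ")[[1]])
}

#' Export per-space loadings and significant residual entries
#'
#' Writes one CSV per retained space: PC loadings for every AV plus a
#' significance flag.
#'
#' @param spaces selected spaces list.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_spaces <- function(spaces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sp in spaces) {
    if (!isTRUE(sp$retained)) next
    df <- data.frame(av = names(sp$v), loading = sp$v,
                     significant = seq_along(sp$v) %in% sp$significant_avs)
    p <- file.path(dir, sprintf("ds_%d.csv", sp$ordinal))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
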