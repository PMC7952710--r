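#' Build the attribute-value (AV) catalog
#'
#' Enumerates every (attribute, observed non-missing value) event of an
#' all-categorical table, in attribute-then-value order, together with its
#' marginal count n and the set of entity indices (EIDs) carrying it. AVs
#' present in every entity (constant attributes, n = N) carry no association
#' information and are dropped with a warning.
#'
#' @param table an all-categorical \code{pdd_table} (quantize numeric
#'   attributes first).
#' @return an object of class \code{pdd_catalog}: a list with \code{av}
#'   (data.frame: attr, attr_name, value, n), \code{eids} (list of integer
#'   vectors), \code{Z} (N x K logical incidence matrix), \code{N},
#'   \code{entity_ids}.
#' @export
build_av_catalog <- function(table) {
  stopifnot(inherits(table, "pdd_table"))
  if (any(table$modes == "numeric")) {
    stop("catalog requires an all-categorical table; quantize numeric attributes first")
  }
  N <- nrow(table$values)
  rows <- list()
  eids <- list()
  for (j in seq_along(table$values)) {
    col <- table$values[[j]]
    vals <- sort(unique(col[!is.na(col)]))
    if (length(vals) == 0L) {
      stop("attribute '", names(table$values)[j], "' has zero non-missing values")
    }
    for (v in vals) {
      idx <- which(!is.na(col) & col == v)
      if (length(idx) == N) {
        warning("dropping constant AV ", names(table$values)[j], "=", v,
                " (marginal n = N carries no association)")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        attr = j, attr_name = names(table$values)[j], value = v,
        n = length(idx), stringsAsFactors = FALSE)
      eids[[length(eids) + 1L]] <- idx
    }
  }
  if (length(rows) == 0L) stop("catalog is empty after dropping constant AVs")
  av <- do.call(rbind, rows)
  av$label <- paste0(av$attr_name, "=", av$value)
  rownames(av) <- NULL
  Z <- matrix(FALSE, N, nrow(av))
  for (k in seq_len(nrow(av))) Z[eids[[k]], k] <- TRUE
  colnames(Z) <- av$label
  structure(list(av = av, eids = eids, Z = Z, N = N, entity_ids = table$entity_ids),
            class = "pdd_catalog")
}

#' @export
print.pdd_catalog <- function(x, ...) {
  cat("AV catalog:", nrow(x$av), "AVs over", length(unique(x$av$attr)),
      "attributes,", x$N, "entities\n")
  invisible(x)
}

#' EID-intersection of a set of AVs
#'
#' The set of entities each of which contains every AV in \code{avs}; its
#' size is the frequency count of that attribute-value association. AVs of
#' one attribute are mutually exclusive events, so at most one AV per
#' attribute is allowed.
#'
#' @param avs integer vector of catalog AV indices (non-empty).
#' @param catalog a \code{pdd_catalog}.
#' @return sorted integer vector of entity indices.
#' @export
eid_intersection <- function(avs, catalog) {
  stopifnot(inherits(catalog, "pdd_catalog"), length(avs) >= 1L)
  attrs <- catalog$av$attr[avs]
  if (anyDuplicated(attrs)) {
    stop("two AVs from the same attribute are mutually exclusive: ",
         paste(catalog$av$label[avs], collapse = ", "))
  }
  out <- catalog$eids[[avs[1]]]
  for (k in avs[-1]) out <- intersect(out, catalog$eids[[k]])
  sort(out)
}

#' Adjusted standardized residual of an AV pair
#'
#' The deviation of the observed co-occurrence count o from its expectation
#' e = n_a n_b / N under independence, standardized and adjusted for the
#' marginals: d = ((o - e)/sqrt(e)) / sqrt((1 - n_a/N)(1 - n_b/N)).
#' Under independence d is approximately standard normal, so |d| >= 1.96
#' marks two-sided 95\% significance; the sign separates positive from
#' negative association.
#'
#' @param o observed co-occurrence count.
#' @param n_a,n_b marginal counts of the two AVs, each strictly inside (0, N).
#' @param N total entity count.
#' @return the SR value (scalar).
#' @export
adjusted_residual <- function(o, n_a, n_b, N) {
  if (n_a <= 0 || n_a >= N || n_b <= 0 || n_b >= N) {
    stop("degenerate marginal: need 0 < n_a, n_b < N (got ", n_a, ", ", n_b,
         " with N = ", N, ")")
  }
  if (o < 0 || o > min(n_a, n_b)) stop("o must lie in [0, min(n_a, n_b)]")
  e <- n_a * n_b / N
  ((o - e) / sqrt(e)) / sqrt((1 - n_a / N) * (1 - n_b / N))
}

#' Compound residual of a high-order AV set
#'
#' Generalizes \code{\link{adjusted_residual}} to k >= 2 AVs (one per
#' attribute): o is the EID-intersection size, e = N prod(n_i/N), and
#' d = ((o - e)/sqrt(e)) / sqrt(prod(1 - n_i/N)). For k = 2 it coincides
#' with the pairwise residual.
#'
#' @param avs integer vector of catalog AV indices, length >= 2.
#' @param catalog a \code{pdd_catalog}.
#' @return the compound SR value (scalar).
#' @export
compound_residual <- function(avs, catalog) {
  stopifnot(length(avs) >= 2L)
  n <- catalog$av$n[avs]
  N <- catalog$N
  if (any(n <= 0 | n >= N)) {
    stop("degenerate marginal in ", paste(catalog$av$label[avs], collapse = ", "))
  }
  o <- length(eid_intersection(avs, catalog))
  compound_residual_stat(o, n, N)
}

# closed form on raw counts; shared by compound_residual and grow_patterns
compound_residual_stat <- function(o, n, N) {
  p <- n / N
  e <- N * prod(p)
  ((o - e) / sqrt(e)) / sqrt(prod(1 - p))
}

#' Build the SR matrix over all AV pairs
#'
#' The square symmetric matrix of adjusted standardized residuals of every
#' cross-attribute AV pair. Same-attribute entries (mutually exclusive
#' events) and the diagonal are structurally zero, which keeps the matrix
#' symmetric and eigendecomposable.
#'
#' @param catalog a \code{pdd_catalog} with AVs from at least two attributes.
#' @return K x K numeric matrix with AV labels as dimnames, plus attribute
#'   index attribute \code{"attr"}.
#' @export
build_sr_matrix <- function(catalog) {
  stopifnot(inherits(catalog, "pdd_catalog"))
  if (length(unique(catalog$av$attr)) < 2L) {
    stop("SR matrix needs AVs from at least 2 attributes")
  }
  n <- catalog$av$n
  N <- catalog$N
  O <- crossprod(catalog$Z)            # co-occurrence counts, K x K
  E <- outer(n, n) / N
  V <- sqrt(outer(1 - n / N, 1 - n / N))
  SR <- (O - E) / sqrt(E) / V
  same <- outer(catalog$av$attr, catalog$av$attr, "==")
  SR[same] <- 0
  if (any(E[!same] < 1)) {
    message("note: ", sum(E[!same] < 1) / 2, " AV pair(s) have expected count < 1")
  }
  dimnames(SR) <- list(catalog$av$label, catalog$av$label)
  attr(SR, "attr") <- catalog$av$attr
  SR
}

#' Export an SR matrix to labeled CSV
#'
#' @param sr SR matrix from \code{\link{build_sr_matrix}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sr_matrix <- function(sr, path) {
  utils::write.csv(as.data.frame(sr), path, row.names = TRUE)
  invisible(path)
}
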