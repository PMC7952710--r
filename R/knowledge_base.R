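#' Assemble the two-level knowledge base
#'
#' The knowledge base (KB) interlinks three things: the disentangled units
#' (DSUs), the discovered patterns, and the entities. It has two sections.
#' The Summary section has one row per DSU carrying the union super-pattern
#' and, per entity, the number of that DSU's patterns the entity contains.
#' The Comprehensive section has one row per individual pattern with 0/1
#' per-entity containment flags. Entities holding no pattern remain as
#' all-zero columns — that is what makes outliers visible in the KB.
#'
#' @param patterns_by_dsu named list: DSU code -> list of pattern records.
#' @param table the (quantized) \code{pdd_table} the patterns came from.
#' @param metadata list of run parameters recorded for reproducibility.
#' @return an object of class \code{pdd_kb} with fields \code{summary}
#'   (count matrix, DSU x entity), \code{comprehensive} (0/1 matrix,
#'   pattern x entity), \code{patterns} (row-aligned pattern records),
#'   \code{summaries} (per-DSU union patterns), \code{entity_ids},
#'   \code{labels}, \code{metadata}.
#' @export
build_kb <- function(patterns_by_dsu, table, metadata = list()) {
  stopifnot(inherits(table, "pdd_table"))
  ids <- table$entity_ids
  n <- length(ids)
  keep <- lengths(patterns_by_dsu) > 0L
  if (any(!keep)) {
    message("dropping ", sum(!keep), " DSU(s) with zero patterns")
  }
  patterns_by_dsu <- patterns_by_dsu[keep]
  dsus <- names(patterns_by_dsu)
  if (length(dsus)) {
    ord <- order(vapply(dsus, function(d) {
      t <- parse_dsu(d); t[1] * 1e6 + t[2] * 1e3 + t[3]
    }, numeric(1)))
    patterns_by_dsu <- patterns_by_dsu[ord]
    dsus <- dsus[ord]
  }
  # row order within a DSU: significance descending
  patterns <- list()
  for (d in dsus) {
    ps <- patterns_by_dsu[[d]]
    bad <- vapply(ps, function(p) !identical(p$dsu, d), logical(1))
    if (any(bad)) stop("pattern/DSU mapping inconsistent under ", d)
    ps <- ps[order(-vapply(ps, function(p) p$significance, numeric(1)))]
    patterns <- c(patterns, ps)
  }
  comp <- matrix(0L, length(patterns), n, dimnames = list(NULL, ids))
  for (i in seq_along(patterns)) comp[i, patterns[[i]]$eids] <- 1L
  summ <- matrix(0L, length(dsus), n, dimnames = list(dsus, ids))
  summaries <- list()
  for (d in dsus) {
    s <- summarize_patterns(patterns_by_dsu[[d]], d, n)
    summaries[[d]] <- s
    summ[d, as.integer(names(s$counts))] <- unname(s$counts)
  }
  structure(
    list(summary = summ, comprehensive = comp, patterns = patterns,
         summaries = summaries, entity_ids = ids,
         labels = table$labels, metadata = metadata),
    class = "pdd_kb")
}

#' @export
print.pdd_kb <- function(x, ...) {
  cat("PDD knowledge base: ", nrow(x$summary), " DSU(s), ",
      length(x$patterns), " pattern(s), ", length(x$entity_ids),
      " entities\n", sep = "")
  if (nrow(x$summary) > 0) {
    for (d in rownames(x$summary)) {
      s <- x$summaries[[d]]
      cat("  DSU", d, ": {", paste(s$av_labels, collapse = ", "), "} — ",
          sum(x$summary[d, ] > 0), " entities covered\n", sep = "")
    }
  }
  invisible(x)
}

#' Export a knowledge base to disk
#'
#' Writes \code{summary.csv} (rows: DSU code + AV union; columns: entity
#' ids, plus a class row when labels exist), \code{comprehensive.csv}
#' (rows: DSU + pattern AVs + significance; columns: 0/1 flags) and
#' \code{metadata.json}. The JSON format nests the same content in one
#' file. Export then import is lossless.
#'
#' @param kb a \code{pdd_kb}.
#' @param dir output directory (created if needed).
#' @param format "csv" or "json".
#' @return named character vector of written files (the manifest).
#' @export
export_kb <- function(kb, dir, format = c("csv", "json")) {
  stopifnot(inherits(kb, "pdd_kb"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "json") {
    path <- file.path(dir, "kb.json")
    obj <- list(
      entity_ids = kb$entity_ids,
      labels = if (is.null(kb$labels)) NULL else unname(kb$labels),
      dsus = rownames(kb$summary),
      summary = unname(asplit(kb$summary, 1)),
      summaries = lapply(kb$summaries, function(s)
        list(dsu = s$dsu, av_labels = s$av_labels)),
      patterns = lapply(kb$patterns, function(p)
        list(dsu = p$dsu, av_labels = p$av_labels, eids = p$eids,
             significance = p$significance)),
      metadata = kb$metadata)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
    return(c(kb = path))
  }
  spath <- file.path(dir, "summary.csv")
  sdf <- data.frame(dsu = rownames(kb$summary),
                    avs = vapply(kb$summaries, function(s)
                      paste(s$av_labels, collapse = ";"), character(1)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  sdf <- cbind(sdf, as.data.frame(kb$summary, check.names = FALSE))
  if (!is.null(kb$labels)) {
    cls <- c(dsu = "class", avs = "", as.list(ifelse(is.na(kb$labels), "", kb$labels)))
    sdf <- rbind(as.data.frame(cls, check.names = FALSE, stringsAsFactors = FALSE), sdf)
  }
  utils::write.csv(sdf, spath, row.names = FALSE)
  cpath <- file.path(dir, "comprehensive.csv")
  cdf <- data.frame(
    dsu = vapply(kb$patterns, function(p) p$dsu, character(1)),
    avs = vapply(kb$patterns, function(p) paste(p$av_labels, collapse = ";"), character(1)),
    significance = vapply(kb$patterns, function(p) p$significance, numeric(1)),
    stringsAsFactors = FALSE)
  cdf <- cbind(cdf, as.data.frame(kb$comprehensive, check.names = FALSE))
  utils::write.csv(cdf, cpath, row.names = FALSE)
  mpath <- file.path(dir, "metadata.json")
  jsonlite::write_json(kb$metadata, mpath, auto_unbox = TRUE, digits = NA)
  c(summary = spath, comprehensive = cpath, metadata = mpath)
}

#' Import a knowledge base written by \code{\link{export_kb}}
#'
#' @param dir directory holding the exported files.
#' @param format "csv" or "json".
#' @return a \code{pdd_kb}.
#' @export
import_kb <- function(dir, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::read_json(file.path(dir, "kb.json"), simplifyVector = TRUE,
                               simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
    ids <- unlist(obj$entity_ids)
    labels <- if (is.null(obj$labels)) NULL else {
      l <- unlist(obj$labels); names(l) <- ids; l
    }
    patterns <- lapply(obj$patterns, function(p)
      list(avs = integer(0), av_labels = unlist(p$av_labels),
           eids = as.integer(unlist(p$eids)),
           order = length(unlist(p$av_labels)),
           significance = p$significance, dsu = p$dsu))
  } else {
    sdf <- utils::read.csv(file.path(dir, "summary.csv"), check.names = FALSE,
                           colClasses = "character")
    cdf <- utils::read.csv(file.path(dir, "comprehensive.csv"), check.names = FALSE,
                           colClasses = "character")
    ids <- names(sdf)[-(1:2)]
    labels <- NULL
    if (nrow(sdf) > 0 && sdf$dsu[1] == "class") {
      l <- as.character(sdf[1, -(1:2)])
      l[l == ""] <- NA_character_
      names(l) <- ids
      labels <- l
      sdf <- sdf[-1, , drop = FALSE]
    }
    patterns <- lapply(seq_len(nrow(cdf)), function(i) {
      flags <- as.integer(cdf[i, -(1:3)])
      list(avs = integer(0),
           av_labels = strsplit(cdf$avs[i], ";", fixed = TRUE)[[1]],
           eids = which(flags == 1L),
           order = length(strsplit(cdf$avs[i], ";", fixed = TRUE)[[1]]),
           significance = as.numeric(cdf$significance[i]),
           dsu = cdf$dsu[i])
    })
    obj <- list(metadata = tryCatch(
      jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE),
      error = function(e) list()))
  }
  # rebuild AV indices against the label universe so summaries reconstruct
  universe <- sort(unique(unlist(lapply(patterns, function(p) p$av_labels))))
  patterns <- lapply(patterns, function(p) {
    p$avs <- match(p$av_labels, universe)
    p
  })
  by_dsu <- split(patterns, vapply(patterns, function(p) p$dsu, character(1)))
  tbl <- pdd_table(data.frame(.placeholder = rep("x", length(ids)),
                              stringsAsFactors = FALSE),
                   entity_ids = ids, labels = labels)
  build_kb(by_dsu, tbl, metadata = obj$metadata)
}
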