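#' Fit a pattern-discovery-and-disentanglement model
#'
#' Runs the full pipeline on a relational table: quantize numeric
#' attributes, build the AV catalog and the matrix of adjusted standardized
#' residuals (SR) over all cross-attribute AV pairs, eigendecompose it into
#' disentangled spaces, retain the statistically significant spaces, split
#' each into pattern groups (PC sign) and sub-pattern groups (positive
#' residual components), grow all significant high-order patterns inside
#' each SubPG, and assemble the two-level knowledge base. When labels are
#' present each pattern additionally gets a class association (labels are
#' reference-only: they never enter the statistics).
#'
#' @param x a \code{pdd_table} or a data.frame (coerced; character columns
#'   categorical, numeric columns numeric).
#' @param labels optional per-entity class vector; defaults to the table's
#'   own labels.
#' @param threshold SR significance threshold (default 1.96, two-sided 95\%
#'   normal bound).
#' @param bins number of quantization intervals for numeric attributes.
#' @param quant_method "equal_width" or "equal_frequency".
#' @param min_occurrence minimum pattern EID-intersection size.
#' @param max_order cap on pattern order.
#' @return an object of class \code{pdd}: list with the quantized
#'   \code{table}, \code{scheme}, \code{catalog}, \code{sr}, \code{spaces}
#'   (all, ordered by |lambda|), \code{retained} (ordinals), \code{units}
#'   (DSU code -> AV index vector), \code{patterns_by_dsu}, \code{kb},
#'   \code{associations} (per comprehensive-KB row, when labeled),
#'   \code{priors}, and the call parameters.
#' @examples
#' tab <- generate(preset("apc1_like"))$table
#' fit <- pdd(tab)
#' print(fit)
#' @export
pdd <- function(x, labels = NULL, threshold = 1.96, bins = 3L,
                quant_method = "equal_width", min_occurrence = 2L,
                max_order = 8L) {
  if (is.data.frame(x)) x <- pdd_table(x)
  stopifnot(inherits(x, "pdd_table"), threshold > 0)
  if (is.null(labels)) labels <- x$labels
  if (!is.null(labels) && is.null(names(labels))) names(labels) <- x$entity_ids
  scheme <- NULL
  qt <- x
  if (any(x$modes == "numeric")) {
    q <- quantize(x, bins = bins, method = quant_method)
    qt <- q$table
    scheme <- q$scheme
  }
  catalog <- build_av_catalog(qt)
  sr <- build_sr_matrix(catalog)
  spaces <- select_spaces(decompose(sr), threshold = threshold)
  retained <- which(vapply(spaces, function(s) isTRUE(s$retained), logical(1)))
  units <- list()
  patterns_by_dsu <- list()
  for (r in retained) {
    sp <- spaces[[r]]
    for (pg in form_pattern_groups(sp)) {
      pg <- form_subpgs(pg, sp, threshold = threshold, sr = sr)
      for (s in seq_along(pg$subpgs)) {
        code <- dsu_code(sp$ordinal, pg$pg_ordinal, s)
        units[[code]] <- pg$subpgs[[s]]
        patterns_by_dsu[[code]] <- grow_patterns(
          pg$subpgs[[s]], catalog, dsu = code, threshold = threshold,
          min_occurrence = min_occurrence, max_order = max_order)$patterns
      }
    }
  }
  meta <- list(threshold = threshold, bins = bins, quant_method = quant_method,
               min_occurrence = min_occurrence, max_order = max_order,
               n_entities = nrow(qt$values), n_avs = nrow(catalog$av),
               package_version = as.character(utils::packageVersion("pddkit")))
  qt$labels <- if (is.null(labels)) NULL else stats::setNames(as.character(labels), qt$entity_ids)
  kb <- suppressMessages(build_kb(patterns_by_dsu, qt, metadata = meta))
  associations <- NULL
  priors <- NULL
  if (!is.null(labels)) {
    associations <- lapply(kb$patterns, associate_class, labels = unname(qt$labels))
    tab <- table(labels[!is.na(labels)])
    priors <- as.numeric(tab) / sum(tab)
    names(priors) <- names(tab)
  }
  structure(
    list(table = qt, scheme = scheme, catalog = catalog, sr = sr,
         spaces = spaces, retained = retained, units = units,
         patterns_by_dsu = patterns_by_dsu, kb = kb,
         associations = associations, priors = priors,
         threshold = threshold, min_occurrence = min_occurrence,
         max_order = max_order),
    class = "pdd")
}

#' @export
print.pdd <- function(x, ...) {
  cat("Pattern discovery and disentanglement fit\n")
  cat("  entities: ", x$catalog$N, ", AVs: ", nrow(x$catalog$av),
      " over ", length(unique(x$catalog$av$attr)), " attributes\n", sep = "")
  cat("  disentangled spaces retained: ", length(x$retained), " of ",
      length(x$spaces), " (|SR| >= ", x$threshold, ")\n", sep = "")
  cat("  disentangled units (DSUs): ", length(x$units),
      ", patterns: ", length(x$kb$patterns), "\n", sep = "")
  invisible(x)
}

#' @export
summary.pdd <- function(object, ...) {
  dsus <- rownames(object$kb$summary)
  df <- data.frame(
    dsu = dsus,
    n_patterns = vapply(dsus, function(d) length(object$patterns_by_dsu[[d]]), integer(1)),
    n_entities = if (length(dsus)) rowSums(object$kb$summary > 0) else integer(0),
    av_union = vapply(dsus, function(d)
      paste(object$kb$summaries[[d]]$av_labels, collapse = ", "), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(object$associations)) {
    df$class <- vapply(dsus, function(d) {
      idx <- which(vapply(object$kb$patterns, function(p) p$dsu == d, logical(1)))
      cls <- vapply(object$associations[idx], function(a)
        if (is.null(a)) NA_character_ else a$class, character(1))
      cls <- cls[!is.na(cls)]
      if (length(cls) == 0) NA_character_ else names(sort(table(cls), decreasing = TRUE))[1]
    }, character(1))
  }
  out <- list(units = df, n_outliers = length(detect_outliers(object$kb)),
              eigenvalues = vapply(object$spaces, function(s) s$lambda, numeric(1)),
              retained = object$retained)
  class(out) <- "summary.pdd"
  out
}

#' @export
print.summary.pdd <- function(x, ...) {
  cat("Disentangled units:\n")
  print(x$units, right = FALSE)
  cat("\nRetained spaces (ordinals):", paste(x$retained, collapse = ", "), "\n")
  cat("Entities with no pattern (outliers):", x$n_outliers, "\n")
  invisible(x)
}

#' @export
#' @describeIn pdd the SR matrix of the fit (the model's residual object).
residuals.pdd <- function(object, ...) object$sr

#' @export
#' @describeIn pdd principal-component loadings of the retained spaces
#'   (AVs x spaces).
coef.pdd <- function(object, ...) {
  if (length(object$retained) == 0) return(matrix(0, nrow(object$catalog$av), 0))
  m <- vapply(object$spaces[object$retained], function(s) s$v,
              numeric(nrow(object$catalog$av)))
  colnames(m) <- paste0("DS", vapply(object$spaces[object$retained],
                                     function(s) s$ordinal, integer(1)))
  rownames(m) <- object$catalog$av$label
  m
}

#' @export
#' @describeIn pdd scree plot of eigenvalue magnitudes with retained spaces
#'   marked, plus an image of the SR matrix.
plot.pdd <- function(x, which = c("scree", "sr"), ...) {
  which <- match.arg(which)
  if (which == "scree") {
    lam <- abs(vapply(x$spaces, function(s) s$lambda, numeric(1)))
    col <- ifelse(seq_along(lam) %in% x$retained, "firebrick", "grey60")
    graphics::barplot(lam, col = col, border = NA,
                      names.arg = seq_along(lam),
                      xlab = "disentangled space (by |eigenvalue|)",
                      ylab = "|eigenvalue|",
                      main = "Scree of SR-matrix decomposition")
    graphics::legend("topright", fill = c("firebrick", "grey60"),
                     legend = c("retained", "dropped"), bty = "n")
  } else {
    k <- nrow(x$sr)
    graphics::image(seq_len(k), seq_len(k), t(x$sr[k:1, , drop = FALSE]),
                    xlab = "AV index", ylab = "AV index",
                    main = "Adjusted standardized residuals", useRaster = TRUE)
  }
  invisible(x)
}
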