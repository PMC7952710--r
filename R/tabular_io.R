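#' Construct a relational table
#'
#' A relational table is the input object of the whole pipeline: rows are
#' entities, columns are mixed-mode attributes (categorical or numeric), with
#' an optional per-entity class label kept apart from the attributes.
#'
#' @param values data.frame of attribute columns (character or numeric).
#' @param entity_ids character vector of unique entity identifiers; defaults
#'   to "E1".."EN" in row order.
#' @param modes character vector, one of "categorical"/"numeric" per column;
#'   inferred from column classes when missing.
#' @param labels optional character vector of class labels (NA allowed).
#' @param provenance free-text source tag.
#' @return an object of class \code{pdd_table}.
#' @export
pdd_table <- function(values, entity_ids = NULL, modes = NULL, labels = NULL,
                      provenance = "") {
  if (!is.data.frame(values)) values <- as.data.frame(values, stringsAsFactors = FALSE)
  n <- nrow(values)
  m <- ncol(values)
  if (n == 0L || m == 0L) stop("empty table: need at least one entity and one attribute")
  if (is.null(entity_ids)) entity_ids <- paste0("E", seq_len(n))
  entity_ids <- as.character(entity_ids)
  if (anyDuplicated(entity_ids)) {
    stop("duplicate entity ids: ", paste(unique(entity_ids[duplicated(entity_ids)]), collapse = ", "))
  }
  if (length(entity_ids) != n) stop("entity_ids length does not match row count")
  if (is.null(modes)) {
    modes <- vapply(values, function(col) if (is.numeric(col)) "numeric" else "categorical",
                    character(1))
  }
  modes <- unname(modes)
  stopifnot(length(modes) == m, all(modes %in% c("categorical", "numeric")))
  for (j in seq_len(m)) {
    values[[j]] <- if (modes[j] == "numeric") as.numeric(values[[j]]) else as.character(values[[j]])
    if (modes[j] == "numeric" && !any(is.finite(values[[j]]))) {
      stop("numeric attribute '", names(values)[j], "' has no finite value")
    }
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("labels must cover every entity (use NA for missing)")
    names(labels) <- entity_ids
  }
  structure(
    list(values = values, entity_ids = entity_ids, modes = modes,
         labels = labels, provenance = provenance),
    class = "pdd_table"
  )
}

#' @export
print.pdd_table <- function(x, ...) {
  cat("Relational table:", nrow(x$values), "entities x", ncol(x$values), "attributes\n")
  cat("  modes:", sum(x$modes == "categorical"), "categorical,",
      sum(x$modes == "numeric"), "numeric\n")
  if (!is.null(x$labels)) {
    tab <- table(x$labels, useNA = "no")
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (nzchar(x$provenance)) cat("  source:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.pdd_table <- function(x) dim(x$values)

#' Read a relational table from CSV
#'
#' Reads an RFC-4180 CSV with a header row. Attribute mode is inferred per
#' column: numeric when every non-missing cell parses as a number, otherwise
#' categorical. Cells equal to \code{missing_marker} become missing values.
#'
#' @param path file path.
#' @param label_column optional header name of the class-label column; it is
#'   extracted into \code{labels} and removed from the attributes.
#' @param id_column optional header name of an entity-id column.
#' @param missing_marker symbol marking missing cells (default "?").
#' @return a \code{pdd_table}.
#' @export
read_table <- function(path, label_column = NULL, id_column = NULL,
                       missing_marker = "?") {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"", blank.lines.skip = TRUE)
  if (length(nf) < 2L) stop("empty table: ", path, " has no data rows")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged CSV: row ", bad, " has ", nf[bad], " cells, expected ", nf[1])
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character(0))
  if (nrow(df) == 0L) stop("empty table: ", path)
  ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(df)) stop("id column '", id_column, "' not in header")
    ids <- df[[id_column]]
    df[[id_column]] <- NULL
  }
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df)) stop("label column '", label_column, "' not in header")
    labels <- df[[label_column]]
    labels[labels == missing_marker | labels == ""] <- NA_character_
    df[[label_column]] <- NULL
  }
  if (ncol(df) == 0L) stop("empty table: no attribute columns left")
  for (j in seq_along(df)) {
    col <- df[[j]]
    col[col == missing_marker] <- NA_character_
    num <- suppressWarnings(as.numeric(col))
    if (!any(is.na(num) & !is.na(col)) && any(is.finite(num))) {
      df[[j]] <- num
    } else {
      df[[j]] <- col
    }
  }
  pdd_table(df, entity_ids = ids, labels = labels, provenance = path)
}

#' Write a relational table to CSV
#'
#' Mirrors \code{\link{read_table}} bit-exactly: re-reading the written file
#' with the same id/label column names reproduces the table.
#'
#' @param table a \code{pdd_table}.
#' @param path output path.
#' @param missing_marker symbol to write for missing cells.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(table, path, missing_marker = "?") {
  stopifnot(inherits(table, "pdd_table"))
  out <- table$values
  for (j in seq_along(out)) {
    col <- as.character(out[[j]])
    col[is.na(col)] <- missing_marker
    out[[j]] <- col
  }
  out <- cbind(data.frame(id = table$entity_ids, stringsAsFactors = FALSE), out)
  if (!is.null(table$labels)) {
    lab <- unname(table$labels)
    lab[is.na(lab)] <- missing_marker
    out$class <- lab
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an aligned sequence block as a relational table
#'
#' Treats each aligned site (column) as a categorical attribute whose values
#' are the residue characters observed there; the gap character "-" is an
#' ordinary category. Accepts aligned FASTA or one-sequence-per-line text.
#'
#' @param path file path.
#' @param site_start 1-based coordinate of the first site, so attributes can
#'   be named e.g. S71..S96 for a block starting at position 71.
#' @return a \code{pdd_table} with one categorical attribute per site.
#' @export
read_alignment <- function(path, site_start = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty alignment file: ", path)
  if (startsWith(trimws(lines[1]), ">")) {
    fas <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE, set.attributes = FALSE)
    seqs <- toupper(vapply(fas, identity, character(1)))
    ids <- names(fas)
  } else {
    seqs <- toupper(trimws(lines))
    ids <- paste0("E", seq_along(seqs))
  }
  if (length(seqs) < 2L) stop("alignment needs at least 2 sequences")
  w <- nchar(seqs)
  if (length(unique(w)) > 1L) {
    bad <- which(w != w[1])
    stop("unequal sequence lengths: record(s) ", paste(ids[bad], collapse = ", "),
         " have length ", paste(unique(w[bad]), collapse = "/"), ", expected ", w[1])
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- paste0("S", seq_len(ncol(df)) + site_start - 1L)
  pdd_table(df, entity_ids = ids, provenance = path)
}

#' Quantize numeric attributes into interval categories
#'
#' Replaces every numeric attribute by a categorical attribute of interval
#' labels, so that values with small variation fall into the same interval.
#' Intervals are left-closed/right-open except the last bin, which is closed.
#' Categorical attributes pass through unchanged. The returned scheme can be
#' re-applied to held-out data (train-fit, test-apply).
#'
#' @param table a \code{pdd_table}.
#' @param bins number of intervals per numeric attribute (>= 1).
#' @param method "equal_width" (default) or "equal_frequency".
#' @return list with elements \code{table} (all-categorical \code{pdd_table})
#'   and \code{scheme} (a \code{pdd_quantization} holding per-attribute edges).
#' @export
quantize <- function(table, bins = 3L, method = c("equal_width", "equal_frequency")) {
  stopifnot(inherits(table, "pdd_table"), bins >= 1L)
  method <- match.arg(method)
  num <- which(table$modes == "numeric")
  edges <- list()
  for (j in num) {
    x <- table$values[[j]]
    fin <- x[is.finite(x)]
    e <- if (method == "equal_width") {
      lo <- min(fin); hi <- max(fin)
      if (lo == hi) c(lo, hi) else lo + (hi - lo) * (0:bins) / bins
    } else {
      q <- unique(stats::quantile(fin, probs = (0:bins) / bins, type = 7, names = FALSE))
      if (length(q) < bins + 1L && length(unique(fin)) > 1L) {
        warning("attribute '", names(table$values)[j],
                "': fewer distinct values than bins; collapsing to ", length(q) - 1L, " bins")
      }
      q
    }
    edges[[names(table$values)[j]]] <- e
  }
  scheme <- structure(list(edges = edges, method = method, bins = bins),
                      class = "pdd_quantization")
  list(table = apply_quantization(scheme, table), scheme = scheme)
}

#' Apply a stored quantization scheme
#'
#' Maps each numeric attribute of \code{table} through the interval edges
#' stored in \code{scheme}. Values outside the training range clamp into the
#' first/last bin. Reapplying a scheme to its training table reproduces the
#' quantized training table exactly.
#'
#' @param scheme a \code{pdd_quantization} from \code{\link{quantize}}.
#' @param table a \code{pdd_table}.
#' @return an all-categorical \code{pdd_table}.
#' @export
apply_quantization <- function(scheme, table) {
  stopifnot(inherits(scheme, "pdd_quantization"), inherits(table, "pdd_table"))
  vals <- table$values
  modes <- table$modes
  for (nm in names(scheme$edges)) {
    j <- match(nm, names(vals))
    if (is.na(j) || modes[j] != "numeric") next
    e <- scheme$edges[[nm]]
    labs <- interval_labels(e)
    x <- vals[[j]]
    if (length(e) == 2L && e[1] == e[2]) {
      b <- ifelse(is.finite(x), 1L, NA_integer_)
    } else {
      # left-closed/right-open, last bin closed; clamp out-of-range values
      b <- findInterval(x, e, rightmost.closed = TRUE, all.inside = TRUE)
      b[!is.finite(x)] <- NA_integer_
    }
    vals[[j]] <- labs[b]
    modes[j] <- "categorical"
  }
  pdd_table(vals, entity_ids = table$entity_ids, modes = modes,
            labels = table$labels, provenance = table$provenance)
}

interval_labels <- function(edges) {
  k <- length(edges) - 1L
  if (k == 0L) return(sprintf("[%g,%g]", edges[1], edges[1]))
  close <- c(rep(")", max(k - 1L, 0L)), "]")
  sprintf("[%g,%g%s", edges[seq_len(k)], edges[seq_len(k) + 1L], close)
}

#' @export
print.pdd_quantization <- function(x, ...) {
  cat("Quantization scheme (", x$method, ", ", x$bins, " bins) over ",
      length(x$edges), " numeric attribute(s)\n", sep = "")
  for (nm in names(x$edges)) cat("  ", nm, ": ", paste(signif(x$edges[[nm]], 6), collapse = " | "), "\n", sep = "")
  invisible(x)
}
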