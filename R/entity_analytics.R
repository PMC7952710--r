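#' Cluster entities from knowledge-base coverage
#'
#' Each covered entity is assigned to the DSU where it holds the most
#' patterns (summary count; ties go to the lower DSU code). DSU clusters
#' whose covered-entity sets overlap by Jaccard >= \code{merge_overlap} are
#' then merged transitively. Entities holding no pattern go to the
#' unassigned set.
#'
#' @param kb a \code{pdd_kb}.
#' @param merge_overlap Jaccard threshold for merging DSU clusters
#'   (default 0.5; 1.0 only merges identical coverage).
#' @return an object of class \code{pdd_clustering}: list with
#'   \code{assignments} (named integer, entity id -> cluster), \code{clusters}
#'   (cluster -> member DSU codes), \code{unassigned} (entity ids).
#' @export
cluster_entities <- function(kb, merge_overlap = 0.5) {
  stopifnot(inherits(kb, "pdd_kb"))
  ids <- kb$entity_ids
  S <- kb$summary
  if (nrow(S) == 0L) {
    return(structure(list(assignments = stats::setNames(integer(0), character(0)),
                          clusters = list(), unassigned = ids),
                     class = "pdd_clustering"))
  }
  dsus <- rownames(S)
  key <- vapply(dsus, function(d) { t <- parse_dsu(d); t[1] * 1e6 + t[2] * 1e3 + t[3] },
                numeric(1))
  # per-entity best DSU (max count, ties -> lower DSU code)
  best <- apply(S, 2, function(col) {
    if (all(col == 0)) return(NA_integer_)
    cand <- which(col == max(col))
    cand[which.min(key[cand])]
  })
  covered <- !is.na(best)
  # merge DSU clusters by transitive Jaccard overlap of covered-entity sets
  cov_sets <- lapply(seq_along(dsus), function(i) which(S[i, ] > 0))
  k <- length(dsus)
  adj <- diag(TRUE, k)
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    u <- length(union(cov_sets[[i]], cov_sets[[j]]))
    jac <- if (u == 0) 0 else length(intersect(cov_sets[[i]], cov_sets[[j]])) / u
    adj[i, j] <- adj[j, i] <- jac >= merge_overlap
  }
  comp <- connected_components(adj)
  # stable cluster numbering: by smallest DSU key in each component
  comp_key <- tapply(key, comp, min)
  relab <- match(comp_key[as.character(comp)], sort(comp_key))
  assignments <- stats::setNames(relab[best[covered]], ids[covered])
  clusters <- split(dsus, relab)
  names(clusters) <- as.character(sort(unique(relab)))
  structure(list(assignments = assignments, clusters = clusters,
                 unassigned = ids[!covered]),
            class = "pdd_clustering")
}

#' @export
print.pdd_clustering <- function(x, ...) {
  cat("Entity clustering:", length(unique(x$assignments)), "cluster(s),",
      length(x$assignments), "assigned,", length(x$unassigned), "unassigned\n")
  for (cl in names(x$clusters)) {
    cat("  cluster ", cl, " [", paste(x$clusters[[cl]], collapse = ", "), "]: ",
        sum(x$assignments == as.integer(cl)), " entities\n", sep = "")
  }
  invisible(x)
}

#' Detect outlier entities
#'
#' An outlier is an entity containing no discovered pattern at the model's
#' statistical threshold: an all-zero column of the knowledge base.
#'
#' @param kb a \code{pdd_kb}.
#' @return character vector of entity ids, in entity order.
#' @export
detect_outliers <- function(kb) {
  stopifnot(inherits(kb, "pdd_kb"))
  if (nrow(kb$comprehensive) == 0L) return(kb$entity_ids)
  kb$entity_ids[colSums(kb$comprehensive) == 0L]
}

#' Detect mislabeled entities
#'
#' An entity is flagged as mislabeled when it matches at least one pattern
#' and every matched pattern's associated class differs from its recorded
#' label. The inferred class is the significance-weighted majority over its
#' matched patterns. Outliers (zero matches) are never mislabeled — the two
#' sets are disjoint by construction.
#'
#' @param kb a \code{pdd_kb}.
#' @param labels per-entity class vector (named by entity id, or in entity
#'   order); defaults to the KB's labels.
#' @param associations per-pattern class associations, row-aligned with the
#'   comprehensive section (as stored on a labeled \code{pdd} fit).
#' @return an object of class \code{pdd_anomalies}: list with
#'   \code{outliers} (ids) and \code{mislabeled} (data.frame: entity, label,
#'   inferred, n_support plus a list-column of supporting pattern rows).
#' @export
detect_mislabeled <- function(kb, labels = NULL, associations) {
  stopifnot(inherits(kb, "pdd_kb"))
  if (is.null(labels)) labels <- kb$labels
  if (is.null(labels)) stop("labels required for mislabel detection")
  labels <- if (is.null(names(labels))) stats::setNames(as.character(labels), kb$entity_ids)
            else labels[kb$entity_ids]
  pat_class <- vapply(associations, function(a)
    if (is.null(a)) NA_character_ else a$class, character(1))
  sig <- vapply(kb$patterns, function(p) p$significance, numeric(1))
  out_ids <- detect_outliers(kb)
  rows <- list()
  for (i in seq_along(kb$entity_ids)) {
    id <- kb$entity_ids[i]
    lab <- labels[[id]]
    if (is.na(lab) || id %in% out_ids) next
    hit <- which(kb$comprehensive[, i] == 1L & !is.na(pat_class))
    if (length(hit) == 0L) next
    if (all(pat_class[hit] != lab)) {
      w <- tapply(sig[hit], pat_class[hit], sum)
      inferred <- names(w)[order(-w, names(w))][1]
      rows[[length(rows) + 1L]] <- data.frame(
        entity = id, label = lab, inferred = inferred,
        n_support = length(hit), stringsAsFactors = FALSE)
      rows[[length(rows)]]$support <- I(list(hit))
    }
  }
  mis <- if (length(rows)) do.call(rbind, rows) else
    data.frame(entity = character(0), label = character(0),
               inferred = character(0), n_support = integer(0))
  structure(list(outliers = out_ids, mislabeled = mis),
            class = "pdd_anomalies")
}

#' @export
print.pdd_anomalies <- function(x, ...) {
  cat("Anomaly report:", length(x$outliers), "outlier(s),",
      nrow(x$mislabeled), "mislabeled\n")
  if (length(x$outliers)) cat("  outliers:", paste(utils::head(x$outliers, 10), collapse = ", "),
                              if (length(x$outliers) > 10) "..." else "", "\n")
  if (nrow(x$mislabeled)) {
    for (i in seq_len(min(nrow(x$mislabeled), 10))) {
      cat("  ", x$mislabeled$entity[i], ": labeled ", x$mislabeled$label[i],
          ", patterns say ", x$mislabeled$inferred[i],
          " (", x$mislabeled$n_support[i], " pattern(s))\n", sep = "")
    }
  }
  invisible(x)
}

#' Run both anomaly checks on a labeled fit
#'
#' @param fit a labeled \code{pdd} fit.
#' @return a \code{pdd_anomalies} report.
#' @export
anomalies <- function(fit) {
  stopifnot(inherits(fit, "pdd"))
  if (is.null(fit$associations)) stop("fit has no labels; refit with labels for mislabel detection")
  detect_mislabeled(fit$kb, labels = fit$table$labels, associations = fit$associations)
}

#' Write an anomaly report to JSON
#' @param report a \code{pdd_anomalies}.
#' @param kb the \code{pdd_kb} the report came from (for pattern AVs).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_anomalies <- function(report, kb, path) {
  obj <- list(
    outliers = lapply(report$outliers, function(id) list(entity = id, type = "outlier")),
    mislabeled = lapply(seq_len(nrow(report$mislabeled)), function(i) {
      hit <- report$mislabeled$support[[i]]
      list(entity = report$mislabeled$entity[i], type = "mislabeled",
           given_label = report$mislabeled$label[i],
           inferred_class = report$mislabeled$inferred[i],
           patterns = lapply(hit, function(j)
             list(avs = kb$patterns[[j]]$av_labels,
                  significance = kb$patterns[[j]]$significance)))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Classify new entities from a labeled fit
#'
#' Each test row is quantized through the training scheme and matched
#' against the knowledge-base patterns; unseen AV values match nothing.
#' The score of class c is the sum over matched patterns associated with c
#' of significance x confidence; the predicted class is the argmax (ties ->
#' lexicographically first class). A row matching no pattern abstains and
#' falls back to the training-majority class.
#'
#' @param object a \code{pdd} fit with labels.
#' @param newdata a \code{pdd_table} or data.frame with the training
#'   attribute schema (raw, unquantized scale).
#' @param ... unused.
#' @return data.frame with columns \code{class}, \code{abstained},
#'   \code{tie}, and one score column per class.
#' @export
predict.pdd <- function(object, newdata, ...) {
  if (is.null(object$associations)) stop("fit has no labels; cannot classify")
  if (is.data.frame(newdata)) newdata <- pdd_table(newdata)
  if (!is.null(object$scheme)) newdata <- apply_quantization(object$scheme, newdata)
  classes <- sort(names(object$priors))
  majority <- classes[which.max(object$priors[classes])]
  pat_class <- vapply(object$associations, function(a)
    if (is.null(a)) NA_character_ else a$class, character(1))
  pat_conf <- vapply(object$associations, function(a)
    if (is.null(a)) NA_real_ else a$confidence, numeric(1))
  sig <- vapply(object$kb$patterns, function(p) p$significance, numeric(1))
  pat_labs <- lapply(object$kb$patterns, function(p) p$av_labels)
  n <- nrow(newdata$values)
  scores <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  pred <- character(n); abst <- logical(n); tie <- logical(n)
  attr_names <- names(newdata$values)
  for (i in seq_len(n)) {
    row_avs <- paste0(attr_names, "=", as.character(unlist(newdata$values[i, ], use.names = FALSE)))
    matched <- which(vapply(pat_labs, function(l) all(l %in% row_avs), logical(1)) &
                       !is.na(pat_class))
    if (length(matched) == 0L) {
      pred[i] <- majority; abst[i] <- TRUE
      next
    }
    for (j in matched) {
      scores[i, pat_class[j]] <- scores[i, pat_class[j]] + sig[j] * pat_conf[j]
    }
    top <- max(scores[i, ])
    winners <- classes[scores[i, ] == top]
    pred[i] <- winners[1]
    tie[i] <- length(winners) > 1L
  }
  out <- data.frame(class = pred, abstained = abst, tie = tie,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(scores))
}

#' Evaluate a clustering against reference classes
#'
#' Clusters are mapped to classes by the optimal one-to-one assignment
#' maximizing total agreement (solved exactly by the Hungarian algorithm).
#' Accuracy is the matched fraction of all entities; unassigned entities
#' count as errors. Precision and recall are per class under that mapping;
#' the F-measure is their harmonic mean, macro-averaged. Metrics are
#' invariant to cluster relabeling.
#'
#' @param clustering a \code{pdd_clustering}.
#' @param truth per-entity class vector named by entity id (or in entity
#'   order over assigned+unassigned entities).
#' @return list with \code{accuracy}, \code{macro_f}, \code{per_class}
#'   (data.frame: class, precision, recall, f), \code{mapping} (cluster ->
#'   class).
#' @export
evaluate_clustering <- function(clustering, truth) {
  stopifnot(inherits(clustering, "pdd_clustering"))
  all_ids <- c(names(clustering$assignments), clustering$unassigned)
  if (is.null(names(truth))) {
    stopifnot(length(truth) == length(all_ids))
    names(truth) <- all_ids
  }
  n_total <- length(all_ids)
  asg <- clustering$assignments
  if (length(asg) == 0L) {
    warning("empty clustering: all metrics zero")
    classes <- sort(unique(stats::na.omit(as.character(truth))))
    return(list(accuracy = 0, macro_f = 0,
                per_class = data.frame(class = classes, precision = 0,
                                       recall = 0, f = 0),
                mapping = character(0)))
  }
  tr <- as.character(truth[names(asg)])
  clusters <- sort(unique(asg))
  classes <- sort(unique(as.character(truth[all_ids])))
  ct <- matrix(0L, length(clusters), length(classes),
               dimnames = list(as.character(clusters), classes))
  for (i in seq_along(asg)) ct[as.character(asg[i]), tr[i]] <- ct[as.character(asg[i]), tr[i]] + 1L
  # pad square and maximize agreement = minimize (max - agreement)
  k <- max(nrow(ct), ncol(ct))
  cost <- matrix(max(ct), k, k)
  cost[seq_len(nrow(ct)), seq_len(ncol(ct))] <- max(ct) - ct
  asn <- hungarian(cost)  # row -> column
  mapping <- character(0)
  matched <- 0L
  for (r in seq_len(nrow(ct))) {
    c_idx <- asn[r]
    if (c_idx <= ncol(ct)) {
      mapping[as.character(clusters[r])] <- classes[c_idx]
      matched <- matched + ct[r, c_idx]
    }
  }
  accuracy <- matched / n_total
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    r <- which(mapping == cl)
    n_cl <- sum(as.character(truth[all_ids]) == cl)
    if (length(r) == 0L) return(data.frame(class = cl, precision = 0, recall = 0, f = 0))
    kname <- names(mapping)[r]
    tp <- ct[kname, cl]
    prec <- if (sum(ct[kname, ]) == 0) 0 else tp / sum(ct[kname, ])
    rec <- if (n_cl == 0) 0 else tp / n_cl
    f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, precision = prec, recall = rec, f = f,
               stringsAsFactors = FALSE)
  }))
  list(accuracy = accuracy, macro_f = mean(per_class$f),
       per_class = per_class, mapping = mapping)
}

# Hungarian algorithm (Kuhn-Munkres, potentials form), square cost matrix,
# minimization; returns column assigned to each row.
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j+1] = row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  asn <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) asn[p[j + 1]] <- j
  asn
}

#' Repeated stratified-split classification experiment
#'
#' For each repeat: a stratified random split keeps \code{train_fraction}
#' of each class for training; accuracy is measured on the held-out rows
#' against their recorded labels. With \code{remove_anomalies} the data
#' are screened first (outlier + mislabel checks on a full-pipeline fit)
#' and flagged entities dropped. By default the screen rectifies the whole
#' dataset before splitting — anomaly removal is a data-cleaning step, and
#' a mislabeled held-out row otherwise caps measurable accuracy no matter
#' how good the classifier is; \code{anomaly_scope = "train"} instead
#' screens each training portion only, leaving the held-out rows
#' untouched. Identical seed gives identical records.
#'
#' @param table a labeled \code{pdd_table}.
#' @param train_fraction fraction of each class used for training
#'   (default 0.8).
#' @param repeats number of repeated splits (default 10).
#' @param seed RNG seed.
#' @param remove_anomalies drop flagged entities before fitting.
#' @param anomaly_scope "dataset" (default) or "train"; see above.
#' @param ... passed to \code{\link{pdd}}.
#' @return list with \code{records} (data.frame: repeat_, accuracy,
#'   n_removed, n_abstained), \code{mean}, \code{variance}.
#' @export
run_split_experiment <- function(table, train_fraction = 0.8, repeats = 10L,
                                 seed = 1L, remove_anomalies = FALSE,
                                 anomaly_scope = c("dataset", "train"), ...) {
  stopifnot(inherits(table, "pdd_table"), !is.null(table$labels))
  anomaly_scope <- match.arg(anomaly_scope)
  n_removed_global <- 0L
  if (remove_anomalies && anomaly_scope == "dataset") {
    full_fit <- pdd(table, ...)
    rep_full <- anomalies(full_fit)
    drop_ids <- c(rep_full$outliers, rep_full$mislabeled$entity)
    keep <- !(table$entity_ids %in% drop_ids)
    lab_keep <- table$labels[keep]
    if (length(drop_ids) &&
        length(unique(lab_keep[!is.na(lab_keep)])) >= 2L) {
      n_removed_global <- sum(!keep)
      table <- subset_table(table, which(keep))
    }
  }
  labels <- table$labels
  ok <- !is.na(labels)
  classes <- unique(labels[ok])
  if (length(classes) < 2L) stop("need at least 2 labeled classes")
  set.seed(seed)
  recs <- list()
  for (r in seq_len(repeats)) {
    for (attempt in 1:10) {
      tr_idx <- unlist(lapply(classes, function(cl) {
        idx <- which(ok & labels == cl)
        sample(idx, max(1L, round(train_fraction * length(idx))))
      }))
      te_idx <- setdiff(which(ok), tr_idx)
      if (length(unique(labels[tr_idx])) == length(classes) && length(te_idx) > 0) break
      message("split redrawn: a class was absent from the training portion")
    }
    train <- subset_table(table, sort(tr_idx))
    n_removed <- n_removed_global
    fit <- pdd(train, ...)
    if (remove_anomalies && anomaly_scope == "train") {
      rep0 <- anomalies(fit)
      drop_ids <- c(rep0$outliers, rep0$mislabeled$entity)
      if (length(drop_ids)) {
        keep <- !(train$entity_ids %in% drop_ids)
        # never drop a class entirely
        if (length(unique(train$labels[keep][!is.na(train$labels[keep])])) == length(classes)) {
          n_removed <- sum(!keep)
          train <- subset_table(train, which(keep))
          fit <- pdd(train, ...)
        }
      }
    }
    test <- subset_table(table, sort(te_idx))
    pr <- predict(fit, test)
    acc <- mean(pr$class == unname(test$labels))
    recs[[r]] <- data.frame(repeat_ = r, accuracy = acc,
                            n_removed = n_removed,
                            n_abstained = sum(pr$abstained))
  }
  records <- do.call(rbind, recs)
  list(records = records, mean = mean(records$accuracy),
       variance = stats::var(records$accuracy))
}

#' Subset a relational table by entity row indices
#' @param table a \code{pdd_table}.
#' @param idx integer row indices.
#' @return a \code{pdd_table} over the selected entities.
#' @export
subset_table <- function(table, idx) {
  pdd_table(table$values[idx, , drop = FALSE],
            entity_ids = table$entity_ids[idx], modes = table$modes,
            labels = if (is.null(table$labels)) NULL else unname(table$labels[idx]),
            provenance = table$provenance)
}
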