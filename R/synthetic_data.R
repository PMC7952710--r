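#' Specify a synthetic relational dataset with planted ground truth
#'
#' Defines a table whose entities fall into classes, each class carrying a
#' planted AV block (attribute -> value map). Blocks may share AVs across
#' classes to create entanglement. Each class entity takes its block's
#' value at a blocked attribute with probability \code{fidelity}, else a
#' uniformly random other value from that attribute's alphabet; non-blocked
#' attributes are uniform. Transition groups interpolate between two class
#' blocks (per-attribute Bernoulli mixture). Noise entities are all-uniform
#' and unlabeled by any block. Mislabels flip the recorded label of
#' randomly chosen class entities; the true label is kept in the ground
#' truth.
#'
#' @param n_attributes number of attributes.
#' @param class_sizes named integer vector: class -> entity count (may be
#'   imbalanced).
#' @param blocks named list: class -> named character vector (attribute
#'   name -> value). Attribute names follow "A1".."AM" unless
#'   \code{alphabets} says otherwise.
#' @param alphabets optional named list: attribute -> value universe;
#'   defaults to the block values at that attribute plus filler symbols up
#'   to size 6.
#' @param fidelity within-block co-occurrence fidelity in [0,1]
#'   (default 0.9).
#' @param noise_rate probability that a non-blocked cell is redrawn
#'   (kept for interface symmetry; non-blocked cells are uniform already).
#' @param mislabel_rate fraction of class entities whose recorded label is
#'   flipped (default 0).
#' @param n_noise_entities count of all-uniform unlabeled-structure
#'   entities appended after the classes (default 0); they keep a recorded
#'   label "noise".
#' @param transitions optional list of lists(from, to, size, fraction):
#'   groups whose entities take the \code{to}-class AV at each blocked
#'   attribute with probability \code{fraction}, else the \code{from}-class
#'   AV.
#' @param numeric_attrs optional named numeric list: attribute ->
#'   per-class means (named by class); these attributes are generated
#'   numeric (mean + N(0, sd)) instead of categorical.
#' @param numeric_sd standard deviation for numeric attributes (default 1).
#' @param seed RNG seed.
#' @return an object of class \code{pdd_synth_spec}.
#' @export
synthetic_spec <- function(n_attributes, class_sizes, blocks,
                           alphabets = NULL, fidelity = 0.9,
                           noise_rate = 0, mislabel_rate = 0,
                           n_noise_entities = 0L, transitions = NULL,
                           numeric_attrs = NULL, numeric_sd = 1,
                           seed = 1L) {
  stopifnot(fidelity >= 0, fidelity <= 1, mislabel_rate >= 0, mislabel_rate <= 1,
            noise_rate >= 0, noise_rate <= 1)
  if (is.null(names(class_sizes)) || is.null(names(blocks))) {
    stop("class_sizes and blocks must be named by class")
  }
  if (!setequal(names(class_sizes), names(blocks))) {
    stop("blocks must cover exactly the classes in class_sizes")
  }
  attr_names <- paste0("A", seq_len(n_attributes))
  for (cl in names(blocks)) {
    unknown <- setdiff(names(blocks[[cl]]), attr_names)
    if (length(unknown)) {
      stop("block for class '", cl, "' references unknown attribute(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  if (is.null(alphabets)) {
    alphabets <- lapply(attr_names, function(a) {
      vals <- unique(unlist(lapply(blocks, function(b)
        if (a %in% names(b)) b[[a]] else NULL)))
      filler <- setdiff(paste0("v", 1:9), vals)
      c(vals, filler)[seq_len(max(6, length(vals)))]
    })
    names(alphabets) <- attr_names
  }
  for (tr in transitions) {
    if (!all(c(tr$from, tr$to) %in% names(blocks))) {
      stop("transition references unknown class")
    }
  }
  structure(
    list(n_attributes = n_attributes, attr_names = attr_names,
         class_sizes = class_sizes, blocks = blocks, alphabets = alphabets,
         fidelity = fidelity, noise_rate = noise_rate,
         mislabel_rate = mislabel_rate,
         n_noise_entities = as.integer(n_noise_entities),
         transitions = transitions, numeric_attrs = numeric_attrs,
         numeric_sd = numeric_sd, seed = as.integer(seed)),
    class = "pdd_synth_spec")
}

#' Generate a synthetic table and its ground truth
#'
#' Draws the table defined by a \code{\link{synthetic_spec}}. Each spec
#' component (class blocks, transitions, noise entities, mislabels) uses
#' its own RNG stream split from the spec seed, so changing one rate never
#' perturbs the other components' draws — essential for paired
#' experiments. Fixed seed gives byte-identical output.
#'
#' @param spec a \code{pdd_synth_spec}.
#' @return list with \code{table} (a labeled \code{pdd_table}) and
#'   \code{truth} (list: true_labels, recorded_labels, mislabeled_ids,
#'   noise_ids, transition_ids, blocks, digest).
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "pdd_synth_spec"))
  set.seed(spec$seed)
  streams <- sample.int(.Machine$integer.max - 1L, 4)
  trans_sizes <- vapply(spec$transitions, function(t) t$size, numeric(1))
  n_class <- sum(spec$class_sizes)
  n <- n_class + sum(trans_sizes) + spec$n_noise_entities
  M <- spec$n_attributes
  vals <- matrix(NA_character_, n, M, dimnames = list(NULL, spec$attr_names))
  num_mat <- NULL
  numeric_cols <- names(spec$numeric_attrs)
  if (length(numeric_cols)) num_mat <- matrix(NA_real_, n, length(numeric_cols),
                                              dimnames = list(NULL, numeric_cols))
  true_labels <- character(n)
  draw_cell <- function(attr, block_val, fidelity) {
    alpha <- spec$alphabets[[attr]]
    if (!is.null(block_val) && stats::runif(1) < fidelity) return(block_val)
    others <- if (is.null(block_val)) alpha else setdiff(alpha, block_val)
    if (length(others) == 0) return(block_val)
    sample(others, 1)
  }
  row_i <- 0L
  # -- class entities
  set.seed(streams[1])
  for (cl in names(spec$class_sizes)) {
    blk <- spec$blocks[[cl]]
    for (e in seq_len(spec$class_sizes[[cl]])) {
      row_i <- row_i + 1L
      true_labels[row_i] <- cl
      for (a in spec$attr_names) {
        if (a %in% numeric_cols) {
          mu <- spec$numeric_attrs[[a]][[cl]]
          num_mat[row_i, a] <- stats::rnorm(1, mu, spec$numeric_sd)
        } else {
          vals[row_i, a] <- draw_cell(a, if (a %in% names(blk)) blk[[a]] else NULL,
                                      spec$fidelity)
        }
      }
    }
  }
  # -- transition entities
  set.seed(streams[2])
  transition_ids <- list()
  for (ti in seq_along(spec$transitions)) {
    tr <- spec$transitions[[ti]]
    ids <- integer(0)
    for (e in seq_len(tr$size)) {
      row_i <- row_i + 1L
      ids <- c(ids, row_i)
      true_labels[row_i] <- paste0("Transition", ti)
      for (a in spec$attr_names) {
        src <- spec$blocks[[tr$from]]; dst <- spec$blocks[[tr$to]]
        if (a %in% numeric_cols) {
          mu_from <- spec$numeric_attrs[[a]][[tr$from]]
          mu_to <- spec$numeric_attrs[[a]][[tr$to]]
          mu <- if (stats::runif(1) < tr$fraction) mu_to else mu_from
          num_mat[row_i, a] <- stats::rnorm(1, mu, spec$numeric_sd)
        } else {
          bv <- if (stats::runif(1) < tr$fraction) dst[[a]] else src[[a]]
          vals[row_i, a] <- draw_cell(a, bv, spec$fidelity)
        }
      }
    }
    transition_ids[[paste0("Transition", ti)]] <- ids
  }
  # -- noise entities
  set.seed(streams[3])
  noise_ids <- integer(0)
  for (e in seq_len(spec$n_noise_entities)) {
    row_i <- row_i + 1L
    noise_ids <- c(noise_ids, row_i)
    true_labels[row_i] <- "noise"
    for (a in spec$attr_names) {
      if (a %in% numeric_cols) {
        mus <- unlist(spec$numeric_attrs[[a]])
        num_mat[row_i, a] <- stats::runif(1, min(mus) - 2, max(mus) + 2)
      } else {
        vals[row_i, a] <- sample(spec$alphabets[[a]], 1)
      }
    }
  }
  # -- mislabels (class entities only)
  set.seed(streams[4])
  recorded <- true_labels
  mislabeled_ids <- integer(0)
  if (spec$mislabel_rate > 0) {
    n_flip <- round(spec$mislabel_rate * n_class)
    mislabeled_ids <- sort(sample(seq_len(n_class), n_flip))
    for (i in mislabeled_ids) {
      others <- setdiff(names(spec$class_sizes), true_labels[i])
      recorded[i] <- if (length(others) == 1) others else sample(others, 1)
    }
  }
  df <- as.data.frame(vals, stringsAsFactors = FALSE)
  if (length(numeric_cols)) for (a in numeric_cols) df[[a]] <- num_mat[, a]
  df <- df[, spec$attr_names, drop = FALSE]
  table <- pdd_table(df, labels = recorded, provenance = "synthetic")
  truth <- list(true_labels = stats::setNames(true_labels, table$entity_ids),
                recorded_labels = stats::setNames(recorded, table$entity_ids),
                mislabeled_ids = table$entity_ids[mislabeled_ids],
                noise_ids = table$entity_ids[noise_ids],
                transition_ids = lapply(transition_ids, function(i) table$entity_ids[i]),
                blocks = spec$blocks,
                attr_names = spec$attr_names,
                digest = sum(utf8ToInt(paste(c(dim(df), spec$seed), collapse = ","))))
  list(table = table, truth = truth)
}

#' Built-in synthetic presets
#'
#' Three shapes mirroring the structures the pipeline is designed for:
#' \describe{
#'   \item{apc1_like}{80 entities over 9 categorical attributes (aligned
#'     protein sites), four imbalanced classes of 30/25/20/5 with disjoint
#'     planted blocks except two deliberately shared (entangled) AVs
#'     across classes.}
#'   \item{cancer_transition_like}{two major classes (447 benign-like /
#'     235 malignant-like over 9 attributes) plus two stochastic
#'     transition groups of 30 entities each interpolating from the first
#'     class block to the second.}
#'   \item{heart_like}{270 entities, 13 mixed-mode attributes (7
#'     categorical + 6 numeric), two classes of 150/120.}
#' }
#' The presets only mirror shape (sizes, modes, group structure); they make
#' no attempt to statistically clone any real dataset.
#'
#' @param name preset name.
#' @param seed RNG seed stored in the spec.
#' @param ... overrides passed to \code{\link{synthetic_spec}} fields
#'   (fidelity, mislabel_rate, n_noise_entities).
#' @return a \code{pdd_synth_spec}.
#' @export
preset <- function(name = c("apc1_like", "cancer_transition_like", "heart_like"),
                   seed = 1L, ...) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown preset '", name[1],
         "'; available: apc1_like, cancer_transition_like, heart_like"))
  over <- list(...)
  arg <- function(key, default) if (!is.null(over[[key]])) over[[key]] else default
  if (name == "apc1_like") {
    attrs <- paste0("A", 1:9)
    mk <- function(sym) stats::setNames(paste0(sym, 1:9), attrs)
    blocks <- list(Mammal = mk("m"), Plant = mk("p"), Fungi = mk("f"),
                   Insect = mk("i"))
    # entanglement: two AVs shared across classes
    blocks$Plant[["A1"]] <- blocks$Mammal[["A1"]]   # shared Mammal/Plant AV
    blocks$Fungi[["A5"]] <- blocks$Plant[["A5"]]    # shared Plant/Fungi AV
    return(synthetic_spec(
      n_attributes = 9,
      class_sizes = c(Mammal = 30, Plant = 25, Fungi = 20, Insect = 5),
      blocks = blocks, fidelity = arg("fidelity", 0.9),
      mislabel_rate = arg("mislabel_rate", 0),
      n_noise_entities = arg("n_noise_entities", 0L), seed = seed))
  }
  if (name == "cancer_transition_like") {
    attrs <- paste0("A", 1:9)
    blocks <- list(Benign = stats::setNames(rep("low", 9), attrs),
                   Malignant = stats::setNames(rep("high", 9), attrs))
    alphabets <- stats::setNames(rep(list(c("low", "mid", "high")), 9), attrs)
    return(synthetic_spec(
      n_attributes = 9,
      class_sizes = c(Benign = 447, Malignant = 235),
      blocks = blocks, alphabets = alphabets,
      fidelity = arg("fidelity", 0.9),
      mislabel_rate = arg("mislabel_rate", 0),
      transitions = list(
        list(from = "Benign", to = "Malignant", size = 30, fraction = 0.33),
        list(from = "Benign", to = "Malignant", size = 30, fraction = 0.67)),
      seed = seed))
  }
  # heart_like: 13 mixed-mode attributes, 2 classes
  attrs <- paste0("A", 1:13)
  cat_attrs <- attrs[1:7]
  num_attrs <- attrs[8:13]
  blocks <- list(
    Absence = stats::setNames(paste0("a", 1:7), cat_attrs),
    Presence = stats::setNames(paste0("b", 1:7), cat_attrs))
  numeric_attrs <- stats::setNames(
    lapply(seq_along(num_attrs), function(i) c(Absence = 0, Presence = 3)),
    num_attrs)
  synthetic_spec(
    n_attributes = 13,
    class_sizes = c(Absence = 150, Presence = 120),
    blocks = blocks, fidelity = arg("fidelity", 0.9),
    mislabel_rate = arg("mislabel_rate", 0),
    numeric_attrs = numeric_attrs, numeric_sd = 1, seed = seed)
}

#' Score pipeline results against planted ground truth
#'
#' Three result kinds are supported. (1) A \code{pdd} fit: AV-block
#' recovery as the adjusted Rand index between planted block membership
#' and discovered SubPG membership over the planted AVs (AVs planted in
#' more than one block have no single true block and are excluded), plus
#' the count of planted classes recovered (a class counts as recovered
#' when some entity cluster maps to it with recall > 0.5 under the optimal
#' assignment). (2) A \code{pdd_clustering}: metrics from
#' \code{\link{evaluate_clustering}} against the true labels. (3) A
#' \code{pdd_anomalies} report: precision/recall against planted mislabels.
#'
#' @param result a \code{pdd}, \code{pdd_clustering} or
#'   \code{pdd_anomalies}.
#' @param truth ground truth from \code{\link{generate}}.
#' @return named list of metrics.
#' @export
score_against_truth <- function(result, truth) {
  if (inherits(result, "pdd")) {
    if (result$catalog$N != length(truth$true_labels)) {
      stop("result and truth come from different tables (size mismatch)")
    }
    # planted AV -> block map, dropping AVs shared between blocks
    planted <- list()
    for (cl in names(truth$blocks)) {
      for (a in names(truth$blocks[[cl]])) {
        lab <- paste0(a, "=", truth$blocks[[cl]][[a]])
        planted[[lab]] <- c(planted[[lab]], cl)
      }
    }
    uniq <- names(planted)[lengths(planted) == 1L]
    true_block <- vapply(planted[uniq], identity, character(1))
    # discovered membership: first DSU (by code order) whose SubPG holds the AV
    cat_labs <- result$catalog$av$label
    found <- rep(NA_character_, length(uniq))
    names(found) <- uniq
    dsus <- names(result$units)
    if (length(dsus)) {
      key <- vapply(dsus, function(d) { t <- parse_dsu(d); t[1] * 1e6 + t[2] * 1e3 + t[3] },
                    numeric(1))
      for (d in dsus[order(key)]) {
        members <- cat_labs[result$units[[d]]]
        hit <- uniq[uniq %in% members & is.na(found[uniq])]
        found[hit] <- d
      }
    }
    found[is.na(found)] <- paste0("none_", seq_len(sum(is.na(found))))
    ari <- mclust::adjustedRandIndex(unname(true_block), unname(found))
    cl <- cluster_entities(result$kb)
    ev <- evaluate_clustering(cl, truth$true_labels)
    recovered <- sum(ev$per_class$recall[ev$per_class$class %in% names(truth$blocks)] > 0.5)
    return(list(av_block_ari = ari, classes_recovered = recovered,
                clustering = ev))
  }
  if (inherits(result, "pdd_clustering")) {
    return(evaluate_clustering(result, truth$true_labels))
  }
  if (inherits(result, "pdd_anomalies")) {
    flagged <- result$mislabeled$entity
    planted <- truth$mislabeled_ids
    tp <- length(intersect(flagged, planted))
    precision <- if (length(flagged) == 0) NA_real_ else tp / length(flagged)
    recall <- if (length(planted) == 0) NA_real_ else tp / length(planted)
    return(list(precision = precision, recall = recall,
                n_flagged = length(flagged), n_planted = length(planted)))
  }
  stop("unsupported result type: ", paste(class(result), collapse = "/"))
}

#' Write a generated dataset and its ground-truth sidecar
#'
#' @param gen output of \code{\link{generate}}.
#' @param dir output directory.
#' @return named character vector of written paths.
#' @export
write_synthetic <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tpath <- file.path(dir, "table.csv")
  write_table(gen$table, tpath)
  gpath <- file.path(dir, "truth.json")
  jsonlite::write_json(gen$truth, gpath, auto_unbox = TRUE, digits = NA)
  c(table = tpath, truth = gpath)
}
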