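test_that("entities go to their max-count DSU and zero-count entities stay out", {
  g <- generate(preset("apc1_like", seed = 6))
  fit <- quiet_pdd(g$table)
  cl <- cluster_entities(fit$kb)
  expect_setequal(c(names(cl$assignments), cl$unassigned), fit$kb$entity_ids)
  expect_length(intersect(names(cl$assignments), cl$unassigned), 0)
  S <- fit$kb$summary
  for (id in names(cl$assignments)) {
    dsus_in_cluster <- cl$clusters[[as.character(cl$assignments[[id]])]]
    best <- max(S[, id])
    expect_true(any(S[dsus_in_cluster, id] == best))
  }
  for (id in cl$unassigned) expect_equal(sum(S[, id]), 0)
})

test_that("DSU clusters with identical coverage merge; overlap=1 never merges unequal ones", {
  g <- generate(two_class_spec(n = 100, m = 6, seed = 2))
  fit <- quiet_pdd(g$table)
  cl_strict <- cluster_entities(fit$kb, merge_overlap = 1.0)
  S <- fit$kb$summary
  for (cid in names(cl_strict$clusters)) {
    ds <- cl_strict$clusters[[cid]]
    if (length(ds) > 1) {
      covs <- lapply(ds, function(d) which(S[d, ] > 0))
      for (i in seq_along(covs)[-1]) expect_equal(covs[[i]], covs[[1]])
    }
  }
  # default overlap merges the redundant per-class DSUs down to the classes
  cl <- cluster_entities(fit$kb)
  ev <- evaluate_clustering(cl, g$truth$true_labels)
  expect_gte(ev$accuracy, 0.9)
})

test_that("outlier and mislabeled sets are disjoint and follow their definitions", {
  g <- generate(two_class_spec(n = 200, m = 6, mislabel_rate = 0.05, seed = 9))
  fit <- quiet_pdd(g$table)
  rep <- anomalies(fit)
  expect_length(intersect(rep$outliers, rep$mislabeled$entity), 0)
  expect_true(all(rep$mislabeled$n_support >= 1))
  # every flagged entity matches only patterns of a class != its label
  pat_class <- vapply(fit$associations, function(a)
    if (is.null(a)) NA_character_ else a$class, character(1))
  for (i in seq_len(nrow(rep$mislabeled))) {
    id <- rep$mislabeled$entity[i]
    e <- match(id, fit$kb$entity_ids)
    hit <- which(fit$kb$comprehensive[, e] == 1L & !is.na(pat_class))
    expect_true(all(pat_class[hit] != fit$table$labels[[id]]))
    expect_equal(rep$mislabeled$inferred[i],
                 names(which.max(tapply(
                   vapply(fit$kb$patterns[hit], `[[`, numeric(1), "significance"),
                   pat_class[hit], sum))))
  }
  # entities matching own-class patterns are never flagged
  flagged <- rep$mislabeled$entity
  clean <- setdiff(fit$kb$entity_ids, c(flagged, rep$outliers))
  for (id in sample(clean, 10)) {
    e <- match(id, fit$kb$entity_ids)
    hit <- which(fit$kb$comprehensive[, e] == 1L & !is.na(pat_class))
    expect_true(any(pat_class[hit] == fit$table$labels[[id]]))
  }
})

test_that("classification scores, abstention and determinism behave", {
  g <- generate(two_class_spec(n = 200, m = 6, seed = 4))
  fit <- quiet_pdd(g$table)
  # disjoint planted blocks: pattern confidences are high
  confs <- vapply(Filter(Negate(is.null), fit$associations),
                  `[[`, numeric(1), "confidence")
  expect_gt(mean(confs > 0.9), 0.9)
  # classify the training rows back: near-perfect on recorded labels
  pr <- predict(fit, fit$table)
  expect_gt(mean(pr$class == unname(fit$table$labels)), 0.95)
  # an unseen-value row matches nothing: majority fallback with abstain flag
  nomatch <- fit$table$values[1, ]
  nomatch[1, ] <- paste0("zz", seq_len(ncol(nomatch)))
  pr2 <- predict(fit, pdd_table(nomatch))
  expect_true(pr2$abstained[1])
  expect_equal(pr2$class[1], names(which.max(fit$priors)))
  # determinism: refit on same data gives identical predictions
  fit2 <- quiet_pdd(g$table)
  expect_identical(predict(fit2, fit$table), pr)
})

test_that("clustering evaluation uses the optimal assignment and ignores labels' names", {
  mk_cl <- function(asg, unassigned = character(0)) {
    structure(list(assignments = asg,
                   clusters = split(paste0("[", unique(asg), " 1 1]"), unique(asg)),
                   unassigned = unassigned), class = "pdd_clustering")
  }
  # printed 2x2 confusion toy: clusters (3,1)/(1,3) over two classes
  asg <- stats::setNames(c(1, 1, 1, 1, 2, 2, 2, 2), paste0("E", 1:8))
  truth <- stats::setNames(c("a", "a", "a", "b", "a", "b", "b", "b"), paste0("E", 1:8))
  ev <- evaluate_clustering(mk_cl(asg), truth)
  expect_equal(ev$accuracy, 0.75)
  # permuting cluster ids leaves all metrics unchanged
  asg2 <- stats::setNames(3 - unname(asg), names(asg))
  ev2 <- evaluate_clustering(mk_cl(asg2), truth)
  expect_equal(ev2$accuracy, ev$accuracy)
  expect_equal(ev2$per_class, ev$per_class)
  # perfect clustering
  ev3 <- evaluate_clustering(mk_cl(stats::setNames(c(1, 1, 2, 2), paste0("E", 1:4))),
                             stats::setNames(c("a", "a", "b", "b"), paste0("E", 1:4)))
  expect_equal(ev3$accuracy, 1.0)
  expect_equal(ev3$macro_f, 1.0)
  # unassigned entities count as errors
  ev4 <- evaluate_clustering(
    mk_cl(stats::setNames(c(1, 1, 2, 2), paste0("E", 1:4)), unassigned = "E5"),
    stats::setNames(c("a", "a", "b", "b", "a"), paste0("E", 1:5)))
  expect_equal(ev4$accuracy, 0.8)
})

test_that("the Hungarian solver matches exhaustive permutation search", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    cost <- matrix(sample(0:20, n * n, replace = TRUE), n, n)
    asn <- pddkit:::hungarian(cost)
    got <- sum(cost[cbind(seq_len(n), asn)])
    perms <- gtools_permutations(n)
    best <- min(vapply(seq_len(nrow(perms)), function(i)
      sum(cost[cbind(seq_len(n), perms[i, ])]), numeric(1)))
    expect_equal(got, best)
    expect_equal(sort(asn), seq_len(n))
  }
})

test_that("split experiments are seed-reproducible and no-op without anomalies", {
  g <- generate(two_class_spec(n = 120, m = 5, seed = 8))
  r1 <- suppressWarnings(run_split_experiment(g$table, repeats = 3, seed = 42))
  r2 <- suppressWarnings(run_split_experiment(g$table, repeats = 3, seed = 42))
  expect_identical(r1$records, r2$records)
  # zero planted anomalies: removal arm may drop nothing material
  r3 <- suppressWarnings(run_split_experiment(g$table, repeats = 3, seed = 42,
                                              remove_anomalies = TRUE))
  expect_equal(r3$mean, r1$mean, tolerance = 0.05)
  expect_error(run_split_experiment(
    pdd_table(g$table$values, labels = rep("one", nrow(g$table$values)))),
    "at least 2")
})
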