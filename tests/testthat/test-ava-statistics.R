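test_that("catalog marginals equal a brute-force column scan", {
  tab <- pdd_table(data.frame(A = c("x", "x", "y", "y"),
                              B = c("u", "v", "u", "v")))
  cat0 <- build_av_catalog(tab)
  expect_equal(cat0$av$label, c("A=x", "A=y", "B=u", "B=v"))
  expect_equal(cat0$av$n, rep(2L, 4))
  expect_equal(cat0$eids[[1]], c(1L, 2L))
  expect_equal(cat0$eids[[2]], c(3L, 4L))

  for (seed in 1:5) {
    tabr <- random_cat_table(30, 4, seed = seed)
    cr <- build_av_catalog(tabr)
    for (k in seq_len(nrow(cr$av))) {
      col <- tabr$values[[cr$av$attr[k]]]
      expect_equal(cr$av$n[k], sum(col == cr$av$value[k]))
      expect_equal(cr$eids[[k]], which(col == cr$av$value[k]))
    }
    # AVs of one attribute have disjoint EIDs summing to N
    for (j in unique(cr$av$attr)) {
      ids <- unlist(cr$eids[cr$av$attr == j])
      expect_equal(sort(ids), seq_len(cr$N))
    }
  }
})

test_that("catalog edge cases: constant AVs dropped, empty attributes error", {
  tab <- pdd_table(data.frame(A = c("x", "x"), B = c("u", "v")))
  expect_warning(catc <- build_av_catalog(tab), "constant AV")
  expect_false("A=x" %in% catc$av$label)
  tab2 <- pdd_table(data.frame(A = c(NA_character_, NA), B = c("u", "v")),
                    modes = c("categorical", "categorical"))
  expect_error(build_av_catalog(tab2), "zero non-missing")
})

test_that("EID-intersection matches an exhaustive row scan and rejects same-attribute sets", {
  tab <- pdd_table(data.frame(A = c("x", "x", "y", "x", "y", "x"),
                              B = c("u", "u", "u", "v", "v", "u"),
                              C = c("p", "q", "p", "p", "q", "p")))
  catal <- build_av_catalog(tab)
  ax <- which(catal$av$label == "A=x")
  bu <- which(catal$av$label == "B=u")
  cp <- which(catal$av$label == "C=p")
  expect_equal(eid_intersection(ax, catal), catal$eids[[ax]])
  got <- eid_intersection(c(ax, bu, cp), catal)
  want <- which(tab$values$A == "x" & tab$values$B == "u" & tab$values$C == "p")
  expect_equal(got, want)
  ay <- which(catal$av$label == "A=y")
  expect_error(eid_intersection(c(ax, ay), catal), "same attribute")
  # disjoint EID sets intersect to empty
  bv <- which(catal$av$label == "B=v")
  expect_length(eid_intersection(c(ay, bv, cp), catal), 0)
})

test_that("adjusted residual matches its closed form and error contract", {
  expect_equal(adjusted_residual(20, 20, 25, 50), 5.7735, tolerance = 1e-4)
  expect_equal(adjusted_residual(10, 20, 25, 50), 0)  # o equals expectation
  expect_error(adjusted_residual(5, 50, 25, 50), "degenerate marginal")
  expect_error(adjusted_residual(5, 0, 25, 50), "degenerate marginal")
  # monotone in o with marginals fixed
  d <- vapply(0:15, function(o) adjusted_residual(o, 20, 25, 50), numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("compound residual evaluates its closed form and restricts to pairs", {
  # N=100, marginals (50,40,20), o=10: e=4, d = 6/2/sqrt(0.24)
  d <- pddkit:::compound_residual_stat(10, c(50, 40, 20), 100)
  expect_equal(d, 6.1237, tolerance = 1e-4)
  expect_equal(pddkit:::compound_residual_stat(4, c(50, 40, 20), 100), 0)
  for (seed in 1:10) {
    tab <- random_cat_table(40, 3, seed = seed)
    catal <- build_av_catalog(tab)
    avs <- c(which(catal$av$attr == 1)[1], which(catal$av$attr == 2)[1])
    o <- length(eid_intersection(avs, catal))
    expect_equal(compound_residual(avs, catal),
                 adjusted_residual(o, catal$av$n[avs[1]], catal$av$n[avs[2]],
                                   catal$N),
                 tolerance = 1e-12)
  }
})

test_that("SR matrix agrees with the 2x2 contingency oracle on random tables", {
  for (seed in 1:10) {
    N <- sample(10:50, 1)
    M <- sample(2:5, 1)
    tab <- random_cat_table(N, M, n_values = sample(2:3, 1), seed = seed + 100)
    catal <- tryCatch(build_av_catalog(tab), warning = function(w) NULL)
    if (is.null(catal)) next
    sr <- suppressMessages(build_sr_matrix(catal))
    expect_lt(max(abs(sr - t(sr))), 1e-12)
    expect_true(all(is.finite(sr)))
    for (rep in 1:10) {
      i <- sample(nrow(catal$av), 1)
      j <- sample(which(catal$av$attr != catal$av$attr[i]), 1)
      want <- sr_oracle_pair(tab, catal$av$attr[i], catal$av$value[i],
                             catal$av$attr[j], catal$av$value[j])
      expect_equal(sr[i, j], unname(want), tolerance = 1e-9)
    }
    # same-attribute blocks and diagonal structurally zero
    same <- outer(catal$av$attr, catal$av$attr, "==")
    expect_true(all(sr[same] == 0))
  }
})

test_that("perfectly concordant binary attributes give the +/-3.1623 pattern", {
  tab <- pdd_table(data.frame(a = rep(c("1", "2"), each = 5),
                              b = rep(c("1", "2"), each = 5)))
  sr <- build_sr_matrix(build_av_catalog(tab))
  expect_equal(sr["a=1", "b=1"], 3.1623, tolerance = 1e-4)
  expect_equal(sr["a=1", "b=2"], -3.1623, tolerance = 1e-4)
})

test_that("SR is invariant under entity permutation", {
  tab <- random_cat_table(40, 4, seed = 7)
  sr1 <- suppressMessages(build_sr_matrix(build_av_catalog(tab)))
  set.seed(99)
  perm <- sample(40)
  tab2 <- subset_table(tab, perm)
  sr2 <- suppressMessages(build_sr_matrix(build_av_catalog(tab2)))
  expect_equal(sr1, sr2)
})
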