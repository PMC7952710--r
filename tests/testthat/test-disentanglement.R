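test_that("rank-one SR is recovered by a single space whose RSRV equals SR", {
  u <- c(0.8, -0.4, 0.2, -0.4)
  u <- u / sqrt(sum(u^2))
  sr <- 3 * tcrossprod(u)
  attrs <- c(1L, 1L, 2L, 2L)
  dimnames(sr) <- list(paste0("av", 1:4), paste0("av", 1:4))
  attr(sr, "attr") <- attrs
  spaces <- decompose(sr)
  lam <- vapply(spaces, function(s) s$lambda, numeric(1))
  expect_equal(sum(abs(lam) > 1e-8), 1L)
  expect_equal(unname(ds_rsrv(spaces[[1]])), unname(unclass(sr)[,]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("sum of rank-one RSRVs reconstructs SR, and re-decomposition is stable", {
  for (seed in 1:5) {
    tab <- random_cat_table(30, 4, seed = seed)
    catal <- tryCatch(build_av_catalog(tab), warning = function(w) NULL)
    if (is.null(catal)) next
    sr <- suppressMessages(build_sr_matrix(catal))
    spaces <- decompose(sr)
    recon <- Reduce(`+`, lapply(spaces, ds_rsrv))
    expect_lt(max(abs(recon - sr)), 1e-8)
    # idempotence: decomposing the reconstruction reproduces eigenvalues
    attr(recon, "attr") <- attr(sr, "attr")
    lam1 <- sort(vapply(spaces, function(s) s$lambda, numeric(1)))
    lam2 <- sort(vapply(decompose(recon), function(s) s$lambda, numeric(1)))
    expect_equal(lam1, lam2, tolerance = 1e-8)
  }
})

test_that("non-symmetric input is rejected", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  attr(m, "attr") <- c(1L, 2L)
  expect_error(decompose(m), "symmetric")
})

test_that("concordant table: leading PC separates the two value pairs by sign", {
  tab <- pdd_table(data.frame(a = rep(c("1", "2"), each = 5),
                              b = rep(c("1", "2"), each = 5)))
  sr <- build_sr_matrix(build_av_catalog(tab))
  v <- decompose(sr)[[1]]$v
  expect_equal(sign(v[["a=1"]]), sign(v[["b=1"]]))
  expect_equal(sign(v[["a=2"]]), sign(v[["b=2"]]))
  expect_true(sign(v[["a=1"]]) != sign(v[["a=2"]]))
})

test_that("space selection thresholds on cross-attribute RSRV entries", {
  # rank-one space with max |entry| = 1.5: dropped
  u <- c(1, 1, -1, -1) / 2
  sr <- 1.5 * tcrossprod(u) / max(abs(1.5 * tcrossprod(u)))
  dimnames(sr) <- list(paste0("av", 1:4), paste0("av", 1:4))
  attr(sr, "attr") <- c(1L, 2L, 1L, 2L)
  sel <- select_spaces(decompose(sr))
  expect_false(any(vapply(sel, function(s) isTRUE(s$retained), logical(1))))
  # a rank-one SR carrying the 5.7735 pair association: retained, both AVs
  # significant, and the rank-one RSRV entry equals the SR entry
  d <- adjusted_residual(20, 20, 25, 50)
  u <- c(1, 1) / sqrt(2)
  sr2 <- d * tcrossprod(u)
  dimnames(sr2) <- list(c("a=1", "b=1"), c("a=1", "b=1"))
  attr(sr2, "attr") <- c(1L, 2L)
  sel2 <- select_spaces(decompose(sr2))
  ret <- Filter(function(s) isTRUE(s$retained), sel2)
  expect_length(ret, 1)
  expect_setequal(ret[[1]]$significant_avs, 1:2)
  expect_equal(ds_rsrv(ret[[1]])["a=1", "b=1"], sr2["a=1", "b=1"],
               tolerance = 1e-8)
})

test_that("retention is per-space: dropping a middle space is representable", {
  g <- generate(preset("apc1_like", seed = 1))
  fit <- quiet_pdd(g$table)
  ret <- fit$retained
  expect_gt(length(ret), 1)
  # ordinals are positions in the |lambda| ordering, so gaps may exist
  expect_true(all(diff(ret) >= 1))
  expect_true(any(diff(seq_len(max(ret)) %in% ret) != 0) || length(ret) == max(ret))
})

test_that("pattern groups partition significant AVs by PC sign", {
  u <- c(0.6, 0.5, -0.45, -0.43)
  u <- u / sqrt(sum(u^2))
  sr <- 10 * tcrossprod(u)
  dimnames(sr) <- list(c("a=1", "b=1", "a=2", "b=2"),
                       c("a=1", "b=1", "a=2", "b=2"))
  attr(sr, "attr") <- c(1L, 2L, 1L, 2L)
  sp <- select_spaces(decompose(sr))[[1]]
  expect_true(sp$retained)
  pgs <- form_pattern_groups(sp)
  expect_equal(pgs[[1]]$side, "positive")
  m1 <- sort(names(sp$v)[pgs[[1]]$members])
  m2 <- sort(names(sp$v)[pgs[[2]]$members])
  # sign convention fixes the largest loading positive, so PG1 = {a=1, b=1}
  expect_equal(m1, c("a=1", "b=1"))
  expect_equal(m2, c("a=2", "b=2"))
  expect_true(setequal(c(m1, m2), names(sp$v)))
  # all-positive loadings leave PG2 empty
  sp2 <- select_spaces(decompose(abs(sr)))[[1]]
  pg2 <- form_pattern_groups(sp2)
  expect_length(pg2[[2]]$members, 0)
  expect_equal(form_subpgs(pg2[[2]], sp2)$subpgs, list())
})

test_that("SubPGs separate planted disjoint blocks that share a PC side", {
  # two 3-attribute co-occurring blocks plus anti-correlated background
  set.seed(42)
  n <- 120
  grp <- rep(c("g1", "g2", "bg"), times = c(40, 40, 40))
  mkcol <- function(block_val, other_vals) {
    ifelse(grp == block_val[1], block_val[2],
           sample(other_vals, n, replace = TRUE))
  }
  df <- data.frame(
    A1 = mkcol(c("g1", "x1"), c("y1", "z1")),
    A2 = mkcol(c("g1", "x2"), c("y2", "z2")),
    A3 = mkcol(c("g1", "x3"), c("y3", "z3")),
    B1 = mkcol(c("g2", "u1"), c("w1", "q1")),
    B2 = mkcol(c("g2", "u2"), c("w2", "q2")),
    B3 = mkcol(c("g2", "u3"), c("w3", "q3")))
  fit <- quiet_pdd(pdd_table(df))
  block1 <- c("A1=x1", "A2=x2", "A3=x3")
  block2 <- c("B1=u1", "B2=u2", "B3=u3")
  units <- lapply(fit$units, function(u) fit$catalog$av$label[u])
  has1 <- vapply(units, function(u) all(block1 %in% u), logical(1))
  has2 <- vapply(units, function(u) all(block2 %in% u), logical(1))
  expect_true(any(has1))
  expect_true(any(has2))
  # no unit mixes the two blocks
  mixed <- vapply(units, function(u) any(block1 %in% u) && any(block2 %in% u),
                  logical(1))
  expect_false(any(mixed))
})

test_that("DSU codes render and parse as the bracketed triple", {
  expect_equal(dsu_code(2, 1, 2), "[2 1 2]")
  expect_equal(parse_dsu("[2 1 2]"), c(2L, 1L, 2L))
  g <- generate(preset("apc1_like", seed = 2))
  fit <- quiet_pdd(g$table)
  codes <- names(fit$units)
  expect_false(anyDuplicated(codes) > 0)
  expect_true(all(grepl("^\\[\\d+ [12] \\d+\\]$", codes)))
})
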