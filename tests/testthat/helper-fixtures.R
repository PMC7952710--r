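# Fixtures are generated in code; nothing is read from disk.

# random all-categorical table: M attributes with small value alphabets
random_cat_table <- function(N, M, n_values = 3, seed = 1) {
  set.seed(seed)
  df <- as.data.frame(lapply(seq_len(M), function(j) {
    sample(paste0("v", seq_len(n_values)), N, replace = TRUE)
  }), col.names = paste0("A", seq_len(M)))
  pdd_table(df)
}

# independent reference for one SR entry: 2x2 contingency table through
# chisq.test's adjusted standardized residuals
sr_oracle_pair <- function(table, attr_a, val_a, attr_b, val_b) {
  a <- factor(table$values[[attr_a]] == val_a, levels = c(TRUE, FALSE))
  b <- factor(table$values[[attr_b]] == val_b, levels = c(TRUE, FALSE))
  suppressWarnings(stats::chisq.test(table(a, b), correct = FALSE))$stdres[1, 1]
}

# brute-force pattern miner: enumerate every legal AV subset directly
enumerate_patterns <- function(subpg, catalog, threshold, min_occurrence) {
  out <- list()
  k <- length(subpg)
  if (k < 2) return(out)
  for (sz in 2:k) {
    for (idx in utils::combn(k, sz, simplify = FALSE)) {
      avs <- subpg[idx]
      if (anyDuplicated(catalog$av$attr[avs])) next
      eids <- catalog$eids[[avs[1]]]
      for (a in avs[-1]) eids <- intersect(eids, catalog$eids[[a]])
      if (length(eids) < min_occurrence) next
      d <- pddkit:::compound_residual_stat(length(eids), catalog$av$n[avs], catalog$N)
      if (d >= threshold) {
        out[[length(out) + 1]] <- list(avs = sort(avs), eids = sort(eids), significance = d)
      }
    }
  }
  out
}

pattern_key <- function(p) paste(sort(p$avs), collapse = ",")

# canonical two-class spec with disjoint planted blocks
two_class_spec <- function(n = 500, m = 8, fidelity = 0.9, mislabel_rate = 0,
                           seed = 1) {
  attrs <- paste0("A", seq_len(m))
  blocks <- list(ClassA = stats::setNames(paste0("a", seq_len(m)), attrs),
                 ClassB = stats::setNames(paste0("b", seq_len(m)), attrs))
  synthetic_spec(m, stats::setNames(c(ceiling(n / 2), floor(n / 2)),
                                    c("ClassA", "ClassB")),
                 blocks, fidelity = fidelity, mislabel_rate = mislabel_rate,
                 seed = seed)
}

quiet_pdd <- function(...) suppressWarnings(suppressMessages(pdd(...)))

# all permutations of 1..n as rows (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
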