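# Independent oracles used across the test files. Each deliberately takes a
# different route than the package code it checks.

# Full-scan KS oracle: walk every position i = 1..n of the profile and take
# the supremum deviation between the set's empirical rank-CDF and the
# uniform CDF, instead of the j-indexed closed form over member ranks.
oracle_es <- function(member_ranks, n) {
  t <- length(member_ranks)
  counts <- tabulate(member_ranks, nbins = n)
  F <- cumsum(counts) / t              # F(i) = fraction of members at rank <= i
  i <- seq_len(n)
  a <- max(F - i / n)
  b <- max(i / n - c(0, F[-n]))
  es <- if (a > b) a else if (b > a) -b else 0
  list(es = es, a_dev = a, b_dev = b)
}

# Per-gene pooled-variance t oracle via stats::t.test (the package computes
# the statistic with vectorised row arithmetic instead).
oracle_deg <- function(expr, condition, reference,
                       fc_threshold = 2, p_threshold = 0.05) {
  ref <- condition == reference
  out <- lapply(rownames(expr), function(g) {
    x <- expr[g, ref]
    y <- expr[g, !ref]
    fc <- mean(y) / mean(x)
    p <- if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
      if (mean(x) == mean(y)) 1 else .Machine$double.xmin
    } else {
      stats::t.test(y, x, var.equal = TRUE)$p.value
    }
    dir <- if (fc > fc_threshold && p < p_threshold) "up"
           else if (fc < 1 / fc_threshold && p < p_threshold) "down"
           else "none"
    data.frame(gene = g, fold_change = fc, p_value = p, direction = dir,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Independent scoring + sort of a whole library using the full-scan oracle.
oracle_rank_library <- function(up, down, ranks, mode = "signed") {
  n <- nrow(ranks)
  scores <- vapply(colnames(ranks), function(cpd) {
    eu <- oracle_es(ranks[up, cpd], n)$es
    ed <- oracle_es(ranks[down, cpd], n)$es
    eu - ed
  }, numeric(1))
  key <- if (mode == "absolute") abs(scores) else scores
  ord <- order(-key, colnames(ranks), method = "radix")
  list(ordering = colnames(ranks)[ord], bone = scores)
}

# Small helper: a named random rank profile over n genes.
random_profile <- function(n) {
  ids <- sprintf("g%03d", seq_len(n))
  stats::setNames(sample.int(n), ids)
}
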