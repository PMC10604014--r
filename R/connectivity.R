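#' Rank-transform per-gene change scores into a compound profile
#'
#' Converts real-valued per-gene change scores (e.g. predicted expression
#' changes for one compound) into an integer rank profile over the gene
#' universe. The largest score receives rank 1, i.e. rank 1 is the gene the
#' compound upregulates most strongly. Ties are broken by ascending gene
#' identifier (byte order), so the transform is deterministic.
#'
#' @param scores Named numeric vector, one finite value per universe gene.
#'   Names are the gene identifiers and must be unique.
#' @param compound_id Optional identifier attached to the profile.
#' @return A named integer vector of ranks (a permutation of `1..n`, names =
#'   gene identifiers) with attribute `compound_id`.
#' @examples
#' rank_transform(c(g1 = 2.0, g2 = -1.0, g3 = 0.5))
#' @export
rank_transform <- function(scores, compound_id = NULL) {
  ids <- names(scores)
  if (is.null(ids) || anyDuplicated(ids) > 0L) {
    stop("scores must be named by unique gene identifiers")
  }
  bad <- !is.finite(scores)
  if (any(bad)) {
    stop("non-finite change score for gene(s): ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
  }
  n <- length(scores)
  if (n < 2L) stop("a rank profile needs a universe of at least 2 genes")
  ord <- order(-scores, ids, method = "radix")
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  names(ranks) <- ids
  attr(ranks, "compound_id") <- compound_id
  ranks
}

#' Rank-based Kolmogorov-Smirnov enrichment score of a gene set in a profile
#'
#' Measures whether the members of a query gene set concentrate near the top
#' (positive score) or bottom (negative score) of a compound's ranked
#' transcriptional profile. With `t` the number of query genes found in the
#' universe, `n` the universe size and `V(j)` the ascending-sorted ranks of
#' the members, the two directional deviations are
#' \deqn{a = \max_{j=1..t}\left(\frac{j}{t} - \frac{V(j)}{n}\right), \qquad
#'       b = \max_{j=1..t}\left(\frac{V(j)}{n} - \frac{j-1}{t}\right),}
#' and the signed enrichment score is `a` if `a > b`, `-b` if `b > a`, and 0
#' on an exact tie. This is the classical unweighted connectivity-map form of
#' the KS statistic: `a` is the largest upward excursion of the set's
#' empirical rank-CDF above the uniform CDF and `b` the largest downward one.
#'
#' Query members absent from the profile's universe are dropped with a
#' warning and reported in the result; `t` is the post-intersection count.
#'
#' @param set Character vector of query gene identifiers (duplicates are
#'   collapsed), or a list with a `members` element.
#' @param profile Named integer rank vector as returned by [rank_transform()]
#'   or a column of a simulated library: a permutation of `1..n` named by the
#'   gene universe.
#' @return An object of class `enrichment_result`: a list with elements
#'   `es`, `a_dev`, `b_dev`, `t`, `n`, and `dropped` (members not in the
#'   universe).
#' @examples
#' prof <- rank_transform(setNames(10:1, paste0("g", 1:10)))
#' enrichment_score(c("g1", "g2"), prof)
#' @export
enrichment_score <- function(set, profile) {
  if (is.list(set)) set <- set$members
  set <- unique(as.character(set))
  universe <- names(profile)
  if (is.null(universe)) stop("profile must be named by gene identifiers")
  keep <- set %in% universe
  dropped <- set[!keep]
  if (length(dropped) > 0L) {
    warning(length(dropped), " query gene(s) absent from the profile universe were dropped")
  }
  members <- set[keep]
  t <- length(members)
  if (t == 0L) stop("query set disjoint from profile universe")
  n <- length(profile)
  d <- ks_devs(sort(unname(profile[members])), n)
  structure(
    list(es = d[["es"]], a_dev = d[["a_dev"]], b_dev = d[["b_dev"]],
         t = t, n = n, dropped = dropped),
    class = "enrichment_result"
  )
}

#' @keywords internal
#' KS deviations from ascending-sorted member ranks V within a universe of n.
ks_devs <- function(V, n) {
  t <- length(V)
  j <- seq_len(t)
  a_dev <- max(j / t - V / n)
  b_dev <- max(V / n - (j - 1) / t)
  es <- if (a_dev > b_dev) a_dev else if (b_dev > a_dev) -b_dev else 0
  c(es = es, a_dev = a_dev, b_dev = b_dev)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Rank-KS enrichment: ES = %.4f (a = %.4f, b = %.4f), t = %d of n = %d\n",
              x$es, x$a_dev, x$b_dev, x$t, x$n))
  if (length(x$dropped) > 0L) {
    cat("  dropped (not in universe):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}
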