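#' Score one compound profile against a signature pair
#'
#' Computes the rank-KS enrichment score of the up-set (`es_up`, often
#' written `a`) and of the down-set (`es_down`, `b`) in one compound's rank
#' profile, and combines them into the bone score
#' `es_up - es_down`. A compound that pushes the up-set genes towards the
#' top of its profile and the down-set genes towards the bottom — i.e. one
#' that reverses the query signature — scores maximally. `abs_gap` is
#' `|es_up - es_down|`, the magnitude used by absolute-mode ranking, which
#' also admits signature mimickers.
#'
#' @param signature A `signature_pair` (or list with non-empty `up` and
#'   `down` character vectors).
#' @param profile Named integer rank vector (permutation of `1..n`), as from
#'   [rank_transform()] or one column of a simulated library.
#' @return A list of class `compound_score`: `compound_id`, `es_up`,
#'   `es_down`, `bone_score`, `abs_gap`.
#' @export
score_compound <- function(signature, profile) {
  up <- enrichment_check(signature$up, profile, "up")
  down <- enrichment_check(signature$down, profile, "down")
  bone <- up$es - down$es
  structure(
    list(compound_id = attr(profile, "compound_id"),
         es_up = up$es, es_down = down$es,
         bone_score = bone, abs_gap = abs(bone)),
    class = "compound_score"
  )
}

#' @keywords internal
enrichment_check <- function(members, profile, which_set) {
  if (length(members) == 0L) {
    stop("signature ", which_set, "-set is empty")
  }
  tryCatch(
    enrichment_score(members, profile),
    error = function(e) {
      stop("signature ", which_set, "-set: ", conditionMessage(e), call. = FALSE)
    }
  )
}

#' @export
print.compound_score <- function(x, ...) {
  cat(sprintf("Compound %s: ES_up = %.4f, ES_down = %.4f, bone score = %.4f (|a-b| = %.4f)\n",
              if (is.null(x$compound_id)) "<unnamed>" else x$compound_id,
              x$es_up, x$es_down, x$bone_score, x$abs_gap))
  invisible(x)
}

#' Rank a compound library against a signature and select candidates
#'
#' Scores every compound in a CTP library against the up/down signature
#' pair, orders the library, and selects the top `k` candidates. In
#' `signed` mode (default) compounds are ordered by bone score
#' `es_up - es_down` descending, which ranks signature *reversers* first.
#' In `absolute` mode they are ordered by `|es_up - es_down|` descending,
#' which ranks reversers and mimickers alike. `intersect` mode orders by the
#' signed score but selects only compounds in the top `k` of *both*
#' orderings. Ties are broken by ascending compound identifier.
#'
#' @param signature A `signature_pair` with non-empty `up` and `down` sets.
#' @param library Integer matrix of ranks, genes x compounds (each column a
#'   permutation of `1..n` over the shared gene universe), or a list with a
#'   `ranks` element as returned by [simulate_ctp_library()].
#' @param mode `"signed"`, `"absolute"`, or `"intersect"`.
#' @param k Number of candidates to select, between 1 and the library size.
#' @param flip If `TRUE`, swap the up- and down-sets before scoring
#'   (reverses the signature orientation, turning reverser scores into
#'   mimicker scores and vice versa).
#' @param validate If `TRUE` (default), check every column is a permutation.
#' @return An object of class `ctp_screen`: list with `scores` (data frame
#'   ordered by rank, columns `compound_id`, `es_up`, `es_down`,
#'   `bone_score`, `abs_gap`, `rank`, `selected`), `mode`, `k`, `selected`
#'   (identifiers), and `signature_provenance`.
#' @examples
#' sig <- list(up = c("g01", "g02", "g03"), down = c("g04", "g05"))
#' lib <- simulate_ctp_library(sig, n_genes = 50, n_compounds = 20,
#'                             n_reversers = 2, strength = 1, seed = 3)
#' scr <- rank_library(sig, lib, k = 5)
#' scr
#' @export
rank_library <- function(signature, library,
                         mode = c("signed", "absolute", "intersect"),
                         k = 10, flip = FALSE, validate = TRUE) {
  mode <- match.arg(mode)
  if (is.list(library) && !is.null(library$ranks)) library <- library$ranks
  if (!is.matrix(library)) stop("library must be a genes x compounds matrix of ranks")
  genes <- rownames(library)
  compounds <- colnames(library)
  if (is.null(genes) || is.null(compounds)) {
    stop("library must have gene rownames and compound colnames")
  }
  m <- ncol(library)
  if (m < 1L) stop("library is empty")
  if (k < 1 || k > m) stop("k must be between 1 and the library size (", m, ")")
  n <- nrow(library)
  if (validate) {
    ok <- apply(library, 2L, function(col) {
      all(!is.na(col)) && length(col) == n && all(sort.int(col) == seq_len(n))
    })
    if (!all(ok)) {
      stop("column(s) are not permutations of 1..", n, ": ",
           paste(utils::head(compounds[!ok], 5L), collapse = ", "))
    }
  }
  if (flip) signature <- list(up = signature$down, down = signature$up,
                              provenance = signature$provenance)
  up <- unique(as.character(signature$up))
  down <- unique(as.character(signature$down))
  if (length(up) == 0L) stop("signature up-set is empty")
  if (length(down) == 0L) stop("signature down-set is empty")
  miss_up <- setdiff(up, genes)
  miss_down <- setdiff(down, genes)
  if (length(miss_up) == length(up)) {
    stop("signature up-set is disjoint from the library universe")
  }
  if (length(miss_down) == length(down)) {
    stop("signature down-set is disjoint from the library universe")
  }
  if (length(miss_up) + length(miss_down) > 0L) {
    warning(length(miss_up) + length(miss_down),
            " signature gene(s) absent from the library universe were dropped")
  }
  up <- intersect(up, genes)
  down <- intersect(down, genes)

  up_rows <- match(up, genes)
  down_rows <- match(down, genes)
  es <- apply(library, 2L, function(col) {
    c(ks_devs(sort.int(col[up_rows]), n)[["es"]],
      ks_devs(sort.int(col[down_rows]), n)[["es"]])
  })
  es_up <- es[1L, ]
  es_down <- es[2L, ]
  bone <- es_up - es_down
  gap <- abs(bone)

  key <- if (mode == "absolute") gap else bone
  ord <- order(-key, compounds, method = "radix")
  scores <- data.frame(
    compound_id = compounds[ord],
    es_up = unname(es_up[ord]),
    es_down = unname(es_down[ord]),
    bone_score = unname(bone[ord]),
    abs_gap = unname(gap[ord]),
    rank = seq_len(m),
    stringsAsFactors = FALSE
  )
  if (mode == "intersect") {
    ord_abs <- order(-gap, compounds, method = "radix")
    selected <- intersect(scores$compound_id[seq_len(k)],
                          compounds[ord_abs][seq_len(k)])
  } else {
    selected <- scores$compound_id[seq_len(k)]
  }
  scores$selected <- scores$compound_id %in% selected

  structure(
    list(scores = scores, mode = mode, k = k, selected = selected,
         signature_provenance = signature$provenance,
         n_genes = n, n_dropped = length(miss_up) + length(miss_down)),
    class = "ctp_screen"
  )
}

#' @export
print.ctp_screen <- function(x, ...) {
  cat(sprintf("CTP library screen: %d compounds over %d genes (%s mode)\n",
              nrow(x$scores), x$n_genes, x$mode))
  if (!is.null(x$signature_provenance)) {
    cat("  signature:", x$signature_provenance, "\n")
  }
  cat(sprintf("  selected (k = %d): %s\n", x$k,
              paste(utils::head(x$selected, 10L), collapse = ", ")))
  cat("Top of the ranking:\n")
  print(utils::head(x$scores, 5L), row.names = FALSE)
  invisible(x)
}

#' @export
summary.ctp_screen <- function(object, ...) {
  s <- object$scores
  cat(sprintf("Screen of %d compounds (%s mode), k = %d\n",
              nrow(s), object$mode, object$k))
  cat("Bone score:    ")
  print(round(summary(s$bone_score), 4))
  cat("|a - b|:       ")
  print(round(summary(s$abs_gap), 4))
  cat(sprintf("Selected: %s\n", paste(object$selected, collapse = ", ")))
  invisible(object)
}

#' Scatter plot of per-compound enrichment scores
#'
#' Plots ES of the up-set (x) against ES of the down-set (y), one point per
#' compound, with selected candidates highlighted. Signature reversers fall
#' towards the lower right (up-set enriched at the top of the profile,
#' down-set at the bottom); mimickers towards the upper left.
#'
#' @param x A `ctp_screen` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.ctp_screen <- function(x, ...) {
  s <- x$scores
  graphics::plot(s$es_up, s$es_down,
                 xlab = "ES (up-set)", ylab = "ES (down-set)",
                 xlim = c(-1, 1), ylim = c(-1, 1),
                 pch = 16, col = ifelse(s$selected, "red", "grey50"),
                 main = sprintf("Compound screen (%s mode)", x$mode), ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 2)
  if (any(s$selected)) {
    graphics::legend("topleft", legend = c("selected", "other"),
                     col = c("red", "grey50"), pch = 16, bty = "n")
  }
  invisible(x)
}

#' Permutation null distribution of the bone score
#'
#' Draws `n_perm` bone scores of uniformly random disjoint up/down query
#' sets of fixed sizes against one fixed random rank profile, giving an
#' empirical null for calibrating "top-ranked" score cutoffs. Reproducible
#' under `seed`.
#'
#' @param t_up,t_down Query set sizes, each >= 1, with
#'   `t_up + t_down <= n`.
#' @param n Universe size.
#' @param n_perm Number of permutation draws, >= 1.
#' @param mode `"signed"` (bone score) or `"absolute"` (`|a - b|`).
#' @param seed Integer seed.
#' @return Object of class `perm_null`: list with `draws` (numeric vector of
#'   length `n_perm`) and the parameters. Use [quantile()] on it for
#'   empirical quantiles (type 1 step function: `quantile(x, 0)` is the
#'   minimum draw and `quantile(x, 1)` the maximum).
#' @examples
#' null <- permutation_null(10, 10, n = 200, n_perm = 500, seed = 3)
#' quantile(null, 0.95)
#' @export
permutation_null <- function(t_up, t_down, n, n_perm,
                             mode = c("signed", "absolute"), seed = 1L) {
  mode <- match.arg(mode)
  if (t_up < 1 || t_down < 1) stop("set sizes must be >= 1")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (t_up + t_down > n) {
    stop("t_up + t_down (", t_up + t_down, ") exceeds the universe size (", n, ")")
  }
  set.seed(as.integer(seed))
  universe <- make_gene_ids(n)
  profile <- sample.int(n)
  names(profile) <- universe
  draws <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, t_up + t_down)
    sc <- score_compound(list(up = universe[idx[seq_len(t_up)]],
                              down = universe[idx[t_up + seq_len(t_down)]]),
                         profile)
    if (mode == "absolute") sc$abs_gap else sc$bone_score
  }, numeric(1))
  structure(list(draws = draws, t_up = t_up, t_down = t_down, n = n,
                 n_perm = n_perm, mode = mode, seed = seed),
            class = "perm_null")
}

#' @export
quantile.perm_null <- function(x, probs = c(0.9, 0.95, 0.99), ...) {
  stats::quantile(x$draws, probs = probs, type = 1, names = TRUE)
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("Permutation null of the %s score: %d draws, t_up = %d, t_down = %d, n = %d\n",
              if (x$mode == "signed") "bone" else "|a-b|",
              x$n_perm, x$t_up, x$t_down, x$n))
  print(round(quantile(x, c(0.5, 0.9, 0.95, 0.99)), 4))
  invisible(x)
}
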