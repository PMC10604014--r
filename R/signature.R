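#' Per-gene differential expression between two conditions
#'
#' Computes, for every gene, the linear fold change between group means and a
#' two-sided pooled-variance (Student's) two-sample t-test P value, then
#' classifies each gene as `up`, `down` or `none` under strict thresholds:
#' `up` when `fold_change > fc_threshold` and `p_value < p_threshold`, `down`
#' when `fold_change < 1/fc_threshold` and `p_value < p_threshold`. The
#' defaults (fold change > 2, P < 0.05) are the conventional RNA-seq screen
#' thresholds this pipeline is built around. No multiple-testing correction
#' is applied by default; `adjust = "BH"` filters on BH-adjusted P instead.
#'
#' Fold change is the ratio of linear-scale group means, non-reference over
#' reference. A gene with reference mean 0 and non-reference mean > 0 gets
#' `fold_change = Inf`; both means 0 gives `fold_change = 1`. If the pooled
#' variance is exactly 0 the t-test is degenerate: P is set to 1 when the
#' group means are equal and to the smallest positive double (with a
#' warning) when they differ, so noise-free synthetic inputs are handled.
#'
#' @param expr Numeric matrix of non-negative linear-scale expression values,
#'   genes in rows (unique rownames), samples in columns. A list with
#'   elements `expr` and `condition` (as returned by
#'   [simulate_expression()]) is also accepted.
#' @param condition Factor or character vector with exactly two levels, one
#'   label per column of `expr`; each level needs at least 2 samples.
#' @param reference Which condition level is the reference (denominator of
#'   the fold change). Default: first level.
#' @param fc_threshold Linear fold-change threshold, > 1. Default 2.
#' @param p_threshold P-value threshold in (0, 1]. Default 0.05.
#' @param adjust `"none"` (raw P, default) or `"BH"` to threshold on
#'   Benjamini-Hochberg adjusted P values.
#' @return A `deg_table`: a data frame with columns `gene`, `fold_change`,
#'   `log2_fc`, `p_value`, `direction`, carrying the thresholds and reference
#'   level as attributes.
#' @seealso [extract_signature()]
#' @export
compute_deg <- function(expr, condition = NULL, reference = NULL,
                        fc_threshold = 2, p_threshold = 0.05,
                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.list(expr) && !is.data.frame(expr) && !is.null(expr$expr)) {
    if (is.null(condition)) condition <- expr$condition
    expr <- expr$expr
  }
  if (!is.matrix(expr) || !is.numeric(expr)) stop("expr must be a numeric matrix")
  genes <- rownames(expr)
  if (is.null(genes) || anyDuplicated(genes) > 0L) {
    stop("expr must have unique gene identifiers as rownames")
  }
  if (any(expr < 0)) stop("expression values must be non-negative")
  if (is.null(condition)) stop("condition labels are required")
  condition <- as.factor(as.character(condition))
  if (length(condition) != ncol(expr)) {
    stop("condition must label every sample: expected ", ncol(expr),
         " labels, got ", length(condition))
  }
  if (nlevels(condition) != 2L) {
    stop("condition must have exactly two levels, got ", nlevels(condition))
  }
  if (is.null(reference)) reference <- levels(condition)[1L]
  if (!reference %in% levels(condition)) {
    stop("reference level '", reference, "' not among condition levels")
  }
  counts <- table(condition)
  if (any(counts < 2L)) {
    stop("each condition needs at least 2 samples for the t-test (",
         paste(sprintf("%s: %d", names(counts), counts), collapse = ", "), ")")
  }
  if (!is.numeric(fc_threshold) || fc_threshold <= 1) {
    stop("fc_threshold must be > 1, got ", fc_threshold)
  }
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    stop("p_threshold must be in (0, 1], got ", p_threshold)
  }

  ref_cols <- condition == reference
  x_ref <- expr[, ref_cols, drop = FALSE]
  x_alt <- expr[, !ref_cols, drop = FALSE]
  n1 <- ncol(x_ref)
  n2 <- ncol(x_alt)
  m1 <- rowMeans(x_ref)
  m2 <- rowMeans(x_alt)
  v1 <- apply(x_ref, 1L, stats::var)
  v2 <- apply(x_alt, 1L, stats::var)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(tstat), df)

  degen <- sp2 == 0
  if (any(degen)) {
    eq <- degen & (m1 == m2)
    p[eq] <- 1
    if (any(degen & !eq)) {
      warning(sum(degen & !eq),
              " gene(s) with zero pooled variance but unequal means; P set to the smallest positive double")
      p[degen & !eq] <- .Machine$double.xmin
    }
  }

  fc <- m2 / m1
  fc[m1 == 0 & m2 > 0] <- Inf
  fc[m1 == 0 & m2 == 0] <- 1

  p_crit <- if (adjust == "BH") stats::p.adjust(p, method = "BH") else p
  direction <- rep("none", length(fc))
  direction[fc > fc_threshold & p_crit < p_threshold] <- "up"
  direction[fc < 1 / fc_threshold & p_crit < p_threshold] <- "down"

  out <- data.frame(
    gene = genes,
    fold_change = unname(fc),
    log2_fc = unname(log2(fc)),
    p_value = unname(p),
    direction = direction,
    stringsAsFactors = FALSE
  )
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "p_threshold") <- p_threshold
  attr(out, "reference") <- reference
  attr(out, "adjust") <- adjust
  class(out) <- c("deg_table", "data.frame")
  out
}

#' @export
print.deg_table <- function(x, ...) {
  cat(sprintf("Differential expression over %d genes (reference: %s; FC > %g, P < %g%s)\n",
              nrow(x), attr(x, "reference"), attr(x, "fc_threshold"),
              attr(x, "p_threshold"),
              if (identical(attr(x, "adjust"), "BH")) ", BH-adjusted" else ""))
  tab <- table(factor(x$direction, levels = c("up", "down", "none")))
  cat(sprintf("  up: %d  down: %d  none: %d\n", tab["up"], tab["down"], tab["none"]))
  NextMethod()
}

#' Extract the up/down signature pair from a DEG table
#'
#' Collects the genes classified `up` and `down` into a disjoint pair of
#' query gene sets, each sorted by gene identifier. Empty sets are allowed
#' here; scoring functions reject them.
#'
#' @param deg A `deg_table` from [compute_deg()].
#' @return An object of class `signature_pair`: list with character vectors
#'   `up` and `down` and a `provenance` string recording the thresholds.
#' @export
extract_signature <- function(deg) {
  if (!inherits(deg, "deg_table")) stop("deg must be a deg_table from compute_deg()")
  up <- sort(deg$gene[deg$direction == "up"], method = "radix")
  down <- sort(deg$gene[deg$direction == "down"], method = "radix")
  provenance <- sprintf(
    "FC > %g & P < %g (%s), reference = %s",
    attr(deg, "fc_threshold"), attr(deg, "p_threshold"),
    if (identical(attr(deg, "adjust"), "BH")) "BH-adjusted" else "raw",
    attr(deg, "reference"))
  structure(list(up = up, down = down, provenance = provenance),
            class = "signature_pair")
}

#' @export
print.signature_pair <- function(x, ...) {
  cat(sprintf("Signature pair: %d up, %d down (%s)\n",
              length(x$up), length(x$down), x$provenance))
  invisible(x)
}
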