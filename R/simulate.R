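#' @keywords internal
make_gene_ids <- function(n) sprintf("g%0*d", nchar(as.character(n)), seq_len(n))

#' @keywords internal
make_compound_ids <- function(m) sprintf("cpd%0*d", nchar(as.character(m)), seq_len(m))

#' Simulate a two-condition expression matrix with planted DEGs
#'
#' Generates a genes x samples matrix for a two-group design (conditions
#' `A` = reference and `B`). Each gene draws a baseline log2 mean from
#' `Normal(baseline_log2_mean, baseline_log2_sd)`; planted up genes add
#' `log2(effect_fc)` to the group-B mean and planted down genes subtract it,
#' so the planted linear fold change is exact in expectation (and exactly
#' `effect_fc` when `noise_sd = 0`). Gaussian noise with standard deviation
#' `noise_sd` is added per observation on the log2 scale and the result is
#' exponentiated, keeping all values positive. The defaults mirror a small
#' bulk RNA-seq contrast: 3 replicates per group, 4-fold planted effects,
#' 0.25 log2 units of replicate noise.
#'
#' Planted genes are placed at seeded-random positions and recorded in the
#' returned ground truth. Generation is a pure function of the arguments:
#' the same seed gives a bit-identical matrix.
#'
#' @param n_genes Number of genes (rows).
#' @param n_deg_up,n_deg_down Number of planted up-/down-regulated genes
#'   (B relative to A); their sum must not exceed `n_genes`.
#' @param n_per_group Replicates per condition, at least 2. Default 3.
#' @param effect_fc Planted linear fold change, > 1. Default 4.
#' @param noise_sd Standard deviation of per-observation log2 noise, >= 0.
#' @param baseline_log2_mean,baseline_log2_sd Baseline log2 expression
#'   distribution across genes.
#' @param seed Integer seed.
#' @return A list with elements `expr` (matrix, rownames = gene ids,
#'   colnames = sample ids), `condition` (named factor `A`/`B`),
#'   `reference` (`"A"`), and `truth` (list of `deg_up` and `deg_down` gene
#'   identifier vectors).
#' @examples
#' sim <- simulate_expression(100, n_deg_up = 5, n_deg_down = 5, seed = 1)
#' compute_deg(sim$expr, sim$condition)
#' @export
simulate_expression <- function(n_genes, n_deg_up = 0, n_deg_down = 0,
                                n_per_group = 3, effect_fc = 4,
                                noise_sd = 0.25,
                                baseline_log2_mean = 6, baseline_log2_sd = 2,
                                seed = 1L) {
  if (n_genes < 1) stop("invalid config: n_genes must be >= 1")
  if (n_deg_up < 0 || n_deg_down < 0) {
    stop("invalid config: n_deg_up and n_deg_down must be >= 0")
  }
  if (n_deg_up + n_deg_down > n_genes) {
    stop("invalid config: n_deg_up + n_deg_down (", n_deg_up + n_deg_down,
         ") exceeds n_genes (", n_genes, ")")
  }
  if (n_per_group < 2) stop("invalid config: n_per_group must be >= 2")
  if (effect_fc <= 1) stop("invalid config: effect_fc must be > 1")
  if (noise_sd < 0) stop("invalid config: noise_sd must be >= 0")

  set.seed(as.integer(seed))
  genes <- make_gene_ids(n_genes)
  samples <- c(paste0("A", seq_len(n_per_group)), paste0("B", seq_len(n_per_group)))
  condition <- factor(rep(c("A", "B"), each = n_per_group), levels = c("A", "B"))
  names(condition) <- samples

  planted <- sample.int(n_genes, n_deg_up + n_deg_down)
  up_idx <- planted[seq_len(n_deg_up)]
  down_idx <- planted[n_deg_up + seq_len(n_deg_down)]

  base <- stats::rnorm(n_genes, baseline_log2_mean, baseline_log2_sd)
  delta <- numeric(n_genes)
  delta[up_idx] <- log2(effect_fc)
  delta[down_idx] <- -log2(effect_fc)

  mu <- cbind(matrix(base, n_genes, n_per_group),
              matrix(base + delta, n_genes, n_per_group))
  noise <- matrix(stats::rnorm(length(mu), 0, noise_sd), nrow(mu), ncol(mu))
  expr <- 2^(mu + noise)
  dimnames(expr) <- list(genes, samples)

  list(expr = expr, condition = condition, reference = "A",
       truth = list(deg_up = genes[sort(up_idx)], deg_down = genes[sort(down_idx)]))
}

#' @keywords internal
#' Build one profile with forced extreme placement of signature members.
#' `top_members` go to ranks 1..k_top (random order), `bottom_members` to the
#' k_bottom bottom-most ranks; the remaining genes are randomly permuted over
#' the remaining ranks (displacement, not swapping).
forced_profile <- function(universe, top_members, bottom_members) {
  n <- length(universe)
  ranks <- integer(n)
  names(ranks) <- universe
  k_top <- length(top_members)
  k_bot <- length(bottom_members)
  if (k_top > 0L) ranks[sample(top_members)] <- seq_len(k_top)
  if (k_bot > 0L) ranks[sample(bottom_members)] <- n - k_bot + seq_len(k_bot)
  rest <- setdiff(universe, c(top_members, bottom_members))
  free <- setdiff(seq_len(n), c(seq_len(k_top), if (k_bot > 0L) n - k_bot + seq_len(k_bot)))
  # sample(free) would misbehave if free had length 1 (sampling 1:free)
  ranks[rest] <- free[sample.int(length(free))]
  ranks
}

#' Simulate a compound CTP library with planted signature-reversers
#'
#' Generates a library of compound transcriptional rank profiles (CTPs) over
#' a shared gene universe: one permutation of `1..n_genes` per compound,
#' rank 1 = most upregulated. Null compounds receive independent uniformly
#' random permutations. A planted *reverser* forces
#' `ceiling(strength * |up|)` up-set genes to the top-most ranks and
#' `ceiling(strength * |down|)` down-set genes to the bottom-most ranks
#' (remaining genes randomly permuted over the remaining ranks); a planted
#' *mimicker* does the mirror image. `strength = 0` makes planted compounds
#' indistinguishable from nulls; `strength = 1` forces the full signature.
#' The default dimensions emulate screening an FDA-approved library of 961
#' compounds over a 12,328-gene universe.
#'
#' @param signature A `signature_pair` (or list with `up`/`down` character
#'   vectors); every member must belong to the generated universe.
#' @param n_genes Universe size. Default 12328.
#' @param n_compounds Library size. Default 961.
#' @param n_reversers,n_mimickers Counts of planted non-null compounds;
#'   their sum must not exceed `n_compounds`.
#' @param strength Fraction in \[0, 1\] of each signature set forced to
#'   extreme ranks in planted compounds.
#' @param seed Integer seed.
#' @return A list with elements `ranks` (integer matrix, genes x compounds,
#'   each column a permutation of `1..n_genes`) and `truth` (list of
#'   `reversers` and `mimickers` compound identifier vectors).
#' @examples
#' sig <- list(up = c("g01", "g02"), down = c("g03", "g04"))
#' lib <- simulate_ctp_library(sig, n_genes = 50, n_compounds = 10,
#'                             n_reversers = 2, strength = 1, seed = 7)
#' @export
simulate_ctp_library <- function(signature, n_genes = 12328, n_compounds = 961,
                                 n_reversers = 0, n_mimickers = 0,
                                 strength = 1, seed = 1L) {
  if (n_genes < 2) stop("invalid config: n_genes must be >= 2")
  if (n_compounds < 1) stop("invalid config: n_compounds must be >= 1")
  if (n_reversers < 0 || n_mimickers < 0) {
    stop("invalid config: n_reversers and n_mimickers must be >= 0")
  }
  if (n_reversers + n_mimickers > n_compounds) {
    stop("invalid config: n_reversers + n_mimickers (",
         n_reversers + n_mimickers, ") exceeds n_compounds (", n_compounds, ")")
  }
  if (strength < 0 || strength > 1) {
    stop("invalid config: strength must be in [0, 1], got ", strength)
  }
  up <- unique(as.character(signature$up))
  down <- unique(as.character(signature$down))

  set.seed(as.integer(seed))
  universe <- make_gene_ids(n_genes)
  missing <- setdiff(c(up, down), universe)
  if (length(missing) > 0L) {
    stop("signature gene(s) not in the simulated universe: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  }
  compounds <- make_compound_ids(n_compounds)
  planted <- sample.int(n_compounds, n_reversers + n_mimickers)
  rev_idx <- planted[seq_len(n_reversers)]
  mim_idx <- planted[n_reversers + seq_len(n_mimickers)]

  k_up <- ceiling(strength * length(up))
  k_down <- ceiling(strength * length(down))

  ranks <- matrix(0L, n_genes, n_compounds, dimnames = list(universe, compounds))
  for (i in seq_len(n_compounds)) {
    if (i %in% rev_idx) {
      forced_up <- if (k_up > 0L) sample(up, k_up) else character(0)
      forced_down <- if (k_down > 0L) sample(down, k_down) else character(0)
      ranks[, i] <- forced_profile(universe, forced_up, forced_down)
    } else if (i %in% mim_idx) {
      forced_up <- if (k_up > 0L) sample(up, k_up) else character(0)
      forced_down <- if (k_down > 0L) sample(down, k_down) else character(0)
      ranks[, i] <- forced_profile(universe, forced_down, forced_up)
    } else {
      ranks[, i] <- sample.int(n_genes)
    }
  }

  list(ranks = ranks,
       truth = list(reversers = compounds[sort(rev_idx)],
                    mimickers = compounds[sort(mim_idx)]))
}

#' Fraction of planted reversers recovered in the top k of a ranking
#'
#' @param ranking Ordered compound identifiers (best first), or a
#'   `ctp_screen` object from [rank_library()].
#' @param truth Ground-truth list with a `reversers` element (as returned by
#'   [simulate_ctp_library()]), or a character vector of reverser ids.
#' @param k Depth of the ranking to consider; at most `length(ranking)`.
#' @return `|top-k intersect reversers| / |reversers|`, in \[0, 1\].
#' @export
recovery_rate <- function(ranking, truth, k) {
  if (inherits(ranking, "ctp_screen")) ranking <- ranking$scores$compound_id
  reversers <- if (is.list(truth)) truth$reversers else truth
  if (length(reversers) == 0L) {
    stop("recovery rate undefined: no planted reversers in ground truth")
  }
  if (k < 1 || k > length(ranking)) {
    stop("k must be between 1 and the ranking length (", length(ranking), ")")
  }
  sum(ranking[seq_len(k)] %in% reversers) / length(reversers)
}
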