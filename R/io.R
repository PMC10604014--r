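#' Read gene sets from a GMT file
#'
#' GMT is the standard tab-separated gene-set interchange format: one set
#' per line, fields `name`, `description`, then one field per member gene.
#' Lines with fewer than 3 fields raise an error naming the line; duplicate
#' members within a set are collapsed with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of gene sets, each a list with `name`,
#'   `description`, and `members` (character vector).
#' @seealso [write_gmt()], [as_signature_pair()]
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  sets <- list()
  for (i in which(keep)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields) | seq_along(fields) <= 2L]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, " in '", path,
           "': expected at least 3 tab-separated fields")
    }
    members <- fields[-(1:2)]
    if (anyDuplicated(members) > 0L) {
      warning("duplicate member(s) in set '", fields[1L], "' (line ", i,
              ") collapsed")
      members <- unique(members)
    }
    sets[[fields[1L]]] <- list(name = fields[1L], description = fields[2L],
                               members = members)
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A named list of gene sets as returned by [read_gmt()], a
#'   `signature_pair`, or a list of character vectors (names become set
#'   names, descriptions default to `"na"`).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "signature_pair")) {
    desc <- if (is.null(sets$provenance)) "na" else sets$provenance
    sets <- list(up = list(name = "up", description = desc, members = sets$up),
                 down = list(name = "down", description = desc, members = sets$down))
  }
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.character(s)) {
      s <- list(name = names(sets)[i], description = "na", members = s)
    }
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a signature pair from named gene sets
#'
#' Picks the sets named `up` and `down` (falling back to the first two sets,
#' in order) and checks they are disjoint.
#'
#' @param sets Named list of gene sets, as from [read_gmt()].
#' @return A `signature_pair`.
#' @export
as_signature_pair <- function(sets) {
  nm <- names(sets)
  if (all(c("up", "down") %in% nm)) {
    up <- sets[["up"]]; down <- sets[["down"]]
  } else if (length(sets) >= 2L) {
    up <- sets[[1L]]; down <- sets[[2L]]
  } else {
    stop("need gene sets named 'up' and 'down' (or at least two sets)")
  }
  up_m <- if (is.list(up)) up$members else up
  down_m <- if (is.list(down)) down$members else down
  both <- intersect(up_m, down_m)
  if (length(both) > 0L) {
    stop("up and down sets overlap: ", paste(utils::head(both, 5L), collapse = ", "))
  }
  prov <- if (is.list(up) && !is.null(up$description) && up$description != "na") {
    up$description
  } else "loaded from GMT"
  structure(list(up = sort(up_m, method = "radix"),
                 down = sort(down_m, method = "radix"),
                 provenance = prov),
            class = "signature_pair")
}

#' @keywords internal
read_tsv_matrix <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L) {
    stop("ragged rows in '", path, "': lines have ",
         paste(unique(nf), collapse = ", "), " fields")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids) > 0L) {
    stop("duplicate row identifier(s) in '", path, "': ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5L), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in '", path, "'")
  rownames(m) <- ids
  m
}

#' Read an expression matrix and its condition file
#'
#' The expression matrix is tab-separated with gene identifiers in the first
#' column and sample identifiers in the header; the sidecar condition file
#' has two tab-separated columns (sample, group) with a header.
#'
#' @param path Path to the expression TSV.
#' @param condition_path Path to the two-column condition TSV.
#' @return A list with `expr` (numeric matrix) and `condition` (named
#'   factor, aligned to the matrix columns).
#' @export
read_expression_matrix <- function(path, condition_path) {
  m <- read_tsv_matrix(path)
  if (any(m < 0)) stop("expression values in '", path, "' must be non-negative")
  cond <- utils::read.delim(condition_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (ncol(cond) < 2L) stop("condition file needs columns (sample, group)")
  idx <- match(colnames(m), cond[[1L]])
  if (anyNA(idx)) {
    stop("sample(s) missing from condition file: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  }
  condition <- factor(cond[[2L]][idx])
  names(condition) <- colnames(m)
  list(expr = m, condition = condition)
}

#' Write an expression matrix and its condition file
#'
#' @param sim List with `expr` and `condition`, as from
#'   [simulate_expression()] or [read_expression_matrix()].
#' @param path Output path for the expression TSV.
#' @param condition_path Output path for the condition TSV.
#' @export
write_expression_matrix <- function(sim, path, condition_path) {
  write_tsv_matrix(sim$expr, path, id_col = "gene")
  utils::write.table(
    data.frame(sample = colnames(sim$expr),
               group = as.character(sim$condition)),
    condition_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
write_tsv_matrix <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CTP library matrix of ranks or change scores
#'
#' @param path Tab-separated genes x compounds matrix, gene identifiers in
#'   the first column, compound identifiers in the header.
#' @param kind `"ranks"`: each column must already be a permutation of
#'   `1..n` (validated; rank 1 = most upregulated). `"scores"`: columns hold
#'   real-valued change scores and are rank-transformed on load via
#'   [rank_transform()].
#' @return Integer matrix of ranks, genes x compounds.
#' @export
read_ctp_library <- function(path, kind = c("ranks", "scores")) {
  kind <- match.arg(kind)
  m <- read_tsv_matrix(path)
  n <- nrow(m)
  if (kind == "ranks") {
    storage.mode(m) <- "integer"
    ok <- apply(m, 2L, function(col) all(sort.int(col) == seq_len(n)))
    if (!all(ok)) {
      stop("column(s) of '", path, "' are not permutations of 1..", n, ": ",
           paste(utils::head(colnames(m)[!ok], 5L), collapse = ", "))
    }
    m
  } else {
    ranks <- apply(m, 2L, function(col) rank_transform(stats::setNames(col, rownames(m))))
    rownames(ranks) <- rownames(m)
    storage.mode(ranks) <- "integer"
    ranks
  }
}

#' Write a CTP library matrix
#'
#' @param library Integer rank matrix, or a list with a `ranks` element.
#' @param path Output TSV path.
#' @export
write_ctp_library <- function(library, path) {
  if (is.list(library) && !is.null(library$ranks)) library <- library$ranks
  write_tsv_matrix(library, path, id_col = "gene")
}

#' Write a DEG table as CSV
#'
#' @param deg A `deg_table` from [compute_deg()].
#' @param path Output CSV path.
#' @export
write_deg_table <- function(deg, path) {
  utils::write.csv(as.data.frame(deg), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a screen report as CSV
#'
#' Columns: `compound_id`, `es_up`, `es_down`, `bone_score`, `abs_gap`,
#' `rank`, `selected`, ordered by rank. With `scatter_path`, a second CSV of
#' per-compound scatter coordinates (`compound_id`, `x` = ES up, `y` = ES
#' down, `selected`) is written for plotting.
#'
#' @param screen A `ctp_screen` from [rank_library()].
#' @param path Output CSV path.
#' @param scatter_path Optional path for the scatter-coordinates CSV.
#' @export
write_screen_report <- function(screen, path, scatter_path = NULL) {
  utils::write.csv(screen$scores, path, row.names = FALSE, quote = FALSE)
  if (!is.null(scatter_path)) {
    utils::write.csv(
      data.frame(compound_id = screen$scores$compound_id,
                 x = screen$scores$es_up, y = screen$scores$es_down,
                 selected = screen$scores$selected),
      scatter_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write ground-truth identifier lists
#'
#' One plain-text file per category (one identifier per line) in `dir`:
#' whichever of `deg_up`, `deg_down`, `reversers`, `mimickers` the truth
#' list carries.
#'
#' @param truth Ground-truth list from [simulate_expression()] or
#'   [simulate_ctp_library()].
#' @param dir Output directory (created if needed).
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(truth)) {
    writeLines(truth[[nm]], file.path(dir, paste0(nm, ".txt")))
  }
  invisible(dir)
}

#' Read ground-truth identifier lists written by [write_ground_truth()]
#'
#' @param dir Directory holding `<category>.txt` files.
#' @return Named list of character vectors.
#' @export
read_ground_truth <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0L) stop("no ground-truth .txt files in '", dir, "'")
  out <- lapply(files, function(f) {
    x <- readLines(f, warn = FALSE)
    x[nzchar(x)]
  })
  names(out) <- sub("\\.txt$", "", basename(files))
  out
}
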