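#' Construct a feature-by-sample abundance table
#'
#' The central container of the package: a nonnegative numeric matrix with
#' features as rows and samples as columns (the canonical orientation
#' throughout), carrying duplicate-free identifier axes. A table may be
#' flagged as holding proportions, in which case every sample column must sum
#' to 1: sums within `1e-6` of 1 are renormalized to exactly 1, sums further
#' away are an error, and all-zero columns are rejected.
#'
#' @param values numeric matrix, features x samples; all entries finite and
#'   nonnegative.
#' @param feature_ids,sample_ids character identifiers; default taken from
#'   `dimnames(values)`.
#' @param proportions logical; declare the columns to be proportions.
#' @return An object of class `feature_table`: a list with elements `values`
#'   (named matrix), `feature_ids`, `sample_ids`, `proportions`.
#' @examples
#' ft <- feature_table(matrix(c(2, 3, 5, 1, 0, 9), nrow = 3,
#'                            dimnames = list(paste0("F", 1:3), c("a", "b"))))
#' to_proportions(ft)
#' @export
feature_table <- function(values, feature_ids = rownames(values),
                          sample_ids = colnames(values),
                          proportions = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop_value("feature table values must be numeric")
  }
  if (is.null(feature_ids)) feature_ids <- sprintf("F%d", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(ncol(values)))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop_identifier("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(feature_ids)) {
    stop_identifier("duplicate feature identifiers: ",
                    paste(unique(feature_ids[duplicated(feature_ids)]),
                          collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop_identifier("duplicate sample identifiers: ",
                    paste(unique(sample_ids[duplicated(sample_ids)]),
                          collapse = ", "))
  }
  if (any(!is.finite(values))) stop_value("feature table contains non-finite values")
  if (any(values < 0)) stop_value("feature table contains negative values")
  dimnames(values) <- list(feature_ids, sample_ids)
  if (isTRUE(proportions) && ncol(values) > 0) {
    cs <- colSums(values)
    if (any(cs == 0)) {
      stop_degenerate("all-zero sample column(s) in a proportion table: ",
                      paste(sample_ids[cs == 0], collapse = ", "))
    }
    off <- abs(cs - 1)
    if (any(off > 1e-6)) {
      stop_value("proportion columns must sum to 1 (worst deviation ",
                 format(max(off)), ")")
    }
    if (any(off > 1e-9)) {
      values <- sweep(values, 2, cs, "/")
    }
  }
  structure(list(values = values, feature_ids = feature_ids,
                 sample_ids = sample_ids, proportions = isTRUE(proportions)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$proportions) "proportions" else "counts"))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
as.matrix.feature_table <- function(x, ...) x$values

#' Per-sample gradient metadata
#'
#' Associates one finite numeric gradient value (pH, days of decomposition,
#' ...) with each sample identifier.
#'
#' @param sample_ids character, duplicate-free.
#' @param gradient numeric, one finite value per sample.
#' @param gradient_name label for the gradient (units are the caller's).
#' @return Object of class `gradient_metadata`: a data frame with columns
#'   `sample_id` and `gradient`, attribute `gradient_name`.
#' @export
gradient_metadata <- function(sample_ids, gradient, gradient_name = "gradient") {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop_identifier("duplicate sample identifiers in metadata")
  }
  gradient <- as.numeric(gradient)
  if (length(gradient) != length(sample_ids)) {
    stop_identifier("one gradient value per sample id is required")
  }
  if (any(!is.finite(gradient))) {
    stop_value("gradient values must be finite")
  }
  structure(data.frame(sample_id = sample_ids, gradient = gradient,
                       stringsAsFactors = FALSE),
            gradient_name = as.character(gradient_name)[1],
            class = c("gradient_metadata", "data.frame"))
}

# Gradient values aligned to the given sample ids; identifier error if absent.
gradient_for <- function(meta, sample_ids) {
  idx <- match(sample_ids, meta$sample_id)
  if (anyNA(idx)) {
    stop_identifier("samples missing from metadata: ",
                    paste(sample_ids[is.na(idx)], collapse = ", "))
  }
  stats::setNames(meta$gradient[idx], sample_ids)
}

#' Read a feature table from delimited text
#'
#' Expects a header line of sample identifiers and one identifier column
#' (features as rows by default). Lines starting with `#` are treated as
#' comments, so files written by the package workflows (which carry a
#' provenance header) round-trip.
#'
#' @param path file path.
#' @param orientation `"features_as_rows"` (default) or `"samples_as_rows"`;
#'   the returned table is always features x samples.
#' @param sep field delimiter, tab by default.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path,
                               orientation = c("features_as_rows",
                                               "samples_as_rows"),
                               sep = "\t") {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 1) stop_value("no columns found in ", path)
  ids <- df[[1]]
  vals <- df[-1]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) num <- matrix(num, nrow = 1)
  if (ncol(df) == 1) num <- matrix(numeric(0), nrow = nrow(df), ncol = 0)
  if (anyNA(num)) stop_value("non-numeric cell(s) in ", path)
  if (any(num < 0)) stop_value("negative cell(s) in ", path)
  rownames(num) <- ids
  colnames(num) <- names(vals)
  if (orientation == "samples_as_rows") num <- t(num)
  feature_table(num)
}

#' Write a feature table as tab-separated text
#'
#' The file is re-readable by [read_feature_table()] into an equal table.
#' Identifiers containing the delimiter or quotes are quoted.
#'
#' @param table a [feature_table()].
#' @param path destination path.
#' @param header optional character vector written as leading `#` comment
#'   lines (provenance).
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path, header = NULL) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(feature_id = table$feature_ids,
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = TRUE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read per-sample gradient metadata from delimited text
#'
#' First column holds sample identifiers; `gradient` names the numeric
#' column to use.
#'
#' @param path file path.
#' @param gradient name of the gradient column.
#' @param sep field delimiter.
#' @return A [gradient_metadata()].
#' @export
read_gradient_metadata <- function(path, gradient, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!gradient %in% names(df)) {
    stop_identifier("gradient column '", gradient, "' not found in ", path)
  }
  gradient_metadata(df[[1]], df[[gradient]], gradient_name = gradient)
}

#' Write gradient metadata as tab-separated text
#'
#' @param meta a [gradient_metadata()].
#' @param path destination path.
#' @param header optional `#` comment lines.
#' @return Invisibly, `path`.
#' @export
write_gradient_metadata <- function(meta, path, header = NULL) {
  stopifnot(inherits(meta, "gradient_metadata"))
  df <- data.frame(sample_id = meta$sample_id, meta$gradient)
  names(df)[2] <- attr(meta, "gradient_name")
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = TRUE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Thin validating wrapper around [ape::read.tree()]: the tree must parse,
#' tip labels must be unique, and branch lengths must be nonnegative; edges
#' without a stated length get length 0.
#'
#' @param path file containing a single Newick string.
#' @return An [ape::phylo] tree.
#' @export
read_tree_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (nchar(gsub("[^(]", "", txt)) != nchar(gsub("[^)]", "", txt))) {
    stop_value("unbalanced parentheses in Newick file ", path)
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop_value("could not parse Newick file ", path)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop_identifier("duplicate tip labels: ",
                    paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                          collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0)) stop_value("negative branch lengths")
  tree
}

#' Convert a count table to per-sample proportions
#'
#' Divides every sample column by its total; zeros are preserved and the
#' operation is idempotent on proportion tables.
#'
#' @param table a [feature_table()].
#' @return A [feature_table()] flagged as proportions.
#' @export
to_proportions <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  cs <- colSums(table$values)
  if (any(cs == 0)) {
    stop_degenerate("cannot form proportions: all-zero sample(s): ",
                    paste(table$sample_ids[cs == 0], collapse = ", "))
  }
  feature_table(sweep(table$values, 2, cs, "/"), proportions = TRUE)
}

#' Centered log-ratio transform
#'
#' For each sample column `x`, returns `ln(x + pseudocount)` minus its mean
#' over features, so every transformed column sums to zero. The pseudocount
#' is added to the raw counts before anything else (never after converting to
#' proportions), the convention used for gradient-sorted heat maps of sparse
#' count tables. A pseudocount of 0 is only accepted when the table is
#' strictly positive.
#'
#' @param table a [feature_table()] of counts.
#' @param pseudocount nonnegative offset added to every count; default 1.
#' @return A features x samples numeric matrix.
#' @examples
#' ft <- feature_table(matrix(c(0, 0, 0, exp(1) - 1), 4, 1,
#'                            dimnames = list(paste0("F", 1:4), "s1")))
#' clr_transform(ft)  # (-0.25, -0.25, -0.25, 0.75)
#' @export
clr_transform <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      !is.finite(pseudocount) || pseudocount < 0) {
    stop_value("pseudocount must be a nonnegative number")
  }
  x <- table$values + pseudocount
  if (any(x <= 0)) {
    stop_value("pseudocount 0 requires a strictly positive table")
  }
  lx <- log(x)
  sweep(lx, 2, colMeans(lx), "-")
}
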