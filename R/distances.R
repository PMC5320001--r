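#' Construct a sample-by-sample distance matrix
#'
#' Validates hollowness (zero diagonal), symmetry within `1e-12`, and
#' nonnegativity, and carries sample identifiers on both axes.
#'
#' @param values square numeric matrix.
#' @param sample_ids identifiers; default from `dimnames`.
#' @return A classed symmetric matrix (`distance_matrix`).
#' @export
distance_matrix <- function(values, sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop_value("distance matrix must be square")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop_identifier("duplicate sample identifiers")
  if (any(!is.finite(values))) stop_value("non-finite distances")
  if (any(values < 0)) stop_value("negative distances")
  if (max(abs(values - t(values))) > 1e-12) stop_value("asymmetric distances")
  if (any(diag(values) != 0)) stop_value("nonzero diagonal")
  values <- (values + t(values)) / 2
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(values, class = c("distance_matrix", class(matrix())))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix over %d samples\n", ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

dm_ids <- function(dm) colnames(dm)

#' Euclidean distances between samples
#'
#' `d(i, j) = sqrt(sum_k (x_ki - x_kj)^2)` over feature rows `k`. On an
#' idealized band table this distance grows linearly with gradient
#' separation only until two samples' bands stop overlapping, after which it
#' saturates at [band_ball_radius()].
#'
#' @param table a [feature_table()].
#' @return A [distance_matrix()].
#' @export
euclidean_dm <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  distance_matrix(as.matrix(stats::dist(t(table$values))),
                  table$sample_ids)
}

#' Saturation radius of a band table
#'
#' Any two band-table samples with disjoint bands (cell value `1/B`) differ
#' in exactly `2B` cells by `1/B`, so their Euclidean distance is
#' `sqrt(2B * (1/B)^2) = sqrt(2/B)` -- once samples stop overlapping they
#' all lie on a sphere of this radius around each other, which is the
#' geometric root of the horseshoe.
#'
#' @param B band size, a positive integer.
#' @return `sqrt(2/B)`.
#' @export
band_ball_radius <- function(B) {
  if (!is.numeric(B) || any(B < 1)) stop_value("band size must be >= 1")
  sqrt(2 / B)
}

#' Chi-squared distances between samples
#'
#' The inter-sample distance induced by correspondence analysis. With the
#' table normalized to grand total 1, sample masses `r_i` and feature masses
#' `c_k`, `d(i,j) = sqrt(sum_k (P_ki/r_i - P_kj/r_j)^2 / c_k)`. Features
#' never observed (`c_k = 0`) are dropped before computing; the distance is
#' invariant to sample sequencing depth.
#'
#' @param table a [feature_table()] with positive grand total and no
#'   all-zero sample.
#' @return A [distance_matrix()].
#' @export
chisq_dm <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$values
  cs <- colSums(x)
  if (any(cs == 0)) {
    stop_degenerate("all-zero sample(s): ",
                    paste(table$sample_ids[cs == 0], collapse = ", "))
  }
  tot <- sum(x)
  if (tot <= 0) stop_value("grand total must be positive")
  P <- x / tot
  cmass <- rowSums(P)                 # feature masses
  keep <- cmass > 0
  P <- P[keep, , drop = FALSE]
  cmass <- cmass[keep]
  rmass <- colSums(P)                 # sample masses
  Q <- sweep(P, 2, rmass, "/")        # sample profiles, columns sum to 1
  Z <- Q / sqrt(cmass)
  distance_matrix(as.matrix(stats::dist(t(Z))), table$sample_ids)
}

# Logical edge x tip incidence for a rooted ape tree: row e is TRUE at the
# tips descending from edge e.
edge_tip_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  inc <- matrix(FALSE, nedge, ntip, dimnames = list(NULL, tree$tip.label))
  tree <- ape::reorder.phylo(tree, "postorder")
  node_rows <- vector("list", ntip + tree$Nnode)
  for (e in seq_len(nedge)) {
    child <- tree$edge[e, 2]
    if (child <= ntip) {
      inc[e, child] <- TRUE
    } else {
      for (r in node_rows[[child]]) inc[e, ] <- inc[e, ] | inc[r, ]
    }
    parent <- tree$edge[e, 1]
    node_rows[[parent]] <- c(node_rows[[parent]], e)
  }
  list(incidence = inc, lengths = tree$edge.length)
}

#' Unweighted UniFrac distances between samples
#'
#' Presence/absence phylogenetic dissimilarity: the branch length unique to
#' exactly one of the two samples divided by the branch length present in at
#' least one, where a branch is present in a sample if any tip descending
#' from it has nonzero abundance there. Bounded in `[0, 1]`; two samples
#' occupying disjoint tip sets of a star tree attain exactly 1. A root stem
#' (`tree$root.edge`), if any, counts only when at least one of the two
#' samples is nonempty.
#'
#' @param table a [feature_table()]; abundances are reduced to
#'   presence/absence.
#' @param tree a rooted [ape::phylo] tree whose tips cover every feature
#'   observed in the table.
#' @return A [distance_matrix()].
#' @export
unifrac_unweighted <- function(table, tree) {
  stopifnot(inherits(table, "feature_table"), inherits(tree, "phylo"))
  present_features <- table$feature_ids[rowSums(table$values) > 0]
  missing <- setdiff(present_features, tree$tip.label)
  if (length(missing)) {
    stop_identifier("features absent from the tree: ",
                    paste(missing, collapse = ", "))
  }
  et <- edge_tip_incidence(tree)
  pres <- table$values > 0
  # tip x sample presence, tips not in the table treated as absent
  tip_pres <- matrix(FALSE, length(tree$tip.label), ncol(pres),
                     dimnames = list(tree$tip.label, table$sample_ids))
  shared_tips <- intersect(rownames(tip_pres), rownames(pres))
  tip_pres[shared_tips, ] <- pres[shared_tips, , drop = FALSE]
  branch_pres <- (et$incidence %*% tip_pres) > 0   # edge x sample
  bl <- et$lengths
  n <- ncol(tip_pres)
  d <- matrix(0, n, n)
  nonempty <- colSums(tip_pres) > 0
  stem <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      a <- branch_pres[, i]
      b <- branch_pres[, j]
      uniq <- sum(bl[xor(a, b)])
      union <- sum(bl[a | b])
      if (stem > 0 && (nonempty[i] || nonempty[j])) {
        union <- union + stem
        if (xor(nonempty[i], nonempty[j])) uniq <- uniq + stem
      }
      d[i, j] <- d[j, i] <- if (union > 0) uniq / union else 0
    }
  }
  distance_matrix(d, table$sample_ids)
}

#' Earth Mover Band Aware Distance (EMBAD)
#'
#' A nonsaturating dissimilarity for gradient-structured tables. Features
#' are arranged along a line by a supplied ordering (prior knowledge of the
#' band structure, e.g. features sorted by [mean_niche_estimator()]), each
#' sample's proportions are read as a probability mass distribution over the
#' ordered positions, and the distance is the minimal total mass flow needed
#' to turn one distribution into the other -- the 1-D Wasserstein-1
#' distance, `d(i,j) = sum_k |C_ik - C_jk| * (pos_{k+1} - pos_k)` with `C`
#' the cumulative ordered proportions. Because moving mass farther always
#' costs more, the distance keeps growing with gradient separation even
#' after samples stop sharing features: it does not saturate, and its PCoA
#' places a clean gradient on axis 1 instead of a horseshoe.
#'
#' @param table a [feature_table()] of proportions (use [to_proportions()]
#'   first).
#' @param order character vector: a permutation of the table's feature ids,
#'   from one end of the gradient to the other.
#' @param positions optional numeric, nondecreasing ground positions for the
#'   ordered features; default is the rank `1..D` with unit spacing (the
#'   band-table convention, under which two band-table samples `i` and `j`
#'   are exactly `|i - j|` apart). Supply gradient values to weight by
#'   gradient instead.
#' @return A [distance_matrix()].
#' @examples
#' bt <- band_table(n_samples = 12, band_size = 4)
#' d <- embad(bt$table, bt$table$feature_ids)
#' d["S001", "S007"]  # 6
#' @export
embad <- function(table, order, positions = NULL) {
  stopifnot(inherits(table, "feature_table"))
  cs <- colSums(table$values)
  if (!table$proportions && any(abs(cs - 1) > 1e-8)) {
    stop_value("embad requires proportions; call to_proportions() first")
  }
  order <- as.character(order)
  if (length(order) != length(table$feature_ids) ||
      anyDuplicated(order) ||
      !setequal(order, table$feature_ids)) {
    stop_identifier("order must be a permutation of the table's feature ids")
  }
  D <- length(order)
  if (is.null(positions)) {
    positions <- seq_len(D)
  } else {
    if (length(positions) != D || any(!is.finite(positions))) {
      stop_value("positions must be one finite value per ordered feature")
    }
    if (is.unsorted(positions)) {
      stop_value("positions must be nondecreasing along the order")
    }
  }
  x <- table$values[order, , drop = FALSE]
  C <- apply(x, 2, cumsum)
  if (D == 1) {
    return(distance_matrix(matrix(0, ncol(x), ncol(x)), table$sample_ids))
  }
  W <- diff(positions)
  Z <- C[-D, , drop = FALSE] * W
  d <- as.matrix(stats::dist(t(Z), method = "manhattan"))
  distance_matrix(d, table$sample_ids)
}

#' Distance-saturation curve from a reference sample
#'
#' Lists the distances from a reference sample to every other sample in
#' gradient order, and estimates where the curve plateaus: the smallest rank
#' `r` such that every distance at rank `>= r` is at least
#' `(1 - epsilon) * max`. A saturating metric on a band table plateaus at
#' rank `B`; a nonsaturating one never stops increasing, so its plateau
#' estimate sits at the last rank.
#'
#' @param dm a [distance_matrix()].
#' @param reference sample id to measure from.
#' @param order character: all sample ids sorted by gradient.
#' @param epsilon plateau tolerance; default 0.01.
#' @return A list of class `saturation_curve`: data frame `curve` with
#'   columns `rank`, `sample_id`, `distance`; `plateau_rank`;
#'   `plateau_value` (the maximal distance); `reference`.
#' @export
saturation_curve <- function(dm, reference, order = dm_ids(dm),
                             epsilon = 0.01) {
  stopifnot(inherits(dm, "distance_matrix"))
  ids <- dm_ids(dm)
  if (!reference %in% ids) stop_identifier("unknown reference sample: ", reference)
  if (!setequal(order, ids) || length(order) != length(ids)) {
    stop_identifier("order must be a permutation of the matrix's samples")
  }
  others <- order[order != reference]
  d <- unclass(dm)[reference, others]
  mx <- max(d)
  ok <- d >= (1 - epsilon) * mx
  plateau <- min(which(rev(cumprod(rev(ok))) == 1))
  structure(list(curve = data.frame(rank = seq_along(others),
                                    sample_id = others,
                                    distance = unname(d)),
                 plateau_rank = plateau,
                 plateau_value = mx,
                 reference = reference,
                 epsilon = epsilon),
            class = "saturation_curve")
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat(sprintf("saturation curve from %s over %d samples: plateau at rank %d (value %.6g)\n",
              x$reference, nrow(x$curve), x$plateau_rank, x$plateau_value))
  invisible(x)
}
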