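# Multiset permutations of an integer group-assignment vector, as a matrix
# with one permutation per column. Used for the exhaustive mode; callers
# guarantee the count is small.
multiset_permutations <- function(labels) {
  rec <- function(lab) {
    if (length(lab) <= 1) return(list(lab))
    out <- list()
    for (u in unique(lab)) {
      rest <- lab[-match(u, lab)]
      for (p in rec(rest)) out[[length(out) + 1L]] <- c(u, p)
    }
    out
  }
  do.call(cbind, rec(labels))
}

count_relabelings <- function(n_g) {
  exp(lgamma(sum(n_g) + 1) - sum(lgamma(n_g + 1)))
}

# SS_within under a label assignment, from the squared-distance matrix.
ss_within <- function(D2, lab) {
  s <- 0
  for (u in unique(lab)) {
    idx <- which(lab == u)
    s <- s + sum(D2[idx, idx]) / (2 * length(idx))
  }
  s
}

#' Single-factor PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance in Anderson's
#' formulation: with `N` samples in `a` groups,
#' `SS_total = sum_{i<j} d_ij^2 / N`,
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`,
#' `SS_between = SS_total - SS_within`, and
#' `pseudo_F = (SS_between / (a - 1)) / (SS_within / (N - a))`.
#' Significance comes from permuting group labels: the p-value is
#' `(1 + #\{permuted F >= observed F\}) / (1 + permutations)` so it can
#' never drop below `1 / (permutations + 1)`. When the number of distinct
#' relabelings is at most 10,000 the permutation distribution is enumerated
#' exhaustively instead (then `p = #\{F >= observed\} / #relabelings`,
#' the identity included). Perfect separation (zero within-group distances)
#' yields `pseudo_F = Inf` and the smallest attainable p.
#'
#' @param dm a [distance_matrix()].
#' @param grouping group label per sample; if named, matched to the
#'   matrix's sample ids, otherwise taken in matrix order. Every group must
#'   have at least 2 members and there must be at least 2 groups.
#' @param permutations Monte-Carlo permutation count; default 9999.
#' @param seed RNG seed for the permutations (`NULL` uses the caller's RNG).
#' @param method `"auto"` (exhaustive when feasible, the default),
#'   `"exhaustive"`, or `"montecarlo"`.
#' @return An object of class `permanova_result`: list with `pseudo_F`,
#'   `p_value`, `permutations` (actual draws or relabelings used),
#'   `exhaustive`, `group_sizes`, `seed`, `ss` (the partition).
#' @export
permanova <- function(dm, grouping, permutations = 9999, seed = NULL,
                      method = c("auto", "exhaustive", "montecarlo")) {
  method <- match.arg(method)
  stopifnot(inherits(dm, "distance_matrix"))
  ids <- dm_ids(dm)
  if (!is.null(names(grouping))) {
    if (!all(ids %in% names(grouping))) {
      stop_identifier("grouping is missing samples: ",
                      paste(setdiff(ids, names(grouping)), collapse = ", "))
    }
    grouping <- grouping[ids]
  }
  if (length(grouping) != length(ids)) {
    stop_identifier("one group label per sample is required")
  }
  lab <- as.integer(factor(as.character(grouping)))
  n_g <- tabulate(lab)
  a <- length(n_g)
  N <- length(lab)
  if (a < 2) stop_value("need at least 2 groups")
  if (any(n_g < 2)) stop_value("singleton group(s) not allowed")
  D2 <- unclass(dm)^2
  ss_t <- sum(D2) / (2 * N)
  f_stat <- function(l) {
    ss_w <- ss_within(D2, l)
    ss_b <- ss_t - ss_w
    if (ss_w <= .Machine$double.eps * ss_t) return(Inf)
    (ss_b / (a - 1)) / (ss_w / (N - a))
  }
  f_obs <- f_stat(lab)
  n_distinct <- count_relabelings(n_g)
  if (method == "exhaustive" && n_distinct > 1e6) {
    stop_value("too many relabelings for exhaustive enumeration")
  }
  if (method == "exhaustive" ||
      (method == "auto" && n_distinct <= 10000)) {
    perms <- multiset_permutations(lab)
    f_perm <- apply(perms, 2, f_stat)
    p <- sum(f_perm >= f_obs) / ncol(perms)
    used <- ncol(perms)
    exhaustive <- TRUE
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(permutations),
             function(k) f_stat(sample(lab)), numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs)) / (1 + permutations)
    used <- permutations
    exhaustive <- FALSE
  }
  ss_w <- ss_within(D2, lab)
  structure(list(pseudo_F = f_obs, p_value = p, permutations = used,
                 exhaustive = exhaustive, group_sizes = n_g,
                 seed = seed,
                 ss = c(total = ss_t, within = ss_w,
                        between = ss_t - ss_w)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, p = %.4g (%s, %d %s; groups %s)\n",
              x$pseudo_F, x$p_value,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$permutations,
              if (x$exhaustive) "relabelings" else "permutations",
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Maximum number of well-separated points on a line segment in a ball
#'
#' Pigeonhole bound behind the impossibility of linear gradient
#' trajectories: points pairwise at least `delta` apart on a line inside a
#' ball of radius `r` lie on a segment of length at most `2r`, so at most
#' `floor(2r / delta) + 1` of them fit. A band table with `n >> B` samples
#' keeps all samples within a ball of radius [band_ball_radius()] while
#' adjacent samples stay `sqrt(2) * shift / B` apart, so for large `n` the
#' samples cannot be collinear -- the gradient is forced to curve.
#'
#' @param delta minimum pairwise separation (> 0).
#' @param r ball radius (> 0).
#' @return Integer bound `floor(2r / delta) + 1`.
#' @export
max_collinear <- function(delta, r) {
  if (!is.numeric(delta) || !is.numeric(r) || delta <= 0 || r <= 0) {
    stop_value("delta and r must be positive")
  }
  as.integer(floor(2 * r / delta + 1e-12) + 1)
}

#' Are points collinear?
#'
#' True when the second singular value of the centered point matrix is at
#' most `tolerance` times the first (all variation lies on one line).
#'
#' @param points numeric matrix, one point per row (at least 2 points).
#' @param tolerance relative singular-value tolerance; default `1e-8`.
#' @return Logical.
#' @export
is_collinear <- function(points, tolerance = 1e-8) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop_value("need at least 2 points")
  if (tolerance < 0) stop_value("tolerance must be nonnegative")
  x <- sweep(points, 2, colMeans(points), "-")
  sv <- svd(x)$d
  if (length(sv) < 2 || sv[1] == 0) return(TRUE)
  sv[2] <= tolerance * sv[1]
}
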