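# Independent oracles and fixture builders shared across the suite.

random_count_table <- function(n_features, n_samples, lambda = 5,
                               ids_with_spaces = FALSE) {
  m <- matrix(rpois(n_features * n_samples, lambda), n_features, n_samples)
  fid <- if (ids_with_spaces) {
    paste("feature", seq_len(n_features), "x")
  } else {
    paste0("F", seq_len(n_features))
  }
  sid <- paste0("S", seq_len(n_samples))
  dimnames(m) <- list(fid, sid)
  feature_table(m)
}

# 1-D optimal transport by sorted atom matching: expand two integer count
# vectors with equal totals into unit mass atoms at the given positions and
# match them in sorted order (provably optimal on the line). Independent of
# the cumulative-sum implementation.
transport_1d_oracle <- function(counts_a, counts_b, positions) {
  stopifnot(sum(counts_a) == sum(counts_b))
  atoms_a <- sort(rep(positions, counts_a))
  atoms_b <- sort(rep(positions, counts_b))
  sum(abs(atoms_a - atoms_b)) / sum(counts_a)
}

# Chi-squared distance by the literal double loop over sample pairs.
brute_chisq <- function(x) {
  x <- x[rowSums(x) > 0, , drop = FALSE]
  P <- x / sum(x)
  r <- colSums(P)
  cmass <- rowSums(P)
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((P[, i] / r[i] - P[, j] / r[j])^2 / cmass))
    }
  }
  d
}

# Unweighted UniFrac by brute-force branch enumeration using
# phangorn::Descendants (an implementation path disjoint from the package's
# postorder accumulation).
brute_unifrac_pair <- function(tree, tips_a, tips_b) {
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  in_a <- match(tips_a, tree$tip.label)
  in_b <- match(tips_b, tree$tip.label)
  uniq <- 0
  union <- 0
  for (e in seq_len(nrow(tree$edge))) {
    pa <- any(desc[[e]] %in% in_a)
    pb <- any(desc[[e]] %in% in_b)
    if (pa || pb) union <- union + tree$edge.length[e]
    if (xor(pa, pb)) uniq <- uniq + tree$edge.length[e]
  }
  if (union > 0) uniq / union else 0
}

# Greedy packing of points pairwise >= delta apart on a segment of length 2r.
line_packing_oracle <- function(delta, r) {
  pos <- 0
  count <- 1
  while (pos + delta <= 2 * r + 1e-12) {
    pos <- pos + delta
    count <- count + 1
  }
  count
}

star_tree <- function(n, bl = 1) {
  ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:%g", seq_len(n), bl), collapse = ","), ");"))
}

presence_table <- function(tips, sample_tips) {
  m <- sapply(sample_tips, function(s) as.numeric(tips %in% s))
  rownames(m) <- tips
  colnames(m) <- names(sample_tips)
  feature_table(m)
}
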