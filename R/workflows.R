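provenance_header <- function(seed, params) {
  c(paste0("embad version ", as.character(utils::packageVersion("embad"))),
    paste0("seed ", if (is.null(seed)) "none" else seed),
    paste("params", paste(names(params), unlist(params), sep = "=",
                          collapse = " ")))
}

write_coordinates <- function(ord, path, header) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  writeLines(paste0("# eigenvalues ",
                    paste(signif(ord$eigenvalues, 8), collapse = " ")), con)
  writeLines(paste0("# proportion_explained ",
                    paste(signif(ord$proportion_explained, 8),
                          collapse = " ")), con)
  df <- data.frame(sample_id = rownames(ord$coordinates), ord$coordinates)
  utils::write.table(df, con, sep = "\t", quote = TRUE, row.names = FALSE)
}

write_dm <- function(dm, path, header) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  df <- data.frame(sample_id = dm_ids(dm), unclass(dm), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = TRUE, row.names = FALSE)
}

#' End-to-end band-table demonstration
#'
#' Runs the canonical demonstration of the horseshoe effect: builds the
#' idealized band table, applies PCA, computes the Euclidean saturation
#' curve from the first sample, and writes the table, the PCA coordinates,
#' the curve and a pass/fail summary (horseshoe sign test, plateau rank
#' versus band size) to `out_dir`. Fully deterministic; a `seed` is accepted
#' only so the provenance headers always record one.
#'
#' @param out_dir output directory (created if needed).
#' @param n_samples,band_size,shift band-table parameters.
#' @param seed recorded in output headers.
#' @return Invisibly, a list with the `table`, `ordination`, `curve`,
#'   `horseshoe` test result and the output `paths`.
#' @export
run_fig1_demo <- function(out_dir, n_samples = 30, band_size = 10,
                          shift = 1, seed = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- list(n_samples = n_samples, band_size = band_size, shift = shift)
  hdr <- provenance_header(seed, params)
  bt <- band_table(n_samples, band_size, shift)
  ord <- ordinate_pca(bt$table, n_axes = 2)
  dm <- euclidean_dm(bt$table)
  g <- gradient_for(bt$metadata, bt$table$sample_ids)
  curve <- saturation_curve(dm, bt$table$sample_ids[1],
                            order = names(sort(g)))
  hs <- horseshoe_test(ord, g)
  paths <- file.path(out_dir, c(table = "band_table.tsv",
                                coords = "pca_coordinates.tsv",
                                curve = "saturation_curve.tsv",
                                summary = "summary.tsv"))
  names(paths) <- c("table", "coords", "curve", "summary")
  write_feature_table(bt$table, paths[["table"]], header = hdr)
  write_coordinates(ord, paths[["coords"]], hdr)
  con <- file(paths[["curve"]], "wt")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(curve$curve, con, sep = "\t", quote = TRUE,
                     row.names = FALSE)
  close(con)
  summary <- data.frame(
    check = c("horseshoe_sign_test", "axis1_spearman", "plateau_rank",
              "plateau_value", "expected_plateau_rank",
              "expected_plateau_value"),
    value = c(as.character(hs$endpoint_sign_horseshoe && hs$arch$arch),
              format(hs$axis1_spearman), format(curve$plateau_rank),
              format(curve$plateau_value), format(band_size),
              format(band_ball_radius(band_size))))
  con <- file(paths[["summary"]], "wt")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(summary, con, sep = "\t", quote = TRUE,
                     row.names = FALSE)
  close(con)
  invisible(list(table = bt$table, ordination = ord, curve = curve,
                 horseshoe = hs, paths = paths))
}

# Extreme-gradient grouping: bottom vs top fraction of the gradient.
extreme_gradient_groups <- function(meta, fraction = 0.25) {
  g <- stats::setNames(meta$gradient, meta$sample_id)
  qs <- stats::quantile(g, c(fraction, 1 - fraction), names = FALSE)
  grp <- rep(NA_character_, length(g))
  grp[g <= qs[1]] <- "low"
  grp[g >= qs[2]] <- "high"
  stats::setNames(grp, names(g))
}

#' Compare distance metrics on one gradient data set
#'
#' For each requested metric this computes the distance matrix, its PCoA,
#' the saturation curve from the gradient-minimal sample, the arch
#' diagnostic, and a PERMANOVA contrasting the low versus high extremes of
#' the gradient (bottom vs top quartile by default). EMBAD uses the feature
#' ordering given by [mean_niche_estimator()] on the same gradient. One
#' summary row per metric is returned and everything is written to
#' `out_dir`.
#'
#' @param table a [feature_table()] of counts or proportions.
#' @param metadata a [gradient_metadata()] covering the samples.
#' @param metrics subset of `c("euclidean", "chisq", "unifrac", "embad")`.
#' @param tree rooted [ape::phylo]; required iff `"unifrac"` is requested.
#' @param group_fraction gradient fraction defining each extreme group.
#' @param permutations,seed passed to [permanova()].
#' @param out_dir output directory.
#' @return Invisibly, a list with `summary` (data frame, one row per
#'   metric) and per-metric results.
#' @export
run_metric_comparison <- function(table, metadata,
                                  metrics = c("euclidean", "chisq", "embad"),
                                  tree = NULL, group_fraction = 0.25,
                                  permutations = 999, seed = 0,
                                  out_dir = NULL) {
  metrics <- match.arg(metrics,
                       c("euclidean", "chisq", "unifrac", "embad"),
                       several.ok = TRUE)
  if ("unifrac" %in% metrics && is.null(tree)) {
    stop_value("metric 'unifrac' requires a tree")
  }
  g <- gradient_for(metadata, table$sample_ids)
  ord_samples <- names(sort(g))
  grp_all <- extreme_gradient_groups(metadata, group_fraction)
  keep <- names(grp_all)[!is.na(grp_all)]
  keep <- intersect(table$sample_ids, keep)
  props <- to_proportions(table)
  est <- mean_niche_estimator(table, metadata)
  forder <- c(est$feature_id[order(est$mean_gradient, est$feature_id)],
              attr(est, "excluded"))
  hdr <- provenance_header(seed, list(metrics = paste(metrics, collapse = ","),
                                      group_fraction = group_fraction,
                                      permutations = permutations))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  results <- list()
  rows <- list()
  for (m in metrics) {
    dm <- switch(m,
                 euclidean = euclidean_dm(props),
                 chisq = chisq_dm(table),
                 unifrac = unifrac_unweighted(table, tree),
                 embad = embad(props, forder))
    ord <- ordinate_pcoa(dm, n_axes = 2)
    curve <- saturation_curve(dm, ord_samples[1], order = ord_samples)
    hs <- horseshoe_test(ord, g)
    sub_ids <- keep
    sub <- distance_matrix(unclass(dm)[sub_ids, sub_ids], sub_ids)
    pmv <- permanova(sub, grp_all[sub_ids], permutations = permutations,
                     seed = seed)
    results[[m]] <- list(dm = dm, ordination = ord, curve = curve,
                         horseshoe = hs, permanova = pmv)
    rows[[m]] <- data.frame(
      metric = m,
      axis1_spearman = hs$axis1_spearman,
      arch = hs$arch$arch,
      curvature = hs$arch$curvature,
      plateau_rank = curve$plateau_rank,
      plateau_value = curve$plateau_value,
      pseudo_F = pmv$pseudo_F,
      p_value = pmv$p_value)
    if (!is.null(out_dir)) {
      write_dm(dm, file.path(out_dir, paste0(m, "_dm.tsv")), hdr)
      write_coordinates(ord, file.path(out_dir, paste0(m, "_pcoa.tsv")), hdr)
      con <- file(file.path(out_dir, paste0(m, "_saturation.tsv")), "wt")
      writeLines(paste0("# ", hdr), con)
      utils::write.table(curve$curve, con, sep = "\t", quote = TRUE,
                         row.names = FALSE)
      close(con)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    con <- file(file.path(out_dir, "summary.tsv"), "wt")
    writeLines(paste0("# ", hdr), con)
    utils::write.table(summary, con, sep = "\t", quote = TRUE,
                       row.names = FALSE)
    close(con)
  }
  invisible(list(summary = summary, results = results))
}
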