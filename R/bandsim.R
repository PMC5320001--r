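#' Simulate an idealized band table
#'
#' Builds the canonical band matrix: sample `j` (0-based) occupies `band_size`
#' consecutive feature rows starting at row `j * shift`, every nonzero cell
#' holding `value`. With the default `value = 1/band_size` each sample column
#' sums to 1, so the table is a proportion table. The gradient attached to
#' the samples is simply the sample index `0, 1, 2, ...`: for a band table
#' the sample order *is* the gradient.
#'
#' @param n_samples number of samples (columns); default 30.
#' @param band_size `B`, the number of nonzero features per sample;
#'   default 10.
#' @param shift rows each successive sample is shifted down by; default 1.
#' @param value value of each nonzero cell; default `1/band_size`.
#' @return A list with elements `table` (a [feature_table()] of
#'   `(n_samples - 1) * shift + band_size` features by `n_samples` samples)
#'   and `metadata` (a [gradient_metadata()] with gradient = sample index).
#' @examples
#' bt <- band_table(n_samples = 30, band_size = 10)
#' colSums(bt$table$values)[1:3]  # all 1
#' @export
band_table <- function(n_samples = 30, band_size = 10, shift = 1,
                       value = 1 / band_size) {
  if (n_samples < 1 || band_size < 1 || shift < 1) {
    stop_value("n_samples, band_size and shift must be positive integers")
  }
  if (value <= 0) stop_value("cell value must be positive")
  n_samples <- as.integer(n_samples)
  band_size <- as.integer(band_size)
  shift <- as.integer(shift)
  n_features <- (n_samples - 1L) * shift + band_size
  fid <- sprintf("F%03d", seq_len(n_features))
  sid <- sprintf("S%03d", seq_len(n_samples))
  m <- matrix(0, n_features, n_samples, dimnames = list(fid, sid))
  for (j in seq_len(n_samples)) {
    m[(j - 1L) * shift + seq_len(band_size), j] <- value
  }
  prop <- abs(band_size * value - 1) <= 1e-9
  list(table = feature_table(m, proportions = prop),
       metadata = gradient_metadata(sid, seq_len(n_samples) - 1,
                                    gradient_name = "sample_index"))
}

#' Simulate a niche-gradient count table
#'
#' Emulates a community sampled along an environmental gradient under niche
#' differentiation: each feature responds to the gradient with a Gaussian
#' niche curve centered on its optimum, and counts are Poisson draws around
#' the expected intensities. Samples and feature optima are evenly spaced
#' across `gradient_range`; the expected count of feature `f` in sample `i`
#' is proportional to `exp(-(g_i - mu_f)^2 / (2 sigma^2))`, rescaled so each
#' sample's expected total is `depth`. Defaults mirror a soil pH survey:
#' 88 samples spanning pH 3 to 9, 200 taxa, niche width 1 pH unit, and an
#' expected sequencing depth of 10,000 counts per sample.
#'
#' @param n_samples,n_features table dimensions.
#' @param gradient_range numeric length-2 interval for the gradient.
#' @param sigma niche width (same units as the gradient); must be positive.
#' @param depth expected total count per sample.
#' @param seed integer RNG seed for the Poisson draws (`NULL` uses the
#'   caller's RNG state).
#' @return A list with `table` (count [feature_table()]), `metadata`
#'   ([gradient_metadata()]), and `optima` (named numeric of true niche
#'   optima per feature, for parameter-recovery checks).
#' @export
niche_table <- function(n_samples = 88, n_features = 200,
                        gradient_range = c(3, 9), sigma = 1,
                        depth = 1e4, seed = NULL) {
  if (n_samples < 1 || n_features < 1) {
    stop_value("n_samples and n_features must be positive")
  }
  if (!is.numeric(sigma) || sigma <= 0) stop_value("sigma must be positive")
  if (depth <= 0) stop_value("depth must be positive")
  g <- seq(gradient_range[1], gradient_range[2], length.out = n_samples)
  mu <- seq(gradient_range[1], gradient_range[2], length.out = n_features)
  fid <- sprintf("F%04d", seq_len(n_features))
  sid <- sprintf("S%03d", seq_len(n_samples))
  w <- exp(-outer(mu, g, "-")^2 / (2 * sigma^2))   # features x samples
  lambda <- sweep(w, 2, colSums(w), "/") * depth
  counts <- with_seed(seed, {
    matrix(stats::rpois(length(lambda), lambda), n_features, n_samples)
  })
  dimnames(counts) <- list(fid, sid)
  list(table = feature_table(counts),
       metadata = gradient_metadata(sid, g, gradient_name = "gradient"),
       optima = stats::setNames(mu, fid))
}

#' Expected site divergence under equal-frequency substitution
#'
#' The saturation analogue from molecular evolution: two lineages evolving
#' independently at substitution rate `rate` per site under an
#' equal-base-frequency (Jukes-Cantor) model show an expected fraction of
#' mismatching sites of `0.75 * (1 - exp(-8 * rate * t / 3))` after
#' divergence time `t`, plateauing at exactly 0.75 as `t -> Inf` -- i.e.
#' sequence identity saturates at 25% no matter how much time elapses, the
#' direct analogue of community-distance saturation.
#'
#' @param t divergence time per lineage (`Inf` for the plateau).
#' @param rate substitution rate per site per unit time; default 1.
#' @return Expected fraction of mismatching sites, in `[0, 0.75]`.
#' @examples
#' substitution_saturation(0)    # 0
#' substitution_saturation(Inf)  # 0.75
#' @export
substitution_saturation <- function(t, rate = 1) {
  if (!is.numeric(t) || any(is.na(t)) || any(t < 0)) {
    stop_value("t must be nonnegative")
  }
  if (rate <= 0) stop_value("rate must be positive")
  0.75 * (1 - exp(-8 * rate * t / 3))
}
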