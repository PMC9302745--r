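# Summary "signature" features of observed (relative) count data.
#
# These are the per-data-set statistics used downstream to predict a
# method's sensitivity and specificity from the relative abundances
# alone: sparsity (zero/one-count proportions, dropout), the shape of
# the abundance distribution per condition, evenness, the sampled
# distribution of pairwise feature correlations on CLR-transformed
# counts, and the prevalence and spread of apparent per-feature fold
# change between conditions.

.sig_large_lfc <- 1   # |delta log2 vs mean delta| >= 1 counts as "large"
.sig_max_corr_features <- 500L

.gini <- function(p) {
  p <- sort(p)
  n <- length(p)
  if (sum(p) == 0) return(0)
  sum((2 * seq_len(n) - n - 1) * p) / (n * sum(p))
}

.pielou <- function(p) {
  p <- p[p > 0] / sum(p)
  if (length(p) <= 1) return(0)
  -sum(p * log(p)) / log(length(p))
}

# run code with a private RNG stream, restoring the caller's state
with_private_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Registry of signature features
#'
#' Stable, ordered list of every signature with a one-line definition.
#'
#' @return data.frame with columns `name` and `definition`.
#' @export
signature_registry <- function() {
  q_names <- function(cond) paste0("logq", c(0, 25, 50, 75, 100), "_c", cond)
  defs <- c(
    prop_zero = "proportion of zero entries in Z",
    prop_zero_c1 = "proportion of zero entries, condition 1",
    prop_zero_c2 = "proportion of zero entries, condition 2",
    prop_one = "proportion of entries equal to 1 in Z",
    prop_one_c1 = "proportion of one-count entries, condition 1",
    prop_one_c2 = "proportion of one-count entries, condition 2",
    dropout_change = "prop_zero_c2 - prop_zero_c1",
    prop_unobserved_c1 = "fraction of features with zero total, condition 1",
    prop_unobserved_c2 = "fraction of features with zero total, condition 2",
    stats::setNames(rep("quantile of log1p per-feature mean counts", 10),
                    c(q_names(1), q_names(2))),
    mean_log_c1 = "mean log1p per-feature mean count, condition 1",
    sd_log_c1 = "sd of log1p per-feature mean counts, condition 1",
    mean_log_c2 = "mean log1p per-feature mean count, condition 2",
    sd_log_c2 = "sd of log1p per-feature mean counts, condition 2",
    evenness_c1 = "Pielou evenness of mean proportions, condition 1",
    evenness_c2 = "Pielou evenness of mean proportions, condition 2",
    evenness_change = "evenness_c2 - evenness_c1",
    gini_c1 = "Gini coefficient of mean proportions, condition 1",
    gini_c2 = "Gini coefficient of mean proportions, condition 2",
    corr_mean = "mean of sampled pairwise CLR feature correlations",
    corr_median = "median of sampled pairwise CLR feature correlations",
    corr_sd = "sd of sampled pairwise CLR feature correlations",
    corr_skew = "adjusted Fisher-Pearson skewness of sampled correlations",
    corr_prop_strong = "fraction of sampled correlations with |rho| > 0.5",
    mean_delta = "mean per-feature log2 change (cond2 vs cond1, +0.5)",
    median_delta = "median per-feature log2 change",
    sd_delta_log = "sd of per-feature change in log2 counts",
    iqr_delta = "interquartile range of per-feature log2 change",
    skew_delta = "skewness of per-feature log2 change",
    max_abs_delta = "largest absolute per-feature log2 change",
    prop_large_decrease =
      "fraction of features with log2 change <= mean change - 1",
    prop_large_increase =
      "fraction of features with log2 change >= mean change + 1",
    total_fc = "ratio of mean observed totals, condition 2 over 1",
    libsize_cv = "coefficient of variation of sample totals",
    detected_frac_c1 = "mean per-sample fraction of detected features, cond 1",
    detected_frac_c2 = "mean per-sample fraction of detected features, cond 2",
    detected_change = "detected_frac_c2 - detected_frac_c1",
    prop_low_c1 = "fraction of features with mean count < 1, condition 1",
    prop_low_c2 = "fraction of features with mean count < 1, condition 2")
  data.frame(name = names(defs), definition = unname(defs),
             stringsAsFactors = FALSE)
}

#' Compute the signature vector of an observed count matrix
#'
#' Deterministic given `seed` (used only to sub-sample features for the
#' pairwise-correlation statistics when there are more than 500
#' features); the caller's RNG state is left untouched.
#'
#' @param Z features x samples matrix of non-negative counts.
#' @param condition two-level grouping vector.
#' @param seed seed of the correlation sub-sample.
#' @return named numeric vector containing every registry feature, in
#'   registry order.
#' @export
compute_signatures <- function(Z, condition, seed = 1L) {
  Z <- as.matrix(Z)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L) stop("two conditions are required")
  P <- nrow(Z)
  g2 <- condition == levels(condition)[2]
  Z1 <- Z[, !g2, drop = FALSE]; Z2 <- Z[, g2, drop = FALSE]
  means1 <- rowMeans(Z1); means2 <- rowMeans(Z2)

  out <- c(
    prop_zero = mean(Z == 0),
    prop_zero_c1 = mean(Z1 == 0), prop_zero_c2 = mean(Z2 == 0),
    prop_one = mean(Z == 1),
    prop_one_c1 = mean(Z1 == 1), prop_one_c2 = mean(Z2 == 1),
    dropout_change = mean(Z2 == 0) - mean(Z1 == 0),
    prop_unobserved_c1 = mean(rowSums(Z1) == 0),
    prop_unobserved_c2 = mean(rowSums(Z2) == 0))

  qs <- c(0, 0.25, 0.5, 0.75, 1)
  q1 <- stats::quantile(log1p(means1), qs, names = FALSE)
  q2 <- stats::quantile(log1p(means2), qs, names = FALSE)
  names(q1) <- paste0("logq", c(0, 25, 50, 75, 100), "_c1")
  names(q2) <- paste0("logq", c(0, 25, 50, 75, 100), "_c2")
  out <- c(out, q1, q2,
    mean_log_c1 = mean(log1p(means1)), sd_log_c1 = stats::sd(log1p(means1)),
    mean_log_c2 = mean(log1p(means2)), sd_log_c2 = stats::sd(log1p(means2)),
    evenness_c1 = .pielou(means1), evenness_c2 = .pielou(means2),
    evenness_change = .pielou(means2) - .pielou(means1),
    gini_c1 = .gini(means1 / max(sum(means1), 1)),
    gini_c2 = .gini(means2 / max(sum(means2), 1)))

  # pairwise feature correlations of CLR-transformed counts, on a
  # seeded sub-sample of features when P is large
  idx <- if (P > .sig_max_corr_features) {
    with_private_seed(derive_seed(seed, 11L),
                      sample.int(P, .sig_max_corr_features))
  } else seq_len(P)
  lz <- log(Z[idx, , drop = FALSE] + 0.5)
  clr <- lz - rep(colMeans(log(Z + 0.5)), each = length(idx))
  cc <- suppressWarnings(stats::cor(t(clr)))
  cc <- cc[upper.tri(cc)]
  cc <- cc[is.finite(cc)]
  out <- c(out,
    corr_mean = mean(cc), corr_median = stats::median(cc),
    corr_sd = stats::sd(cc), corr_skew = skewness_g1(cc),
    corr_prop_strong = mean(abs(cc) > 0.5))

  delta <- log2((means2 + 0.5) / (means1 + 0.5))
  centered <- delta - mean(delta)
  out <- c(out,
    mean_delta = mean(delta), median_delta = stats::median(delta),
    sd_delta_log = stats::sd(delta),
    iqr_delta = stats::IQR(delta), skew_delta = skewness_g1(delta),
    max_abs_delta = max(abs(delta)),
    prop_large_decrease = mean(centered <= -.sig_large_lfc),
    prop_large_increase = mean(centered >= .sig_large_lfc),
    total_fc = sum(means2) / max(sum(means1), 1e-12),
    libsize_cv = stats::sd(colSums(Z)) / mean(colSums(Z)),
    detected_frac_c1 = mean(colSums(Z1 > 0)) / P,
    detected_frac_c2 = mean(colSums(Z2 > 0)) / P,
    detected_change = (mean(colSums(Z2 > 0)) - mean(colSums(Z1 > 0))) / P,
    prop_low_c1 = mean(means1 < 1), prop_low_c2 = mean(means2 < 1))

  reg <- signature_registry()$name
  out[is.na(out)] <- 0
  stopifnot(setequal(names(out), reg))
  out[reg]
}
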