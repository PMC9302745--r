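# Per-sample size factors under five renormalization strategies.
#
# Every strategy is re-implemented here from its algorithmic definition
# (total counts; trimmed mean of M-values; median-of-ratios;
# pooling-and-deconvolution; sampling-fraction bias correction). All
# factor vectors are returned normalized to geometric mean 1: any global
# constant cancels in two-group testing, and the convention makes
# strategies directly comparable.

new_size_factors <- function(values, method, reference = NULL) {
  values <- unname(values)
  stopifnot(all(is.finite(values)), all(values > 0))
  structure(list(values = geo_mean_one(values), method = method,
                 reference = reference),
            class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  cat(sprintf("size_factors (%s): n = %d, range [%.3g, %.3g]\n",
              x$method, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Total-count (library size) size factors
#'
#' The anticipated worst case: factors proportional to per-sample column
#' totals, i.e. counts-per-million style rescaling.
#'
#' @param Z count matrix (features x samples).
#' @return a `size_factors` object (geometric mean 1).
#' @export
size_factors_total <- function(Z) {
  totals <- colSums(Z)
  if (any(totals <= 0)) stop("sample with zero total count")
  new_size_factors(totals, "total")
}

#' Trimmed mean of M-values (TMM) size factors
#'
#' For each sample, the log2 factor is the doubly trimmed,
#' inverse-variance-weighted mean of per-feature log2 ratios of
#' proportions (M-values) against a reference sample; features are
#' trimmed by the most extreme `trim_M` of M-values and `trim_A` of
#' average log2 abundances (A-values). The reference sample is the one
#' whose upper-quartile CPM is closest to the mean upper quartile.
#' Factors describe compositional correction only (a pure depth change
#' leaves them at 1); multiply by column totals to obtain effective
#' library sizes.
#'
#' @param Z count matrix (features x samples).
#' @param ref_sample reference column index, or `NULL` for automatic
#'   selection.
#' @param trim_M,trim_A total trim fractions for M- and A-values
#'   (canonical 0.30 and 0.05).
#' @return a `size_factors` object.
#' @export
size_factors_tmm <- function(Z, ref_sample = NULL, trim_M = 0.30,
                             trim_A = 0.05) {
  n <- ncol(Z)
  totals <- colSums(Z)
  if (any(totals <= 0)) stop("sample with zero total count")
  if (is.null(ref_sample)) {
    uq <- apply(sweep(Z, 2, totals, "/") * 1e6, 2, stats::quantile,
                probs = 0.75)
    ref_sample <- which.min(abs(uq - mean(uq)))
  }
  pr <- Z[, ref_sample] / totals[ref_sample]
  f <- numeric(n)
  for (i in seq_len(n)) {
    if (i == ref_sample) { f[i] <- 1; next }
    pi_ <- Z[, i] / totals[i]
    ok <- pi_ > 0 & pr > 0
    if (sum(ok) < 3L) {
      warning("fewer than 3 shared positive features; ",
              "falling back to total-count factor")
      f[i] <- totals[i] / totals[ref_sample]
      next
    }
    M <- log2(pi_[ok] / pr[ok])
    A <- (log2(pi_[ok]) + log2(pr[ok])) / 2
    # asymptotic (delta-method) variance of M for count data
    w <- 1 / ((1 - pi_[ok]) / (totals[i] * pi_[ok]) +
              (1 - pr[ok]) / (totals[ref_sample] * pr[ok]))
    keepM <- M >= stats::quantile(M, trim_M / 2) &
             M <= stats::quantile(M, 1 - trim_M / 2)
    keepA <- A >= stats::quantile(A, trim_A / 2) &
             A <= stats::quantile(A, 1 - trim_A / 2)
    keep <- keepM & keepA
    if (!any(keep)) keep <- keepM
    f[i] <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  new_size_factors(f, "tmm", reference = ref_sample)
}

#' Median-of-ratios size factors
#'
#' The reference profile is the per-feature geometric mean across
#' samples over features positive in every sample (optionally restricted
#' to a user-supplied control-feature set); each sample's factor is the
#' median across those features of its count divided by the reference.
#'
#' @param Z count matrix (features x samples).
#' @param controls optional integer/logical/character index of control
#'   features to restrict the reference to.
#' @return a `size_factors` object.
#' @export
size_factors_median_ratio <- function(Z, controls = NULL) {
  M <- Z
  if (!is.null(controls)) M <- Z[controls, , drop = FALSE]
  pos <- rowSums(M > 0) == ncol(M)
  if (!any(pos)) {
    stop("no feature is positive in all samples; ",
         "filter low-abundance features first")
  }
  L <- log(M[pos, , drop = FALSE])
  ref <- rowMeans(L)                       # log geometric mean
  f <- exp(apply(L - ref, 2, stats::median))
  new_size_factors(f, "median_ratio",
                   reference = if (!is.null(controls)) controls else NULL)
}

#' Pooling-and-deconvolution size factors
#'
#' Samples are ordered on a ring by library size; for several pool
#' sizes, sums of counts over contiguous pools are compared with an
#' average reference profile, giving per-pool ratio estimates that are
#' linear in the per-sample factors. The resulting system (augmented
#' with low-weight per-sample median-ratio equations to fix the scale)
#' is solved by least squares; non-positive solutions are floored.
#' When `condition` is supplied, deconvolution runs within each
#' condition and the two blocks are rescaled against each other with a
#' median ratio of their pooled profiles, mirroring cluster-wise usage
#' on heterogeneous data.
#'
#' @param Z count matrix (features x samples).
#' @param condition optional two-level grouping vector.
#' @param pool_sizes candidate pool sizes; shrunk adaptively when there
#'   are fewer samples than the defaults assume.
#' @param min_mean features with mean count below this are ignored.
#' @return a `size_factors` object.
#' @export
size_factors_deconvolution <- function(Z, condition = NULL,
                                       pool_sizes = c(21, 26, 31, 36, 41),
                                       min_mean = 0.1) {
  if (!is.null(condition)) {
    groups <- split(seq_len(ncol(Z)), condition)
    if (length(groups) > 1L) {
      f <- numeric(ncol(Z))
      pooled <- matrix(0, nrow(Z), length(groups))
      for (k in seq_along(groups)) {
        idx <- groups[[k]]
        f[idx] <- .deconvolve_one(Z[, idx, drop = FALSE], pool_sizes,
                                  min_mean)
        pooled[, k] <- rowMeans(sweep(Z[, idx, drop = FALSE], 2, f[idx],
                                      "/"))
      }
      # rescale groups against the first via median ratio of pooled
      # profiles over shared positive features
      for (k in seq_along(groups)[-1]) {
        ok <- pooled[, 1] > 0 & pooled[, k] > 0
        if (sum(ok) < 3L) next
        f[groups[[k]]] <- f[groups[[k]]] *
          stats::median(pooled[ok, k] / pooled[ok, 1])
      }
      return(new_size_factors(f, "deconvolution"))
    }
  }
  new_size_factors(.deconvolve_one(Z, pool_sizes, min_mean),
                   "deconvolution")
}

.deconvolve_one <- function(Z, pool_sizes, min_mean) {
  n <- ncol(Z)
  Z <- Z[rowMeans(Z) >= min_mean, , drop = FALSE]
  if (nrow(Z) < 2L || n < 4L) return(colSums(Z) / mean(colSums(Z)))
  sizes <- unique(pmin(pool_sizes, n))
  sizes <- sizes[sizes >= 2L]
  if (max(pool_sizes) > n) {
    sizes <- sort(unique(pmax(2L, round(n * c(0.3, 0.5, 0.7)))))
  }
  lib <- colSums(Z)
  ord <- order(lib)
  # interleave so library size varies smoothly around the ring
  ring <- ord[c(seq(1, n, by = 2), rev(seq(2, n, by = 2)))]
  ref <- rowMeans(Z)
  ok <- ref > 0
  rows <- list(); b <- numeric(0)
  for (s in sizes) {
    for (start in seq_len(n)) {
      pool <- ring[((start - 1 + seq_len(s) - 1) %% n) + 1]
      v <- rowSums(Z[, pool, drop = FALSE])
      r <- stats::median(v[ok] / ref[ok])
      row <- numeric(n); row[pool] <- 1
      rows[[length(rows) + 1L]] <- row
      b <- c(b, r)
    }
  }
  # low-weight per-sample equations make the system full rank and pin
  # the overall scale to per-sample median ratios
  w_single <- 0.05
  for (i in seq_len(n)) {
    row <- numeric(n); row[i] <- w_single
    rows[[length(rows) + 1L]] <- row
    b <- c(b, w_single * stats::median(Z[ok, i] / ref[ok]))
  }
  A <- do.call(rbind, rows)
  f <- tryCatch(drop(qr.solve(crossprod(A), crossprod(A, b))),
                error = function(e) NULL)
  if (is.null(f) || any(!is.finite(f))) {
    warning("singular deconvolution system; falling back to median ratio")
    pos <- rowSums(Z > 0) == n
    if (!any(pos)) return(lib / mean(lib))
    L <- log(Z[pos, , drop = FALSE])
    return(exp(apply(L - rowMeans(L), 2, stats::median)))
  }
  if (any(f <= 0)) {
    floor_val <- if (any(f > 0)) 0.1 * min(f[f > 0]) else 1e-3
    f[f <= 0] <- floor_val
  }
  f
}

#' Sampling-fraction (bias-correction) size factors
#'
#' Treats each sample's observed counts as a fraction of its absolute
#' abundance and estimates per-sample log offsets by alternating trimmed
#' means on the log scale: given sample offsets, per-condition feature
#' log means are re-estimated; given feature means, each sample offset
#' is the trimmed mean of its residuals; the cross-condition component
#' of the offset is identified as the trimmed mean of per-feature
#' between-condition differences (assuming a majority of stable
#' features).
#'
#' @param Z count matrix (features x samples).
#' @param condition two-level grouping vector, each level with >= 2
#'   samples.
#' @param pseudo pseudo-count added before taking logs.
#' @param trim total trim fraction of the trimmed means.
#' @param tol,max_iter convergence controls.
#' @return a `size_factors` object; attribute `converged` reports
#'   whether the alternating scheme reached `tol`.
#' @export
size_factors_bias_correction <- function(Z, condition, pseudo = 0.5,
                                         trim = 0.2, tol = 1e-6,
                                         max_iter = 100L) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L || any(table(condition) < 2L)) {
    stop("two condition groups with >= 2 samples each are required")
  }
  L <- log(Z + pseudo)
  n <- ncol(Z)
  g1 <- condition == levels(condition)[1]
  d <- numeric(n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d_old <- d
    Lc <- sweep(L, 2, d)
    th1 <- rowMeans(Lc[, g1, drop = FALSE])
    th2 <- rowMeans(Lc[, !g1, drop = FALSE])
    resid <- Lc - cbind(th1)[, rep(1, n)]
    resid[, !g1] <- Lc[, !g1, drop = FALSE] - th2
    d_within <- apply(resid, 2, mean, trim = trim / 2)
    # cross-condition shift: trimmed center of per-feature differences
    shift <- mean(th2 - th1, trim = trim / 2)
    d <- d + d_within
    d[!g1] <- d[!g1] + shift
    d <- d - mean(d)
    if (max(abs(d - d_old)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("bias-correction offsets did not converge; returning last iterate")
  }
  out <- new_size_factors(exp(d), "bias_correction")
  attr(out, "converged") <- converged
  out
}
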