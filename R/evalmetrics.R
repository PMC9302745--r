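# Scoring observed-data calls against the absolute-data oracle.

#' Confusion counts of observed-data calls against oracle calls
#'
#' The oracle calls (NB GLM on absolute counts) define "true"
#' differential abundance: oracle-positive and observed-positive is a
#' true positive, oracle-negative and observed-positive a false
#' positive, and so on. Sensitivity is TP/(TP+FN), specificity
#' TN/(TN+FP); either is `NA` (flagged undefined) when its denominator
#' is zero.
#'
#' @param oracle_calls,observed_calls equal-length logical vectors over
#'   the same features.
#' @param dataset_id,method,setting optional labels carried through.
#' @return one-row data.frame of class `accuracy_record` with columns
#'   `dataset_id`, `method`, `setting`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `fp_count`.
#' @export
confusion <- function(oracle_calls, observed_calls, dataset_id = NA,
                      method = NA, setting = NA) {
  stopifnot(is.logical(oracle_calls), is.logical(observed_calls))
  if (length(oracle_calls) != length(observed_calls)) {
    stop("oracle and observed call vectors differ in length")
  }
  tp <- sum(oracle_calls & observed_calls)
  fp <- sum(!oracle_calls & observed_calls)
  tn <- sum(!oracle_calls & !observed_calls)
  fn <- sum(oracle_calls & !observed_calls)
  out <- data.frame(
    dataset_id = dataset_id, method = method, setting = setting,
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    fp_count = fp, stringsAsFactors = FALSE)
  class(out) <- c("accuracy_record", class(out))
  out
}

#' Aggregate accuracy records
#'
#' Per group: median sensitivity and specificity (undefined values
#' excluded), the percentage of records with specificity below 0.95 and
#' below 0.5, and the median false positive count.
#'
#' @param records data.frame of accuracy records.
#' @param group_by character vector of grouping columns (e.g.
#'   `c("setting", "method")`), or `NULL` for one overall row.
#' @return summary data.frame.
#' @export
aggregate_accuracy <- function(records, group_by = NULL) {
  stopifnot(nrow(records) > 0)
  if (is.null(group_by)) {
    groups <- list(all = seq_len(nrow(records)))
    keys <- data.frame(group = "all")
  } else {
    key <- interaction(records[group_by], drop = TRUE, sep = "\r")
    groups <- split(seq_len(nrow(records)), key)
    keys <- do.call(rbind, lapply(strsplit(names(groups), "\r", fixed = TRUE),
                                  function(x) {
                                    as.data.frame(as.list(stats::setNames(x, group_by)),
                                                  stringsAsFactors = FALSE)
                                  }))
  }
  rows <- lapply(seq_along(groups), function(i) {
    r <- records[groups[[i]], ]
    sp <- r$specificity[!is.na(r$specificity)]
    data.frame(
      n = nrow(r),
      median_sensitivity = stats::median(r$sensitivity, na.rm = TRUE),
      median_specificity = stats::median(r$specificity, na.rm = TRUE),
      pct_below_95 = if (length(sp)) 100 * mean(sp < 0.95) else NA_real_,
      pct_below_50 = if (length(sp)) 100 * mean(sp < 0.5) else NA_real_,
      median_fp_count = stats::median(r$fp_count, na.rm = TRUE))
  })
  cbind(keys, do.call(rbind, rows))
}

#' Classify a simulated data set into experimental settings
#'
#' Settings are defined from the grid levels of feature number and
#' perturbation scale: Microbial = low-to-moderate feature number
#' (P <= 1000) with the largest perturbation level; Bulk Transcriptomic
#' = the largest feature number (P = 5000) with the lower perturbation
#' levels; Cell Transcriptomic = moderate-to-large feature number
#' (P >= 1000) with moderate perturbation levels. Labels may overlap;
#' data sets matching none are labeled "other".
#'
#' @param P feature number.
#' @param a_level grid level of the perturbation scale `a`, 1 (lowest)
#'   to `n_levels` (highest).
#' @param n_levels number of grid levels of `a` (default 5).
#' @return character vector of setting labels.
#' @export
classify_setting <- function(P, a_level, n_levels = 5L) {
  stopifnot(a_level >= 1, a_level <= n_levels)
  labels <- character(0)
  if (P <= 1000 && a_level == n_levels) labels <- c(labels, "Microbial")
  if (P >= 1000 && a_level > 1 && a_level < n_levels) {
    labels <- c(labels, "Cell")
  }
  if (P == 5000 && a_level <= 2) labels <- c(labels, "Bulk")
  if (!length(labels)) labels <- "other"
  labels
}

#' Spearman correlations of data characteristics with accuracy
#'
#' Joins accuracy records to signature vectors by `dataset_id` and
#' computes the tie-corrected Spearman correlation of every signature
#' feature with sensitivity and with specificity.
#'
#' @param records accuracy records (one or more methods).
#' @param signatures data.frame of signature vectors with a
#'   `dataset_id` column.
#' @return data.frame: `feature`, `rho_sensitivity`,
#'   `rho_specificity`; constant features yield `NA` (flagged
#'   undefined).
#' @export
correlate_characteristics <- function(records, signatures) {
  stopifnot("dataset_id" %in% names(records),
            "dataset_id" %in% names(signatures))
  merged <- merge(records[, c("dataset_id", "sensitivity", "specificity")],
                  signatures, by = "dataset_id")
  feats <- setdiff(names(signatures), "dataset_id")
  rho <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(x[ok], y[ok], method = "spearman")
  }
  data.frame(
    feature = feats,
    rho_sensitivity = vapply(feats, function(f)
      rho(merged[[f]], merged$sensitivity), numeric(1)),
    rho_specificity = vapply(feats, function(f)
      rho(merged[[f]], merged$specificity), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
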