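# Orchestration: the hyperparameter grid, the per-cell
# simulate -> test -> score pipeline, sweeps, and report tables.

#' Default hyperparameter levels of the simulation grid
#'
#' Numeric values are chosen so that realized data spans the intended
#' breadth: percent zeros from near zero to above 80%, total-abundance
#' fold changes from none to several-fold, and detectable differential
#' abundance from sparse to widespread. Baseline log mean `m` and log
#' sd `S` are co-incremented low to high as five pairs; the
#' perturbation variance `a` is swept as a proportion of `m`; replicate
#' noise `g` has three steps; correlation structure has five presets
#' ([correlation_preset()]). The full Cartesian product is
#' 3 x 5 x 5 x 5 x 3 x 5 = 5625 cells.
#'
#' @return named list of level vectors.
#' @export
grid_levels <- function() {
  list(
    P = c(100L, 1000L, 5000L),
    mS = data.frame(m = c(2, 3.5, 5, 6.5, 8), S = c(1, 1.5, 2, 2.5, 3)),
    prop_a = c(0.05, 0.1, 0.25, 0.5, 1.0),
    corr_level = 1:5,
    g = c(0.05, 0.2, 0.5),
    c = c(0.2, 0.3, 0.5, 0.7, 0.9))
}

#' Expand hyperparameter levels into a grid of cells
#'
#' Full Cartesian product over level indices, in a fixed deterministic
#' order, with one derived seed per cell.
#'
#' @param levels list in the shape of [grid_levels()].
#' @param root_seed root seed; each cell's seed is derived from it and
#'   the cell index.
#' @return data.frame with one row per cell: indices, parameter values
#'   (`a = prop_a * m`), `cell` and `seed`.
#' @export
expand_sim_grid <- function(levels = grid_levels(), root_seed = 1L) {
  stopifnot(all(lengths(levels[c("P", "prop_a", "corr_level", "g", "c")]) > 0),
            nrow(levels$mS) > 0)
  g <- expand.grid(
    P_idx = seq_along(levels$P),
    mS_idx = seq_len(nrow(levels$mS)),
    a_level = seq_along(levels$prop_a),
    corr_level = levels$corr_level,
    g_idx = seq_along(levels$g),
    c_idx = seq_along(levels$c))
  g$P <- levels$P[g$P_idx]
  g$m <- levels$mS$m[g$mS_idx]
  g$S <- levels$mS$S[g$mS_idx]
  g$prop_a <- levels$prop_a[g$a_level]
  g$a <- g$prop_a * g$m
  g$g <- levels$g[g$g_idx]
  g$c <- levels$c[g$c_idx]
  g$cell <- seq_len(nrow(g))
  g$seed <- vapply(g$cell, function(i) derive_seed(root_seed, i), integer(1))
  g
}

#' Build the simulation grid for a preset
#'
#' The `"full"` preset is the complete 5625-cell product (long
#' running). The `"reduced"` preset is the desk-scale surface: cells
#' with P <= 1000, sub-sampled uniformly at random (seeded) to
#' `n_cells` rows.
#'
#' @param preset `"reduced"` or `"full"`.
#' @param root_seed root seed for cell seeds and the sub-sample.
#' @param n_cells number of cells in the reduced preset.
#' @param levels hyperparameter levels.
#' @return grid data.frame (see [expand_sim_grid()]).
#' @export
sim_grid <- function(preset = c("reduced", "full"), root_seed = 1L,
                     n_cells = 300L, levels = grid_levels()) {
  preset <- match.arg(preset)
  g <- expand_sim_grid(levels, root_seed = root_seed)
  if (preset == "full") return(g)
  g <- g[g$P <= 1000, , drop = FALSE]
  if (n_cells < nrow(g)) {
    idx <- with_private_seed(derive_seed(root_seed, 0L),
                             sort(sample.int(nrow(g), n_cells)))
    g <- g[idx, , drop = FALSE]
  }
  g
}

#' Turn one grid row into a simulation config
#'
#' @param row one-row data.frame from a grid.
#' @param R,d_abs,depth_lo,depth_hi passed to [simulation_config()].
#' @return a [simulation_config()].
#' @export
config_from_row <- function(row, R = 10L, d_abs = 1000,
                            depth_lo = 5000, depth_hi = 2e6) {
  simulation_config(P = row$P, m = row$m, S = row$S,
                    corr = correlation_preset(row$corr_level),
                    a = row$a, c = row$c, g = row$g, R = R,
                    d_abs = d_abs, depth_lo = depth_lo,
                    depth_hi = depth_hi, seed = row$seed)
}

#' Default calling policies
#'
#' @return named list: `lenient` (FDR 0.05, no fold-change threshold)
#'   and `stringent` (FDR 0.01 plus two-fold).
#' @export
da_policies <- function() {
  list(lenient = call_policy(0.05, 0), stringent = call_policy(0.01, 1))
}

#' Run the full pipeline on one grid cell
#'
#' Simulates the paired data, runs the oracle NB GLM on absolute
#' counts, runs every requested method on observed counts, scores each
#' (method, policy) combination against the oracle under the same
#' policy, and computes the signature vector of the observed counts.
#'
#' @param config a [simulation_config()].
#' @param methods methods to run on observed counts.
#' @param policies named list of [call_policy()] objects.
#' @param a_level grid level of `a` (for setting labels); `NA` labels
#'   the cell "other".
#' @param dataset_id identifier carried into the outputs.
#' @param n_mc Monte-Carlo instances for `clr_mc`.
#' @return list: `records` (one row per method x policy, with a
#'   `policy` column), `signatures` (one-row data.frame), `sim` is not
#'   retained.
#' @export
run_cell <- function(config, methods = rescaling_methods(),
                     policies = da_policies(), a_level = NA,
                     dataset_id = "cell1", n_mc = 128L) {
  sim <- simulate_dataset(config)
  setting <- if (is.na(a_level)) "other" else {
    paste(classify_setting(config$P, a_level), collapse = "+")
  }
  oracle <- run_method(sim$Y, sim$condition, "oracle_glm",
                       seed = config$seed)
  res <- lapply(seq_along(methods), function(i) {
    run_method(sim$Z, sim$condition, methods[i],
               seed = derive_seed(config$seed, 100L + i), n_mc = n_mc)
  })
  names(res) <- methods
  rows <- list()
  for (pn in names(policies)) {
    pol <- policies[[pn]]
    oc <- call_features(oracle, pol)
    for (m in methods) {
      rec <- confusion(oc, call_features(res[[m]], pol),
                       dataset_id = dataset_id, method = m,
                       setting = setting)
      rec$policy <- pn
      rows[[length(rows) + 1L]] <- rec
    }
  }
  sig <- compute_signatures(sim$Z, sim$condition, seed = config$seed)
  sig_df <- cbind(data.frame(dataset_id = dataset_id,
                             stringsAsFactors = FALSE),
                  as.data.frame(as.list(sig)))
  list(records = do.call(rbind, rows), signatures = sig_df)
}

#' Sweep the pipeline over a grid
#'
#' Cells run independently; a failure in one cell is recorded in the
#' manifest and the sweep continues. When `out_dir` is given, per-cell
#' CSVs are written and already-completed cells are skipped on re-run
#' (resumability).
#'
#' @param grid grid data.frame from [sim_grid()].
#' @param methods,policies,n_mc passed to [run_cell()].
#' @param out_dir optional directory for per-cell outputs.
#' @param progress print a line every `progress` cells (0 = quiet).
#' @return list: `records`, `signatures`, `manifest` (per-cell status).
#' @export
run_grid <- function(grid, methods = rescaling_methods(),
                     policies = da_policies(), n_mc = 128L,
                     out_dir = NULL, progress = 0L) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  records <- list(); signatures <- list(); status <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    id <- paste0("cell", row$cell)
    rec_path <- if (!is.null(out_dir)) {
      file.path(out_dir, paste0(id, "_records.csv"))
    }
    sig_path <- if (!is.null(out_dir)) {
      file.path(out_dir, paste0(id, "_signatures.csv"))
    }
    if (!is.null(out_dir) && file.exists(rec_path) &&
        file.exists(sig_path)) {
      records[[i]] <- utils::read.csv(rec_path, stringsAsFactors = FALSE)
      signatures[[i]] <- utils::read.csv(sig_path,
                                         stringsAsFactors = FALSE)
      status[i] <- "cached"
      next
    }
    out <- tryCatch(
      run_cell(config_from_row(row), methods = methods,
               policies = policies, a_level = row$a_level,
               dataset_id = id, n_mc = n_mc),
      error = function(e) e)
    if (inherits(out, "error")) {
      status[i] <- paste0("error: ", conditionMessage(out))
      next
    }
    records[[i]] <- out$records
    signatures[[i]] <- out$signatures
    status[i] <- "ok"
    if (!is.null(out_dir)) {
      utils::write.csv(out$records, rec_path, row.names = FALSE)
      utils::write.csv(out$signatures, sig_path, row.names = FALSE)
    }
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("[%d/%d] %s", i, nrow(grid), id))
    }
  }
  manifest <- data.frame(cell = grid$cell, seed = grid$seed,
                         status = status, stringsAsFactors = FALSE)
  list(records = do.call(rbind, records),
       signatures = do.call(rbind, signatures), manifest = manifest)
}

#' Build summary report tables from a sweep
#'
#' Produces the per-setting/per-method median-and-thresholded
#' specificity tables under the lenient and stringent policies, overall
#' pooled medians per policy, and (when signatures are supplied) the
#' table of Spearman correlations between signatures and accuracy.
#'
#' @param records accuracy records from [run_grid()].
#' @param signatures optional signature table from [run_grid()].
#' @return list of data.frames: `by_setting_lenient`,
#'   `by_setting_stringent`, `overall`, `correlations`.
#' @export
make_report <- function(records, signatures = NULL) {
  stopifnot(nrow(records) > 0)
  len <- records[records$policy == "lenient", ]
  str <- records[records$policy == "stringent", ]
  overall <- do.call(rbind, lapply(split(records, records$policy),
    function(r) cbind(policy = r$policy[1],
                      aggregate_accuracy(r)[, -1, drop = FALSE])))
  out <- list(
    by_setting_lenient = if (nrow(len)) {
      aggregate_accuracy(len, c("setting", "method"))
    },
    by_setting_stringent = if (nrow(str)) {
      aggregate_accuracy(str, c("setting", "method"))
    },
    overall = overall)
  if (!is.null(signatures) && nrow(len)) {
    out$correlations <- correlate_characteristics(len, signatures)
  }
  out
}
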