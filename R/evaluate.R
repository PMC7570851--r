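#' Generate a replicated synthetic experiment
#'
#' Realizes one mixture design and measures every sample `n_replicates`
#' times with fresh drift and noise (identical targets), emulating repeated
#' instrument runs; replicate measurements feed the precision (CV) metric.
#'
#' @param design a [design_spec()].
#' @param levels level table.
#' @param array an `array_config`.
#' @param seed master seed (sample realization and measurements).
#' @param n_replicates number of measured replicates (default 3).
#' @return list of datasets (data.frames in the [dataset_columns()] schema);
#'   the first is the primary dataset.
#' @export
generate_experiment <- function(design = design_spec(),
                                levels = default_levels(),
                                array = default_array_config(),
                                seed = 1, n_replicates = 3) {
  design$seed <- as.integer(seed)
  samples <- realize_samples(factorial_design(design), levels, design)
  mseeds <- derive_seeds(seed + 1L, n_replicates)
  lapply(seq_len(n_replicates), function(r)
    measure_samples(samples, array, seed = mseeds[r]))
}

#' k-fold cross-validation of one model on a dataset
#'
#' Shuffles samples (seeded) into k folds of near-equal size; within each
#' fold the feature scaler and the explained-variance feature-width rule are
#' fitted on the training split only. Per-ion metrics are pooled over the
#' out-of-fold predictions.
#'
#' @param dataset data.frame in the [dataset_columns()] schema.
#' @param spec a [model_spec()].
#' @param k number of folds (>= 2, <= n).
#' @param seed integer seed (fold shuffle and model fits).
#' @param replicates optional list of replicate datasets (same rows/targets,
#'   fresh measurement noise) used for the CV precision metric.
#' @param variance_threshold explained-variance fraction for the DKL feature
#'   width (default 0.98).
#' @param model_label label written into the report rows.
#' @return data.frame with one row per ion: `ion`, `model`, `rmse_mgL`,
#'   `r2`, `cv_pct`, `slope`, `intercept`, `n`, `seed`. The out-of-fold
#'   prediction matrix is attached as attribute `"predictions"`.
#' @export
kfold_cv <- function(dataset, spec = model_spec(), k = 10, seed = 1,
                     replicates = NULL, variance_threshold = 0.98,
                     model_label = toupper(spec$type)) {
  check_dataset(dataset)
  n <- nrow(dataset)
  if (k < 2) stop_input("k must be >= 2")
  if (n < k) stop_input("need at least k samples (n = ", n, ", k = ", k, ")")
  X_all <- enrich_dataset(dataset)
  Y_all <- as.matrix(dataset[, paste0("c_", ion_names())])
  colnames(Y_all) <- ion_names()
  Xrep <- lapply(replicates %||% list(), enrich_dataset)
  fold_of <- integer(n)
  fold_of[with_seed(seed, sample.int(n))] <- rep(seq_len(k), length.out = n)
  fit_seeds <- derive_seeds(seed + 1L, k)
  pred <- matrix(NA_real_, n, length(ion_names()),
                 dimnames = list(NULL, ion_names()))
  pred_rep <- lapply(Xrep, function(...) pred)
  for (f in seq_len(k)) {
    tr <- fold_of != f; te <- !tr
    scaler <- fit_scaler(X_all[tr, , drop = FALSE])
    Xtr <- apply_scaler(scaler, X_all[tr, , drop = FALSE])
    fd <- if (spec$type == "dkl")
      spec$feature_dim %||% select_pc_count(Xtr, variance_threshold)
    else NULL
    model <- fit_ion_model(Xtr, Y_all[tr, , drop = FALSE], spec,
                           seed = fit_seeds[f], feature_dim = fd)
    pred[te, ] <- predict_ions(model, apply_scaler(scaler, X_all[te, , drop = FALSE]))
    for (r in seq_along(Xrep))
      pred_rep[[r]][te, ] <- predict_ions(
        model, apply_scaler(scaler, Xrep[[r]][te, , drop = FALSE]))
  }
  rows <- lapply(ion_names(), function(ion) {
    a <- Y_all[, ion]; p <- pred[, ion]
    co <- coef(lm(p ~ a))
    cv <- if (length(pred_rep)) {
      reps <- cbind(p, vapply(pred_rep, function(m) m[, ion], numeric(n)))
      coeff_variation(reps)
    } else NA_real_
    data.frame(ion = ion, model = model_label,
               rmse_mgL = rmse(a, p), r2 = r_squared(a, p), cv_pct = cv,
               slope = unname(co[2]), intercept = unname(co[1]),
               n = n, seed = seed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "predictions") <- pred
  out
}

#' Cross-validated comparison of the three regression back ends
#'
#' For each seed: realize the design, measure it (with replicate runs for
#' the precision metric), and evaluate every model by k-fold
#' cross-validation. Per-ion, per-model metrics are aggregated as medians
#' across seeds. A model failure is recorded for its cells and does not
#' abort the report.
#'
#' @param model_specs named list of [model_spec()] objects.
#' @param design a [design_spec()].
#' @param levels level table.
#' @param array an `array_config`.
#' @param seeds integer vector of benchmark seeds.
#' @param k folds (default 10).
#' @param n_replicates measured replicates per seed (default 3).
#' @return object of class `comparison_report`: list with `summary`
#'   (medians across seeds), `per_seed` (all rows) and `failures`.
#' @export
compare_models <- function(model_specs = default_model_specs(),
                           design = design_spec(),
                           levels = default_levels(),
                           array = default_array_config(),
                           seeds = 1:5, k = 10, n_replicates = 3) {
  t0 <- Sys.time()
  per_seed <- list(); failures <- character(0)
  for (s in seeds) {
    dsets <- generate_experiment(design, levels, array, seed = s,
                                 n_replicates = n_replicates)
    for (nm in names(model_specs)) {
      res <- tryCatch(
        kfold_cv(dsets[[1]], model_specs[[nm]], k = k, seed = s,
                 replicates = dsets[-1], model_label = nm),
        error = function(e) {
          failures <<- c(failures, paste0(nm, "@seed", s, ": ",
                                          conditionMessage(e)))
          NULL
        })
      if (!is.null(res)) per_seed[[paste(nm, s)]] <- res
    }
  }
  all_rows <- do.call(rbind, per_seed)
  rownames(all_rows) <- NULL
  summary <- do.call(rbind, lapply(split(
    all_rows, list(all_rows$ion, all_rows$model), drop = TRUE),
    function(d) data.frame(
      ion = d$ion[1], model = d$model[1],
      rmse_mgL = median(d$rmse_mgL), r2 = median(d$r2),
      cv_pct = median(d$cv_pct), slope = median(d$slope),
      intercept = median(d$intercept), n = d$n[1],
      n_seeds = nrow(d), stringsAsFactors = FALSE)))
  summary <- summary[order(match(summary$ion, ion_names()), summary$model), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, per_seed = all_rows,
                 failures = failures,
                 log = list(seeds = seeds, k = k,
                            n_replicates = n_replicates,
                            n_levels = design$n_levels,
                            models = names(model_specs),
                            elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                            units = "secs")),
                            timestamp = format(t0, "%Y-%m-%d %H:%M:%S"))),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> medians over",
      length(unique(x$per_seed$seed)), "seed(s)\n")
  df <- x$summary
  df$rmse_mgL <- round(df$rmse_mgL, 1); df$r2 <- round(df$r2, 3)
  df$cv_pct <- round(df$cv_pct, 1)
  df$slope <- round(df$slope, 3); df$intercept <- round(df$intercept, 2)
  print(df, row.names = FALSE)
  if (length(x$failures))
    cat("failures:\n ", paste(x$failures, collapse = "\n  "), "\n")
  invisible(x)
}

#' Write a comparison report as CSV
#'
#' @param report a `comparison_report`.
#' @param path file path.
#' @param which `"summary"` (default) or `"per_seed"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, which = c("summary", "per_seed")) {
  which <- match.arg(which)
  write.csv(report[[which]], path, row.names = FALSE)
  invisible(path)
}
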