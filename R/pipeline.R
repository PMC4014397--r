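#' Pipeline configuration
#'
#' @param n_promoters promoters to simulate (default 20).
#' @param synthetic a [synthetic_config()] controlling the simulator.
#' @param window sliding-window size for the derivative (default 17).
#' @param n_points shared generation grid size (default 100).
#' @param error_norm relative-error norm (`"l2"` or `"mae"`).
#' @param violation_threshold relative-error threshold for flagging
#'   superposition violations (default 0.2).
#' @param center_pca mean-center the per-promoter PCA? Default `FALSE`.
#' @param n_null_shuffles shuffles for the randomized PCA null (default 100).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_promoters = 20L,
                            synthetic = synthetic_config(),
                            window = 17L,
                            n_points = 100L,
                            error_norm = "l2",
                            violation_threshold = 0.2,
                            center_pca = FALSE,
                            n_null_shuffles = 100L) {
  structure(list(n_promoters = as.integer(n_promoters), synthetic = synthetic,
                 window = as.integer(window), n_points = as.integer(n_points),
                 error_norm = error_norm,
                 violation_threshold = violation_threshold,
                 center_pca = center_pca,
                 n_null_shuffles = as.integer(n_null_shuffles)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Fields missing from the file take their [pipeline_config()] /
#' [synthetic_config()] defaults; unknown fields raise an error naming them.
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn_raw <- raw$synthetic %||% list()
  raw$synthetic <- NULL
  bad <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(syn_raw), names(formals(synthetic_config)))
  if (length(bad))
    stop("unknown config field(s): ", paste0("synthetic.", bad, collapse = ", "))
  if (!is.null(syn_raw$rates)) syn_raw$rates <- unlist(syn_raw$rates)
  syn <- do.call(synthetic_config, syn_raw)
  do.call(pipeline_config, c(raw, list(synthetic = syn)))
}

# Fit all combined conditions of one promoter's condition matrix under the
# three models. Returns a list of superpose_fit lists keyed by model.
fit_condition_matrix <- function(m, promoter, error_norm = "l2") {
  keys <- rownames(m)
  sizes <- lengths(strsplit(keys, "+", fixed = TRUE))
  singles <- keys[sizes == 1]
  out <- list(superposition = list(), unconstrained = list(),
              multiplicative = list())
  for (key in keys[sizes >= 2]) {
    members <- condition_set(key)
    if (!all(members %in% singles)) next
    A <- t(m[members, , drop = FALSE])
    colnames(A) <- members
    y <- m[key, ]
    for (mod in names(out)) {
      f <- superpose(y, A, model = mod, error_norm = error_norm)
      f$promoter <- promoter
      f$target_conditions <- members
      out[[mod]][[key]] <- f
    }
  }
  out
}

#' Run the full analysis pipeline on synthetic plates
#'
#' Executes, in order, any prefix of the stages
#' `simulate -> activity -> pca -> fit -> predict -> evaluate`:
#' simulate ground truth and render noisy plates; derive activity curves on
#' the shared generation grid; per-promoter principal component shapes with
#' randomized null and PC1-growth correlation; superposition /
#' unconstrained / multiplicative fits of every combined condition;
#' pair-based prediction of triplet and quadruplet weights and dynamics;
#' and the evaluation summaries (day-to-day error, weight-sum statistics,
#' violation flags, exemplar baseline, prediction-error medians and
#' cumulative histogram). Outputs are written as CSV under `out`, alongside
#' a `manifest.json` recording the seed, configuration hash and package
#' version; rerunning with the same seed reproduces the outputs exactly.
#'
#' @param config a [pipeline_config()] (or path to a JSON config).
#' @param out output directory (created); `NULL` skips all file output.
#' @param seed integer seed driving the simulation.
#' @param stages character vector: which stages to run. Must be a prefix of
#'   the canonical order.
#' @return invisibly, a list with the in-memory objects of every executed
#'   stage (`truth`, `collection`, `curves`, `matrices`, `shapes`, `fits`,
#'   `predictions`, `evaluation`).
#' @export
run_pipeline <- function(config = pipeline_config(), out = NULL, seed = 1L,
                         stages = c("simulate", "activity", "pca", "fit",
                                    "predict", "evaluate")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  all_stages <- c("simulate", "activity", "pca", "fit", "predict", "evaluate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!identical(stages, all_stages[seq_along(stages)]))
    stop("stages must be a prefix of: ", paste(all_stages, collapse = ", "))
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  st <- list(config = config, seed = seed)

  # simulate
  st$truth <- generate_truth(config$n_promoters, config$synthetic, seed = seed)
  st$collection <- render_plate(st$truth, seed = seed + 1L)
  if (!is.null(out)) {
    write_truth_csv(st$truth, file.path(out, "truth.csv"))
    write_synthetic_plates(st$collection, file.path(out, "plates"))
  }
  if (length(stages) >= 2) {
    st$curves <- activity_curves(st$collection, window = config$window,
                                 n_points = config$n_points)
    if (!is.null(out))
      write_activity_csv(unlist(st$curves, recursive = FALSE),
                         file.path(out, "activity.csv"))
    st$matrices <- lapply(names(st$curves), function(p)
      condition_matrix(st$curves[[p]]))
    names(st$matrices) <- names(st$curves)
  }
  if (length(stages) >= 3) {
    st$shapes <- lapply(st$matrices, function(m)
      principal_shapes(m, k = min(2L, min(dim(m))), center = config$center_pca))
    st$growth_r2 <- vapply(names(st$shapes), function(p) {
      gcur <- aggregate_growth(st$collection, st$curves[[p]][[1]]$generations,
                               window = config$window)
      pc1_growth_correlation(st$shapes[[p]], gcur)
    }, numeric(1))
    st$null_2pc <- lapply(st$matrices, randomized_null,
                          n_shuffles = config$n_null_shuffles,
                          seed = seed + 2L, center = config$center_pca)
    if (!is.null(out))
      write_shapes_csv(st$shapes, file.path(out, "shapes.csv"),
                       file.path(out, "shapes_summary.csv"),
                       growth_r2 = st$growth_r2)
  }
  if (length(stages) >= 4) {
    per_prom <- lapply(names(st$matrices), function(p)
      fit_condition_matrix(st$matrices[[p]], p, error_norm = config$error_norm))
    names(per_prom) <- names(st$matrices)
    st$fits <- list(
      superposition = unlist(lapply(per_prom, `[[`, "superposition"),
                             recursive = FALSE),
      unconstrained = unlist(lapply(per_prom, `[[`, "unconstrained"),
                             recursive = FALSE),
      multiplicative = unlist(lapply(per_prom, `[[`, "multiplicative"),
                              recursive = FALSE))
    st$fits_by_promoter <- per_prom
    if (!is.null(out))
      write_fits_csv(c(st$fits$superposition, st$fits$unconstrained,
                       st$fits$multiplicative),
                     file.path(out, "fits.csv"))
  }
  if (length(stages) >= 5) {
    st$predictions <- pipeline_predictions(st)
    if (!is.null(out))
      write_predictions_csv(st$predictions, file.path(out, "predictions.csv"))
  }
  if (length(stages) >= 6) {
    st$evaluation <- pipeline_evaluation(st)
    if (!is.null(out)) {
      ev <- st$evaluation
      utils::write.csv(ev$summary, file.path(out, "evaluation.csv"),
                       row.names = FALSE)
      utils::write.csv(ev$prediction_summary$histogram,
                       file.path(out, "prediction_histogram.csv"),
                       row.names = FALSE)
    }
  }
  if (!is.null(out)) {
    cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                                 digits = NA)
    tmp <- tempfile(); writeLines(cfg_json, tmp)
    manifest <- list(seed = seed,
                     stages = stages,
                     config_hash = unname(tools::md5sum(tmp)),
                     package_version = as.character(utils::packageVersion("dynsup")))
    unlink(tmp)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(st)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unname(x)
}

# Mean instantaneous growth-rate curve across conditions, interpolated onto
# the promoter grid. One well per (condition, day) suffices since growth is
# a property of the condition, not the reporter.
aggregate_growth <- function(collection, grid, window = 17L) {
  key <- vapply(collection, function(s)
    paste(condition_key(s$condition_set), s$replicate_day, sep = "|"), character(1))
  first_wells <- collection[!duplicated(key)]
  gcurves <- lapply(first_wells, growth_rate, window = window)
  gres <- resample_to_common_grid(gcurves, grid = grid)
  rowMeans(vapply(gres, `[[`, numeric(length(grid)), "rate"))
}

# Triplet/quadruplet predictions from pair superposition fits, with errors
# against the measured combined-condition curves.
pipeline_predictions <- function(st) {
  labels <- st$config$synthetic$labels
  preds <- list()
  for (p in names(st$matrices)) {
    m <- st$matrices[[p]]
    sup <- st$fits_by_promoter[[p]]$superposition
    sizes <- lengths(strsplit(names(sup), "+", fixed = TRUE))
    pair_fits <- sup[sizes == 2]
    targets <- condition_combinations(labels)
    targets <- targets[lengths(targets) >= 3]
    for (S in targets) {
      need <- vapply(utils::combn(S, 2, simplify = FALSE), condition_key,
                     character(1))
      if (!all(need %in% names(pair_fits))) next
      w <- predict_weights_iterative(pair_fits[need], S)
      singles <- as.list(as.data.frame(t(m[S, , drop = FALSE])))
      curve <- predict_dynamics(w, singles)
      key <- condition_key(S)
      err <- if (key %in% rownames(m))
        relative_fit_error(curve, m[key, ], norm = st$config$error_norm)
      else NA_real_
      preds[[paste(p, key)]] <- list(promoter = p, target = S,
                                     predicted_weights = w,
                                     predicted_curve = curve,
                                     relative_error_vs_measured = err)
    }
  }
  unname(preds)
}

pipeline_evaluation <- function(st) {
  cfg <- st$config
  # day-to-day error per (promoter, condition): needs per-day curves
  rep_errors <- unlist(lapply(names(st$curves), function(p) {
    curves <- st$curves[[p]]
    keys <- vapply(curves, function(cur) condition_key(cur$condition_set),
                   character(1))
    vapply(unique(keys), function(k)
      day_to_day_error(curves[keys == k], norm = cfg$error_norm), numeric(1))
  }))
  # replicate-matched fit errors: fit each day's combined curve against the
  # same day's single curves (no cross-day averaging)
  per_day_err <- unlist(lapply(names(st$curves), function(p) {
    curves <- st$curves[[p]]
    keys <- vapply(curves, function(cur) condition_key(cur$condition_set),
                   character(1))
    days <- vapply(curves, `[[`, integer(1), "replicate_day")
    unlist(lapply(unique(days), function(d) {
      cd <- curves[days == d]; kd <- keys[days == d]
      singles <- kd[lengths(strsplit(kd, "+", fixed = TRUE)) == 1]
      vapply(kd[lengths(strsplit(kd, "+", fixed = TRUE)) >= 2], function(key) {
        members <- condition_set(key)
        if (!all(members %in% singles)) return(NA_real_)
        A <- vapply(members, function(l) cd[[match(l, kd)]]$activity,
                    numeric(cfg$n_points))
        superpose(cd[[match(key, kd)]]$activity, A,
                  error_norm = cfg$error_norm)$relative_error
      }, numeric(1))
    }))
  }))
  per_day_err <- per_day_err[!is.na(per_day_err)]
  # exemplar baseline per prediction target
  baselines <- vapply(st$predictions, function(pr) {
    m <- st$matrices[[pr$promoter]]
    key <- condition_key(pr$target)
    if (!key %in% rownames(m)) return(NA_real_)
    others <- setdiff(rownames(m), key)
    baseline_exemplar_error(m[key, ],
                            lapply(others, function(k) m[k, ]),
                            norm = cfg$error_norm)
  }, numeric(1))
  pred_summary <- prediction_error_summary(st$predictions)
  # weight-sum statistics over the pair fits (one sum w_A + w_B per fit)
  unc_sizes <- vapply(st$fits$unconstrained, function(f)
    length(f$target_conditions), integer(1))
  wstats <- weight_sum_statistics(st$fits$unconstrained[unc_sizes == 2])
  # violation flags use, per (promoter, target), the best-fitting linear
  # combination: the smaller of the superposition and EIV errors
  best_fits <- lapply(seq_along(st$fits$superposition), function(i) {
    s <- st$fits$superposition[[i]]; u <- st$fits$unconstrained[[i]]
    if (u$relative_error < s$relative_error) u else s
  })
  viol <- flag_violations(best_fits, threshold = cfg$violation_threshold)
  sup_err <- vapply(st$fits$superposition, `[[`, numeric(1), "relative_error")
  pred_err <- vapply(st$predictions, function(p)
    p$relative_error_vs_measured %||% NA_real_, numeric(1))
  summary <- data.frame(
    metric = c("mean_day_to_day_error", "mean_fit_error_per_day",
               "mean_fit_error_day_averaged", "frac_day_fits_under_0.2",
               "weight_sum_mean", "weight_sum_sd",
               "frac_weights_positive", "median_prediction_error",
               "median_baseline_error", "n_flagged_promoters"),
    value = c(mean(rep_errors, na.rm = TRUE), mean(per_day_err),
              mean(sup_err), mean(per_day_err < 0.2),
              wstats$mean_sum, wstats$sd_sum,
              wstats$frac_positive,
              stats::median(pred_err, na.rm = TRUE),
              stats::median(baselines, na.rm = TRUE),
              length(unique(viol$promoter))))
  list(summary = summary, day_to_day = rep_errors,
       per_day_fit_errors = per_day_err,
       superposition_errors = sup_err,
       prediction_errors = pred_err, baseline_errors = baselines,
       prediction_summary = pred_summary, weight_stats = wstats,
       violations = viol, best_fit_errors = vapply(
         best_fits, `[[`, numeric(1), "relative_error"))
}
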