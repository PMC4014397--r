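#' Day-to-day replicate error of an activity curve
#'
#' Mean over all replicate pairs of the symmetrized relative fit error
#' `(err(a,b) + err(b,a)) / 2` -- the L2 error ratio is asymmetric in its
#' denominator, and the symmetric mean makes the estimate invariant to
#' replicate ordering. This is the empirical noise floor against which fit
#' and prediction errors are judged.
#'
#' @param replicate_curves list of >= 2 [activity_curve()] objects for the
#'   same promoter and condition, on a shared grid.
#' @param norm error norm, see [relative_fit_error()].
#' @return mean pairwise error, or `NA` with fewer than 2 replicates.
#' @export
day_to_day_error <- function(replicate_curves, norm = "l2") {
  if (length(replicate_curves) < 2L) return(NA_real_)
  val <- function(x) if (inherits(x, "activity_curve")) x$activity else as.numeric(x)
  vs <- lapply(replicate_curves, val)
  pairs <- utils::combn(length(vs), 2, simplify = FALSE)
  mean(vapply(pairs, function(p) {
    a <- vs[[p[1]]]; b <- vs[[p[2]]]
    (relative_fit_error(a, b, norm) + relative_fit_error(b, a, norm)) / 2
  }, numeric(1)))
}

#' Exemplar baseline error for a condition's dynamics
#'
#' The no-information baseline: "predict" the promoter's dynamics in the
#' target condition by each measured curve of the same promoter in every
#' other condition, and average the resulting relative errors. The average
#' is exhaustive over exemplars, so the statistic is deterministic (random
#' sampling of exemplars converges to this mean).
#'
#' @param measured [activity_curve()] (or numeric) in the target condition.
#' @param exemplars list of the promoter's curves in all other conditions,
#'   on the same grid.
#' @param norm error norm, see [relative_fit_error()].
#' @return mean relative error over all exemplars.
#' @export
baseline_exemplar_error <- function(measured, exemplars, norm = "l2") {
  stopifnot(length(exemplars) >= 1L)
  val <- function(x) if (inherits(x, "activity_curve")) x$activity else as.numeric(x)
  y <- val(measured)
  mean(vapply(exemplars, function(e) relative_fit_error(val(e), y, norm),
              numeric(1)))
}

#' Summarize prediction errors by cocktail size
#'
#' @param predictions list of prediction records, each with `target`
#'   (condition set) and `relative_error_vs_measured`.
#' @param bin_edges error values at which the cumulative histogram is
#'   evaluated (default `seq(0, 1, 0.05)`).
#' @return list with `medians` (named by cocktail size; sizes with no
#'   predictions are absent) and `histogram`, a data frame of (size,
#'   error_bin, cumulative_fraction).
#' @export
prediction_error_summary <- function(predictions, bin_edges = seq(0, 1, 0.05)) {
  sizes <- vapply(predictions, function(p) length(condition_set(p$target)), integer(1))
  errs <- vapply(predictions, function(p)
    p$relative_error_vs_measured %||% NA_real_, numeric(1))
  ok <- !is.na(errs)
  sizes <- sizes[ok]; errs <- errs[ok]
  medians <- tapply(errs, sizes, stats::median)
  hist <- do.call(rbind, lapply(sort(unique(sizes)), function(s) {
    e <- errs[sizes == s]
    data.frame(size = s, error_bin = bin_edges,
               cumulative_fraction = vapply(bin_edges, function(b) mean(e <= b),
                                            numeric(1)))
  }))
  list(medians = medians, histogram = hist)
}

#' Flag promoters violating linear superposition
#'
#' A promoter is flagged when the relative error of its best-fit linear
#' combination exceeds `threshold` in any fitted combined condition --
#' the signature of sequential regulation (diauxie-like dynamics) that a
#' constant-weight mixture cannot reproduce.
#'
#' @param fits list of `superpose_fit` objects (the best linear-combination
#'   fit per promoter and combined condition).
#' @param threshold relative-error threshold (default 0.2).
#' @return data frame of flagged (promoter, target, relative_error) rows;
#'   zero rows when nothing is flagged.
#' @export
flag_violations <- function(fits, threshold = 0.2) {
  if (threshold <= 0) stop("threshold must be > 0")
  d <- data.frame(
    promoter = vapply(fits, `[[`, character(1), "promoter"),
    target = vapply(fits, function(f) condition_key(f$target_conditions), character(1)),
    relative_error = vapply(fits, `[[`, numeric(1), "relative_error"))
  d[d$relative_error > threshold, , drop = FALSE]
}

#' Read a supplementary-style weight table
#'
#' Reads a CSV in the layout written by [write_fits_csv()]: one row per
#' (promoter, combined condition), per-single weight columns `w_*`, and a
#' `relative_error` column.
#'
#' @param path CSV path (optionally gzipped).
#' @return data frame.
#' @export
read_weight_table <- function(path) {
  d <- utils::read.csv(path)
  if (!"relative_error" %in% names(d))
    stop("weight table lacks a 'relative_error' column")
  d
}

#' Summarize a weight table's fit errors
#'
#' Recomputes the two headline fit-quality summaries from a weight table:
#' the mean relative fit error and the fraction of fits with error below
#' `threshold`.
#'
#' @param table data frame from [read_weight_table()].
#' @param threshold error cutoff for the "good fit" fraction (default 0.2).
#' @return list with `mean_error`, `frac_under_threshold`, `n`.
#' @export
summarize_weight_table <- function(table, threshold = 0.2) {
  e <- table$relative_error
  e <- e[!is.na(e)]
  if (!length(e)) stop("weight table has no usable relative_error values")
  list(mean_error = mean(e),
       frac_under_threshold = mean(e < threshold),
       n = length(e))
}
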