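#' Fit a combined-condition activity curve as a mixture of single-condition
#' curves
#'
#' `superpose()` is the package's central model fit. Given the measured
#' activity dynamics of a promoter in a combined condition (the *target*)
#' and in each of the component single conditions (the *singles*), all on a
#' shared generation grid, it estimates mixture weights \eqn{w_i} such that
#' the target is approximated by \eqn{\sum_i w_i P_i}, under one of three
#' models:
#'
#' \describe{
#'   \item{`"superposition"`}{linear superposition: least squares subject to
#'     \eqn{w_i \ge 0} and \eqn{\sum_i w_i = 1} (a weighted average; for a
#'     pair this is a single free parameter in `[0,1]`). Solved exactly by
#'     active-set enumeration over weight supports.}
#'   \item{`"unconstrained"`}{error-in-variables (total least squares)
#'     linear combination: both target and singles are treated as noisy
#'     with equal error variance; solved via the right singular vector of
#'     the smallest singular value of the stacked matrix `[singles |
#'     target]`, renormalized so the target coefficient is -1. No sign or
#'     sum constraints.}
#'   \item{`"multiplicative"`}{log-domain superposition: `ln(target)` fitted
#'     as \eqn{\sum_i w_i \ln P_i} on the simplex, i.e. the target is
#'     modeled as a weighted geometric mean of the singles. Curves are
#'     floored at `floor_frac` times their maximum before taking logs; the
#'     reported fit error is computed in the original linear domain.}
#' }
#'
#' The relative fit error is \eqn{\|fit - measured\|_2 / \|measured\|_2}
#' (`error_norm = "l2"`), or a mean-absolute variant. The AIC is
#' \eqn{n \ln(RSS/n) + 2k} under a Gaussian likelihood with unknown common
#' variance, where `k` counts free weight parameters: `N - 1` on the simplex
#' (the sum constraint removes one), `N` unconstrained.
#'
#' @param target an [activity_curve()] (or numeric vector) for the combined
#'   condition.
#' @param singles named list of [activity_curve()] (or a numeric matrix with
#'   named columns), one per single condition, on the identical grid as
#'   `target`.
#' @param model `"superposition"` (default), `"unconstrained"` or
#'   `"multiplicative"`.
#' @param error_norm `"l2"` (default) or `"mae"` for the relative error.
#' @param floor_frac positivity floor for the multiplicative model, as a
#'   fraction of each curve's maximum (default `1e-6`).
#' @param kappa_max condition-number threshold above which a collinearity
#'   note is recorded in the fit (default 15). Mixture weights become
#'   unidentifiable once the singles' condition number exceeds roughly the
#'   reciprocal of the relative curve noise (about 0.07 for 14% day-to-day
#'   error averaged over four replicates), so fits beyond that carry a
#'   warning in their metadata and are excluded from "well-conditioned"
#'   summaries.
#' @return an object of class `superpose_fit` with components `weights`
#'   (named), `fitted`, `measured`, `generations`, `relative_error`, `rss`,
#'   `aic`, `k`, `n_points`, `model`, `promoter`, `target_conditions`,
#'   `notes`. Supports `print`, `summary`, `coef`, `fitted`, `residuals`,
#'   `predict` and `plot`.
#' @examples
#' g <- seq(0, 6, length.out = 50)
#' pa <- exp(-(g - 2)^2); pb <- exp(-(g - 4)^2)
#' tgt <- 0.3 * pa + 0.7 * pb
#' fit <- superpose(tgt, list(A = pa, B = pb))
#' coef(fit)   # 0.3, 0.7
#' @export
superpose <- function(target, singles,
                      model = c("superposition", "unconstrained", "multiplicative"),
                      error_norm = c("l2", "mae"),
                      floor_frac = 1e-6, kappa_max = 15) {
  model <- match.arg(model)
  error_norm <- match.arg(error_norm)
  ex <- extract_curves(target, singles)
  y <- ex$y; A <- ex$A
  n <- length(y); N <- ncol(A)
  if (n < N + 2L)
    stop("superpose: need at least ", N + 2L, " grid points for ", N, " singles")
  notes <- character(0)
  kappa <- tryCatch({d <- svd(A, nu = 0, nv = 0)$d; d[1] / d[length(d)]},
                    error = function(e) Inf)
  if (!is.finite(kappa) || kappa > kappa_max)
    notes <- c(notes, sprintf("singles nearly collinear (condition number %.3g)", kappa))
  if (model == "superposition") {
    w <- simplex_ls(A, y)
    fit <- as.vector(A %*% w)
    k <- N - 1L
  } else if (model == "unconstrained") {
    tl <- tls_weights(A, y)
    w <- tl$w
    notes <- c(notes, tl$notes)
    fit <- as.vector(A %*% w)
    k <- N
  } else {
    fl <- apply(A, 2, function(col) {
      mx <- max(col)
      if (mx <= 0) stop("multiplicative model: non-positive curve after floor")
      pmax(col, floor_frac * mx)
    })
    my <- max(y)
    if (my <= 0) stop("multiplicative model: non-positive target after floor")
    yf <- pmax(y, floor_frac * my)
    w <- simplex_ls(log(fl), log(yf))
    fit <- exp(as.vector(log(fl) %*% w))
    k <- N - 1L
  }
  names(w) <- colnames(A)
  rss <- sum((fit - y)^2)
  structure(list(
    promoter = ex$promoter,
    target_conditions = ex$target_conditions,
    model = model,
    weights = w,
    fitted = fit,
    measured = y,
    generations = ex$generations,
    relative_error = relative_fit_error(fit, y, norm = error_norm),
    error_norm = error_norm,
    rss = rss,
    k = k,
    n_points = n,
    aic = n * log(rss / n) + 2 * k,
    notes = notes), class = "superpose_fit")
}

# Pull numeric target/singles out of activity curves (or accept raw
# numerics), checking grid identity.
extract_curves <- function(target, singles) {
  val <- function(x) if (inherits(x, "activity_curve")) x$activity else as.numeric(x)
  gen <- function(x) if (inherits(x, "activity_curve")) x$generations else NULL
  y <- val(target)
  g0 <- gen(target)
  if (!is.null(g0) && is.list(singles)) {
    for (s in singles)
      if (inherits(s, "activity_curve") && !isTRUE(all.equal(s$generations, g0)))
        stop("superpose: curves are not on the identical shared grid")
  }
  if (is.matrix(singles)) {
    A <- singles
  } else {
    stopifnot(is.list(singles), length(singles) >= 1L)
    A <- vapply(singles, val, numeric(length(y)))
    if (is.null(colnames(A)))
      colnames(A) <- names(singles)
  }
  if (is.null(colnames(A)) || any(!nzchar(colnames(A)))) {
    nm <- if (is.list(singles) && all(vapply(singles, inherits, logical(1), "activity_curve")))
      vapply(singles, function(s) condition_key(s$condition_set), character(1))
    else paste0("s", seq_len(ncol(A)))
    colnames(A) <- nm
  }
  if (nrow(A) != length(y)) stop("superpose: length mismatch between target and singles")
  list(y = y, A = A,
       promoter = if (inherits(target, "activity_curve")) target$promoter else "",
       target_conditions = if (inherits(target, "activity_curve"))
         target$condition_set else character(0),
       generations = g0 %||% seq_along(y))
}

# Exact simplex-constrained least squares: enumerate weight supports, solve
# the equality-constrained problem on each by its KKT system, keep feasible
# candidates, return the best. Intended for the small single counts (<= 4)
# of condition cocktails; complexity 2^N - 1 supports.
simplex_ls <- function(A, y) {
  N <- ncol(A)
  best <- NULL; best_obj <- Inf
  for (bits in seq_len(2^N - 1)) {
    S <- which(bitwAnd(bits, 2^(seq_len(N) - 1)) > 0)
    As <- A[, S, drop = FALSE]
    ns <- length(S)
    K <- rbind(cbind(2 * crossprod(As), rep(1, ns)), c(rep(1, ns), 0))
    rhs <- c(2 * crossprod(As, y), 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    ws <- sol[seq_len(ns)]
    if (any(ws < -1e-10)) next
    obj <- sum((As %*% ws - y)^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      w <- numeric(N); w[S] <- ws
      best <- w
    }
  }
  if (is.null(best)) stop("simplex_ls: no feasible support (degenerate inputs)")
  best <- pmax(best, 0)
  best / sum(best)
}

# Total least squares weights: smallest right singular vector of [A | y],
# scaled so the target coefficient is -1. Falls back to OLS when that
# coefficient vanishes (target orthogonal to the small singular direction).
tls_weights <- function(A, y) {
  X <- cbind(A, y)
  sv <- svd(X)
  v <- sv$v[, ncol(X)]
  notes <- character(0)
  if (abs(v[length(v)]) < 1e-12) {
    w <- as.vector(qr.solve(A, y))
    notes <- "TLS degenerate (zero target coefficient); ordinary least squares used"
  } else {
    w <- -v[-length(v)] / v[length(v)]
  }
  list(w = w, notes = notes)
}

#' Relative fit error between a fitted and a measured curve
#'
#' The default is the L2 norm ratio \eqn{\|fit - measured\|_2 /
#' \|measured\|_2}; `norm = "mae"` uses mean absolute deviation over mean
#' absolute signal instead. Reported numbers throughout the package state
#' which norm was used.
#'
#' @param fit_curve numeric vector (model curve).
#' @param measured numeric vector, same length, not all zero.
#' @param norm `"l2"` (default) or `"mae"`.
#' @return non-negative fraction.
#' @export
relative_fit_error <- function(fit_curve, measured, norm = c("l2", "mae")) {
  norm <- match.arg(norm)
  if (length(fit_curve) != length(measured))
    stop("relative_fit_error: length mismatch")
  if (all(measured == 0)) stop("relative_fit_error: measured curve is all zero")
  if (norm == "l2")
    sqrt(sum((fit_curve - measured)^2)) / sqrt(sum(measured^2))
  else
    mean(abs(fit_curve - measured)) / mean(abs(measured))
}

#' @rdname superpose
#' @param ... arguments passed on to [superpose()].
#' @export
fit_linear_unconstrained <- function(target, singles, ...)
  superpose(target, singles, model = "unconstrained", ...)

#' @rdname superpose
#' @export
fit_linear_superposition <- function(target, singles, ...)
  superpose(target, singles, model = "superposition", ...)

#' @rdname superpose
#' @export
fit_multiplicative <- function(target, singles, ...)
  superpose(target, singles, model = "multiplicative", ...)

#' Rank competing fits of one target by AIC
#'
#' All fits must concern the same target curve (same `n_points`). Lower AIC
#' wins; ties are broken toward fewer parameters.
#'
#' @param fits list of `superpose_fit` objects.
#' @return data frame (model, k, rss, relative_error, aic, delta_aic),
#'   ordered best first.
#' @export
aic_compare <- function(fits) {
  stopifnot(length(fits) >= 1L)
  n <- unique(vapply(fits, `[[`, integer(1), "n_points"))
  if (length(n) != 1L) stop("aic_compare: fits have differing n_points")
  d <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    k = vapply(fits, `[[`, integer(1), "k"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    relative_error = vapply(fits, `[[`, numeric(1), "relative_error"),
    aic = vapply(fits, `[[`, numeric(1), "aic"))
  d <- d[order(d$aic, d$k), , drop = FALSE]
  d$delta_aic <- d$aic - d$aic[1]
  rownames(d) <- NULL
  d
}

#' Summary statistics of unconstrained weight sums
#'
#' For a collection of unconstrained (error-in-variables) fits, summarizes
#' the distribution of the per-fit weight sums \eqn{\sum_i w_i} -- under
#' linear superposition these concentrate around one -- and the fraction of
#' individual weights exceeding -0.05 (i.e. not meaningfully negative).
#' The standard deviation is the sample (n-1) convention.
#'
#' @param fits list of `superpose_fit` objects with `model ==
#'   "unconstrained"`.
#' @return list with `mean_sum`, `sd_sum`, `median_sum`, `frac_positive`,
#'   `n_fits`. The median is reported alongside the mean because
#'   error-in-variables estimates on nearly collinear singles have heavy
#'   tails that can dominate the sample mean.
#' @export
weight_sum_statistics <- function(fits) {
  if (length(fits) == 0L) stop("weight_sum_statistics: empty input")
  if (!all(vapply(fits, `[[`, character(1), "model") == "unconstrained"))
    stop("weight_sum_statistics: all fits must be unconstrained")
  sums <- vapply(fits, function(f) sum(f$weights), numeric(1))
  all_w <- unlist(lapply(fits, `[[`, "weights"))
  list(mean_sum = mean(sums),
       sd_sum = if (length(sums) > 1) stats::sd(sums) else NA_real_,
       median_sum = stats::median(sums),
       frac_positive = mean(all_w > -0.05),
       n_fits = length(fits))
}

#' @export
print.superpose_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<superpose_fit> %s%s | model %s\n",
              if (nzchar(x$promoter)) paste0(x$promoter, " ") else "",
              if (length(x$target_conditions))
                condition_key(x$target_conditions) else "",
              x$model))
  cat("  weights: ",
      paste(sprintf("%s=%.*f", names(x$weights), digits, x$weights),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  relative error (%s): %.*f | AIC: %.*f | n = %d\n",
              x$error_norm, digits, x$relative_error, digits, x$aic, x$n_points))
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.superpose_fit <- function(object, ...) {
  structure(list(fit = object,
                 weight_sum = sum(object$weights),
                 rmse = sqrt(object$rss / object$n_points)),
            class = "summary.superpose_fit")
}

#' @export
print.summary.superpose_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  weight sum: %.4f | RMSE: %.4g\n", x$weight_sum, x$rmse))
  invisible(x)
}

#' @export
coef.superpose_fit <- function(object, ...) object$weights

#' @export
fitted.superpose_fit <- function(object, ...) object$fitted

#' @export
residuals.superpose_fit <- function(object, ...) object$measured - object$fitted

#' Predict a mixture curve from a fitted superposition model
#'
#' Applies the fitted weights to a (possibly new) set of single-condition
#' curves. With no `newdata`, returns the fitted values.
#'
#' @param object a `superpose_fit`.
#' @param newdata optional named list of [activity_curve()] or numeric
#'   vectors matching the fit's single names.
#' @param ... unused.
#' @return numeric vector of predicted activity.
#' @export
predict.superpose_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  val <- function(x) if (inherits(x, "activity_curve")) x$activity else as.numeric(x)
  nm <- names(object$weights)
  if (!all(nm %in% names(newdata)))
    stop("newdata is missing singles: ",
         paste(setdiff(nm, names(newdata)), collapse = ", "))
  A <- vapply(newdata[nm], val, numeric(length(val(newdata[[1]]))))
  if (object$model == "multiplicative")
    exp(as.vector(log(pmax(A, 1e-300)) %*% object$weights))
  else as.vector(A %*% object$weights)
}

#' @export
plot.superpose_fit <- function(x, ...) {
  graphics::plot(x$generations, x$measured, type = "l", lwd = 2, col = "steelblue",
                 xlab = "generations", ylab = "promoter activity",
                 main = sprintf("%s %s (%s, err %.2f)", x$promoter,
                                condition_key(x$target_conditions), x$model,
                                x$relative_error), ...)
  graphics::lines(x$generations, x$fitted, lwd = 2, col = "black", lty = 2)
  graphics::legend("topright", c("measured", "fitted"), lwd = 2,
                   col = c("steelblue", "black"), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Write a table of fits as CSV
#'
#' One row per (promoter, target condition), with one weight column per
#' single condition plus `relative_error`, `model`, `aic` -- the layout of a
#' supplementary weight table.
#'
#' @param fits list of `superpose_fit` objects.
#' @param path output CSV path.
#' @return invisibly, the written data frame.
#' @export
write_fits_csv <- function(fits, path) {
  labs <- sort(unique(unlist(lapply(fits, function(f) names(f$weights)))))
  rows <- lapply(fits, function(f) {
    r <- data.frame(promoter = f$promoter,
                    target = condition_key(f$target_conditions))
    for (l in labs) r[[paste0("w_", l)]] <-
      if (l %in% names(f$weights)) unname(f$weights[l]) else NA_real_
    r$relative_error <- f$relative_error
    r$model <- f$model
    r$aic <- f$aic
    r
  })
  d <- do.call(rbind, rows)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}
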