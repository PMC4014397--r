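#' Predict N-cocktail mixture weights from all (N-1)-cocktail weights
#'
#' Under linear superposition an N-supplement cocktail can be decomposed in
#' N ways into one missing supplement plus the remaining (N-1)-cocktail, and
#' all decompositions must agree. That self-consistency determines the full
#' weight vector from the lower-order ones: writing \eqn{w_i^{(\neq j)}} for
#' the weight of single condition i within the cocktail missing supplement
#' j, the prediction is
#' \deqn{w_i = \frac{N - 2}{\sum_{j \ne i} 1 / w_i^{(\neq j)} - 1}.}
#' If simplex weights \eqn{w^*} exist such that every lower-order weight is
#' the renormalized restriction \eqn{w_i^{(\neq j)} = w^*_i / (1 - w^*_j)},
#' the formula returns \eqn{w^*} exactly. Any non-positive lower-order
#' weight propagates to a zero prediction for that supplement; the raw
#' result is then clipped to `[0, 1]` and renormalized to sum to one.
#'
#' @param lower_order named list with one element per (N-1)-subset of the
#'   target, keyed by [condition_key()]; each element is a named numeric
#'   weight vector (or a `superpose_fit`, whose coefficients are used).
#' @return named numeric vector of predicted weights over the N single
#'   conditions, summing to one.
#' @examples
#' # ground truth (0.5, 0.3, 0.2); pairs are renormalized restrictions
#' lo <- list("A+B" = c(A = 0.625, B = 0.375),
#'            "A+C" = c(A = 5/7, C = 2/7),
#'            "B+C" = c(B = 0.6, C = 0.4))
#' predict_weights(lo)
#' @export
predict_weights <- function(lower_order) {
  stopifnot(is.list(lower_order), length(lower_order) >= 1L)
  wlist <- lapply(lower_order, function(x) {
    if (inherits(x, "superpose_fit")) stats::coef(x) else x
  })
  labels <- condition_set(unlist(lapply(wlist, names)))
  N <- length(labels)
  if (N < 3L) stop("predict_weights: target must have at least 3 supplements")
  subs <- lapply(labels, function(j) setdiff(labels, j))
  keys <- vapply(subs, condition_key, character(1))
  have <- vapply(wlist, function(w) condition_key(names(w)), character(1))
  miss <- setdiff(keys, have)
  if (length(miss))
    stop("predict_weights: missing lower-order weights for: ",
         paste(miss, collapse = ", "))
  raw <- vapply(labels, function(i) {
    others <- setdiff(labels, i)
    wij <- vapply(others, function(j) {
      w <- wlist[[match(condition_key(setdiff(labels, j)), have)]]
      unname(w[i])
    }, numeric(1))
    if (any(is.na(wij)))
      stop("predict_weights: weight for '", i, "' absent from a lower-order fit")
    if (any(wij <= 0)) return(0)
    (N - 2) / (sum(1 / wij) - 1)
  }, numeric(1))
  w <- pmin(pmax(raw, 0), 1)
  if (sum(w) == 0) w <- rep(1 / N, N)
  w <- w / sum(w)
  names(w) <- labels
  w
}

#' Predict cocktail weights iteratively from pair weights alone
#'
#' Builds every triplet's weights from the pairs via [predict_weights()],
#' then every quadruplet from the predicted triplets, and so on up to the
#' target cocktail.
#'
#' @param pair_fits named list keyed by pair [condition_key()] covering all
#'   `choose(N, 2)` pairs of the target's labels; elements are named weight
#'   vectors or `superpose_fit` objects.
#' @param target character vector (or key) of the target condition set,
#'   size >= 3.
#' @return named numeric vector of predicted weights for `target`.
#' @export
predict_weights_iterative <- function(pair_fits, target) {
  target <- condition_set(target)
  N <- length(target)
  if (N < 3L) stop("predict_weights_iterative: target must have >= 3 supplements")
  wlist <- lapply(pair_fits, function(x) {
    if (inherits(x, "superpose_fit")) stats::coef(x) else x
  })
  names(wlist) <- vapply(wlist, function(w) condition_key(names(w)), character(1))
  pairs <- utils::combn(target, 2, simplify = FALSE)
  miss <- setdiff(vapply(pairs, condition_key, character(1)), names(wlist))
  if (length(miss))
    stop("predict_weights_iterative: missing pair fit(s): ",
         paste(miss, collapse = ", "))
  level <- wlist
  for (k in 3:N) {
    subsets <- utils::combn(target, k, simplify = FALSE)
    nxt <- lapply(subsets, function(S) {
      lower <- lapply(S, function(j) level[[condition_key(setdiff(S, j))]])
      predict_weights(lower)
    })
    names(nxt) <- vapply(subsets, condition_key, character(1))
    level <- nxt
  }
  level[[condition_key(target)]]
}

#' Compose a predicted mixture curve from weights and single curves
#'
#' @param predicted_weights named numeric weights over single conditions.
#' @param singles named list of [activity_curve()] (or numeric vectors) on a
#'   shared grid, names matching the weights.
#' @return numeric vector: the point-wise weighted sum of the singles.
#' @export
predict_dynamics <- function(predicted_weights, singles) {
  val <- function(x) if (inherits(x, "activity_curve")) x$activity else as.numeric(x)
  nm <- names(predicted_weights)
  if (is.null(nm) || !all(nm %in% names(singles)))
    stop("predict_dynamics: singles missing for: ",
         paste(setdiff(nm, names(singles)), collapse = ", "))
  A <- vapply(singles[nm], val, numeric(length(val(singles[[nm[1]]]))))
  as.vector(A %*% predicted_weights)
}

#' Write cocktail weight predictions as CSV
#'
#' @param predictions list of records, each with fields `promoter`,
#'   `target` (condition set), `predicted_weights` (named), and optionally
#'   `relative_error_vs_measured`.
#' @param path output CSV path.
#' @return invisibly, the written data frame.
#' @export
write_predictions_csv <- function(predictions, path) {
  labs <- sort(unique(unlist(lapply(predictions, function(p)
    names(p$predicted_weights)))))
  rows <- lapply(predictions, function(p) {
    r <- data.frame(promoter = p$promoter,
                    target = condition_key(p$target))
    for (l in labs) r[[paste0("w_", l)]] <-
      if (l %in% names(p$predicted_weights)) unname(p$predicted_weights[l]) else NA_real_
    r$relative_error_vs_measured <-
      if (!is.null(p$relative_error_vs_measured)) p$relative_error_vs_measured else NA_real_
    r
  })
  d <- do.call(rbind, rows)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}
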