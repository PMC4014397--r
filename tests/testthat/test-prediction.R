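# Build the self-consistent lower-order weights of a simplex point:
# within the cocktail missing supplement j, the weight of i is
# w*_i / (1 - w*_j).
restrict_weights <- function(wstar, drop) {
  keep <- setdiff(names(wstar), drop)
  wstar[keep] / sum(wstar[keep])
}
consistent_lower <- function(wstar) {
  labs <- names(wstar)
  lo <- lapply(labs, function(j) restrict_weights(wstar, j))
  names(lo) <- vapply(lo, function(w) condition_key(names(w)), character(1))
  lo
}

test_that("the prediction formula is exact on self-consistent weights", {
  # symmetric case: all pair weights 1/2 -> thirds
  lo <- list("A+B" = c(A = 0.5, B = 0.5),
             "A+C" = c(A = 0.5, C = 0.5),
             "B+C" = c(B = 0.5, C = 0.5))
  expect_equal(unname(predict_weights(lo)), rep(1 / 3, 3), tolerance = 1e-12)
  # worked example: w* = (0.5, 0.3, 0.2)
  wstar <- c(A = 0.5, B = 0.3, C = 0.2)
  lo2 <- consistent_lower(wstar)
  expect_equal(lo2[["A+B"]][["A"]], 0.625, tolerance = 1e-12)
  expect_equal(lo2[["A+C"]][["A"]], 1 / 1.4, tolerance = 1e-12)
  expect_equal(predict_weights(lo2), wstar, tolerance = 1e-12)
  # N = 4 uniform: triplet weights 1/3 -> (N-2)/(3*3-1) = 1/4 each
  wu <- c(A = .25, B = .25, C = .25, D = .25)
  expect_equal(predict_weights(consistent_lower(wu)), wu, tolerance = 1e-12)
})

test_that("prediction is exact over random simplex ground truths", {
  set.seed(41)
  for (N in c(3, 4)) {
    labs <- LETTERS[1:N]
    errs <- vapply(1:250, function(i) {
      w <- rexp(N); w <- w / sum(w); names(w) <- labs
      max(abs(predict_weights(consistent_lower(w)) - w))
    }, numeric(1))
    expect_lt(max(errs), 1e-9)
  }
})

test_that("prediction handles zeros, missing inputs, and relabeling", {
  # zero propagation: a supplement with zero weight in some pair stays zero
  wstar <- c(A = 0.6, B = 0.4, C = 0)
  lo <- consistent_lower(wstar)
  expect_equal(predict_weights(lo), wstar, tolerance = 1e-9)
  # missing subset is an error listing the subset
  expect_error(predict_weights(lo[c("A+B", "A+C")]), "B\\+C")
  # permutation equivariance: relabeling conditions permutes predictions
  set.seed(42)
  w <- c(A = 0.5, B = 0.3, C = 0.15, D = 0.05)
  p1 <- predict_weights(consistent_lower(w))
  relab <- c(A = "C", B = "D", C = "A", D = "B")
  w2 <- stats::setNames(w, relab[names(w)])
  p2 <- predict_weights(consistent_lower(w2))
  expect_equal(p2[relab[names(p1)]], stats::setNames(p1, relab[names(p1)]),
               tolerance = 1e-12)
})

test_that("iterative pair-based prediction recovers the quadruplet", {
  set.seed(43)
  w <- rexp(4); w <- w / sum(w); names(w) <- LETTERS[1:4]
  pairs <- utils::combn(names(w), 2, simplify = FALSE)
  pair_w <- lapply(pairs, function(S) w[S] / sum(w[S]))
  names(pair_w) <- vapply(pairs, condition_key, character(1))
  got <- predict_weights_iterative(pair_w, LETTERS[1:4])
  expect_equal(got, w, tolerance = 1e-10)
  # uniform pairs give the uniform quadruplet
  unif <- lapply(pairs, function(S) stats::setNames(c(.5, .5), S))
  names(unif) <- names(pair_w)
  expect_equal(unname(predict_weights_iterative(unif, LETTERS[1:4])),
               rep(0.25, 4), tolerance = 1e-12)
  # missing pair errors
  expect_error(predict_weights_iterative(pair_w[-1], LETTERS[1:4]), "A\\+B")
})

test_that("prediction degrades gracefully and stays near truth under noise", {
  set.seed(44)
  noise_levels <- c(0.02, 0.05, 0.1)
  med_err <- vapply(noise_levels, function(s) {
    errs <- vapply(1:200, function(i) {
      w <- rexp(4); w <- w / sum(w); names(w) <- LETTERS[1:4]
      pairs <- utils::combn(names(w), 2, simplify = FALSE)
      pair_w <- lapply(pairs, function(S) {
        pw <- w[S] / sum(w[S]) + runif(2, -s, s)
        pw <- pmax(pw, 1e-6); pw / sum(pw)
      })
      names(pair_w) <- vapply(pairs, condition_key, character(1))
      max(abs(predict_weights_iterative(pair_w, LETTERS[1:4]) - w))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  # +-0.05 pair noise keeps the quadruplet within 0.15 of truth
  expect_lt(med_err[2], 0.15)
  # error grows monotonically with the injected noise scale
  expect_true(all(diff(med_err) > 0))
})

test_that("predicted dynamics compose single curves with the weights", {
  sh <- toy_shapes()
  singles <- list(A = 1 + sh$s1, B = 2 + sh$s2, C = 3 - sh$s1)
  expect_equal(predict_dynamics(c(A = 1, B = 0, C = 0), singles), singles$A)
  same <- list(A = singles$A, B = singles$A, C = singles$A)
  expect_equal(predict_dynamics(c(A = 1/3, B = 1/3, C = 1/3), same), singles$A,
               tolerance = 1e-12)
  expect_error(predict_dynamics(c(A = 1, Z = 0), singles), "Z")
  # noiseless simulator: the true combined curve is exactly the weighted
  # mixture of the true single curves with the true restricted weights
  truth <- generate_truth(4, synthetic_config(n_violators = 0), seed = 45)
  g <- seq(0.2, 5.8, length.out = 80)
  for (p in names(truth$promoters)) {
    S <- c("A", "B", "C")
    singles_true <- lapply(S, function(l) true_activity_fun(truth, p, l)(g))
    names(singles_true) <- S
    w <- true_weights(truth, p, S)
    combined <- true_activity_fun(truth, p, S)(g)
    expect_equal(predict_dynamics(w, singles_true), combined, tolerance = 1e-9)
  }
})
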