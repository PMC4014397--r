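test_that("exact mixtures are recovered by every linear model", {
  sh <- toy_shapes()
  pa <- 2 + sh$s1; pb <- 2 + sh$s2
  tgt <- 0.4 * pa + 0.6 * pb
  for (model in c("superposition", "unconstrained")) {
    f <- superpose(tgt, list(A = pa, B = pb), model = model)
    expect_equal(unname(coef(f)), c(0.4, 0.6), tolerance = 1e-9)
    expect_equal(f$relative_error, 0, tolerance = 1e-9)
  }
  # target equal to one single
  f1 <- superpose(pa, list(A = pa, B = pb))
  expect_equal(unname(coef(f1)), c(1, 0), tolerance = 1e-9)
  f1u <- superpose(pa, list(A = pa, B = pb), model = "unconstrained")
  expect_equal(unname(coef(f1u)), c(1, 0), tolerance = 1e-8)
})

test_that("simplex fit projects onto the boundary for out-of-hull targets", {
  sh <- toy_shapes()
  # orthogonal singles: target 0.3/0.7 mixture recovered; 2 * P_A clips to (1,0)
  f <- superpose(0.3 * sh$s1 + 0.7 * sh$s2, list(A = sh$s1, B = sh$s2))
  expect_equal(unname(coef(f)), c(0.3, 0.7), tolerance = 1e-9)
  f2 <- superpose(2 * sh$s1, list(A = sh$s1, B = sh$s2))
  expect_equal(unname(coef(f2)), c(1, 0), tolerance = 1e-9)
})

test_that("simplex fits match a fine grid search over the simplex", {
  set.seed(31)
  n <- 40
  for (rep in 1:20) {
    A <- matrix(runif(n * 3, 0, 2), n, 3)
    colnames(A) <- c("A", "B", "C")
    y <- A %*% runif(3) + rnorm(n, 0, 0.3)
    f <- superpose(as.vector(y), A)
    # grid search with 0.001 steps over the 3-simplex
    step <- 0.001
    w1 <- seq(0, 1, by = step)
    grid <- expand.grid(a = w1, b = w1)
    grid <- grid[grid$a + grid$b <= 1, ]
    W <- cbind(grid$a, grid$b, 1 - grid$a - grid$b)
    G <- crossprod(A); b2 <- crossprod(A, y)
    obj <- rowSums((W %*% G) * W) - 2 * as.vector(W %*% b2)
    best_grid <- min(obj) + as.numeric(crossprod(y))
    ours <- sum((A %*% coef(f) - y)^2)
    expect_lte(ours, best_grid + 1e-8)          # never worse than the grid
    expect_lt(abs(ours - best_grid) / max(ours, 1e-12), 0.01)
  }
})

test_that("unconstrained fits match an independent total-least-squares oracle", {
  set.seed(32)
  sh <- toy_shapes()
  for (rep in 1:20) {
    pa <- 2 + sh$s1 + rnorm(60, 0, 0.05)
    pb <- 2 + sh$s2 + rnorm(60, 0, 0.05)
    tgt <- 0.5 * pa + 0.8 * pb + rnorm(60, 0, 0.05)
    f <- superpose(tgt, list(A = pa, B = pb), model = "unconstrained")
    # oracle: smallest eigenvector of crossprod([A | y])
    X <- cbind(pa, pb, tgt)
    ev <- eigen(crossprod(X), symmetric = TRUE)$vectors
    v <- ev[, 3]
    w_oracle <- -v[1:2] / v[3]
    expect_equal(unname(coef(f)), w_oracle, tolerance = 1e-8)
  }
})

test_that("the simplex constraint can only worsen the least-squares objective", {
  set.seed(33)
  sh <- toy_shapes()
  for (rep in 1:25) {
    A <- cbind(A = 2 + sh$s1 + rnorm(60, 0, 0.1),
               B = 2 + sh$s2 + rnorm(60, 0, 0.1))
    y <- A %*% runif(2, 0, 1.5) + rnorm(60, 0, 0.2)
    fs <- superpose(as.vector(y), A)
    # ordinary least squares is the unconstrained optimum of the same
    # objective
    rss_ols <- sum(resid(lm.fit(A, as.vector(y)))^2)
    expect_gte(fs$rss + 1e-10, rss_ols)
    # and the TLS solution beats any fixed weights on the TLS objective
    tls_obj <- function(w) sum((A %*% w - y)^2) / (1 + sum(w^2))
    fu <- superpose(as.vector(y), A, model = "unconstrained")
    expect_lte(tls_obj(coef(fu)), tls_obj(coef(fs)) + 1e-10)
  }
})

test_that("multiplicative fits recover geometric-mean mixtures", {
  sh <- toy_shapes()
  pa <- 2 + sh$s1; pb <- 3 + sh$s2
  f <- superpose(sqrt(pa * pb), list(A = pa, B = pb), model = "multiplicative")
  expect_equal(unname(coef(f)), c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(f$relative_error, 0, tolerance = 1e-9)
  f1 <- superpose(pa, list(A = pa, B = pb), model = "multiplicative")
  expect_equal(unname(coef(f1)), c(1, 0), tolerance = 1e-8)
  # noisy geometric mixture, weights recovered within 0.02
  set.seed(34)
  errs <- vapply(1:20, function(i) {
    tgt <- exp(0.2 * log(pa) + 0.8 * log(pb)) * (1 + rnorm(60, 0, 0.01))
    fm <- superpose(tgt, list(A = pa, B = pb), model = "multiplicative")
    abs(coef(fm)[["A"]] - 0.2)
  }, numeric(1))
  expect_lt(median(errs), 0.02)
  # a linear (non-geometric) mixture is not fit exactly by the
  # multiplicative model
  flin <- superpose(0.5 * pa + 0.5 * pb, list(A = pa, B = pb),
                    model = "multiplicative")
  expect_gt(flin$relative_error, 1e-6)
})

test_that("relative fit error is the L2 norm ratio", {
  expect_equal(relative_fit_error(c(1, 2, 3), c(1, 2, 3)), 0)
  m <- runif(30, 1, 2)
  expect_equal(relative_fit_error(1.1 * m, m), 0.1, tolerance = 1e-12)
  set.seed(35)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(relative_fit_error(a, b),
               sqrt(sum((a - b)^2)) / sqrt(sum(b^2)), tolerance = 1e-12)
  expect_error(relative_fit_error(a, rep(0, 20)), "zero")
  expect_error(relative_fit_error(a, b[1:5]), "mismatch")
})

test_that("AIC follows n ln(RSS/n) + 2k and prefers parsimony on ties", {
  mk_fit <- function(rss, k, n = 100L) {
    structure(list(model = paste0("k", k), k = as.integer(k), rss = rss,
                   relative_error = 0.1, n_points = n,
                   aic = n * log(rss / n) + 2 * k), class = "superpose_fit")
  }
  # n = 100, RSS = 100, k = 1 -> AIC = 2
  expect_equal(mk_fit(100, 1)$aic, 2)
  # equal RSS: k = 1 beats k = 2 by exactly 2
  cmp <- aic_compare(list(mk_fit(50, 2), mk_fit(50, 1)))
  expect_identical(cmp$model[1], "k1")
  expect_equal(cmp$delta_aic[2], 2)
  expect_error(aic_compare(list(mk_fit(1, 1, 10L), mk_fit(1, 1, 20L))),
               "n_points")
})

test_that("model selection prefers superposition on superposition data", {
  # exact simplex mixtures plus exchangeable multiplicative noise at the
  # replicate-error scale: the extra amplitude parameter of the
  # unconstrained model should rarely justify its AIC cost
  sh <- toy_shapes()
  set.seed(36)
  prefer <- vapply(1:100, function(i) {
    pa <- (2 + sh$s1) * (1 + rnorm(60, 0, 0.14))
    pb <- (2 + sh$s2) * (1 + rnorm(60, 0, 0.14))
    w <- runif(1)
    tgt <- (w * (2 + sh$s1) + (1 - w) * (2 + sh$s2)) *
      (1 + rnorm(60, 0, 0.14))
    fits <- list(superpose(tgt, list(A = pa, B = pb)),
                 superpose(tgt, list(A = pa, B = pb), model = "unconstrained"))
    aic_compare(fits)$model[1] == "superposition"
  }, logical(1))
  expect_gte(mean(prefer), 0.8)
})

test_that("weight-sum statistics use sample conventions", {
  mk <- function(w) structure(list(model = "unconstrained", weights = w),
                              class = "superpose_fit")
  st <- weight_sum_statistics(list(mk(c(A = 0.3, B = 0.5)),
                                   mk(c(A = 0.7, B = 0.5))))
  expect_equal(st$mean_sum, 1.0)
  expect_equal(st$sd_sum, sd(c(0.8, 1.2)))        # sample SD ~ 0.283
  expect_equal(st$sd_sum, 0.2828427, tolerance = 1e-6)
  st2 <- weight_sum_statistics(list(mk(c(A = 0.5, B = 0.5))))
  expect_equal(st2$frac_positive, 1.0)
  expect_error(weight_sum_statistics(list()), "empty")
  expect_error(weight_sum_statistics(list(structure(list(model = "superposition",
    weights = 1), class = "superpose_fit"))), "unconstrained")
})

test_that("fit accessors and methods are coherent", {
  sh <- toy_shapes()
  pa <- 2 + sh$s1; pb <- 2 + sh$s2
  cur_t <- as_curve(0.25 * pa + 0.75 * pb, sh$g, conditions = "A+B")
  f <- superpose(cur_t, list(A = as_curve(pa, sh$g),
                             B = as_curve(pb, sh$g, conditions = "B")))
  expect_s3_class(f, "superpose_fit")
  expect_equal(fitted(f) + residuals(f), f$measured)
  expect_equal(predict(f), fitted(f))
  expect_equal(predict(f, newdata = list(A = pa, B = pb)), fitted(f))
  expect_equal(sum(coef(f)), 1, tolerance = 1e-8)
  expect_output(print(f), "superpose_fit")
  expect_output(print(summary(f)), "weight sum")
  # mismatched grids rejected
  expect_error(superpose(cur_t, list(A = as_curve(pa[1:59], sh$g[1:59]))),
               "grid")
})
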