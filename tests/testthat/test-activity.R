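test_that("promoter activity recovers slope over mean OD in closed forms", {
  # linear GFP ramp over constant OD: slope 2 / od 0.5 = 4, any window
  for (w in c(5L, 17L)) {
    s <- toy_series(n = 30, fluo = 2 * seq(0, by = 8, length.out = 30),
                    od = rep(0.5, 30))
    cur <- promoter_activity(s, window = w)
    expect_equal(cur$activity, rep(4, length(cur$activity)), tolerance = 1e-12)
  }
  # constant fluorescence: zero activity regardless of OD
  s0 <- toy_series(n = 25, fluo = rep(123, 25))
  expect_equal(promoter_activity(s0, window = 5)$activity, rep(0, 21),
               tolerance = 1e-12)
  # too-short series
  expect_error(promoter_activity(toy_series(n = 9), window = 17), "shorter")
})

test_that("windowed slopes match a brute-force per-window regression oracle", {
  t <- seq(0, 32 * 8, by = 8)
  s <- toy_series(n = length(t), fluo = t^2, od = rep(1, length(t)))
  cur <- promoter_activity(s, window = 5)
  h <- 2
  oracle <- vapply((h + 1):(length(t) - h), function(i) {
    idx <- (i - h):(i + h)
    unname(coef(lm(y ~ x, data.frame(x = t[idx], y = t[idx]^2)))[2])
  }, numeric(1))
  expect_equal(cur$activity, oracle, tolerance = 1e-10)
})

test_that("activity is exactly equivariant under fluorescence scaling", {
  set.seed(42)
  s <- toy_series(n = 40, fluo = cumsum(runif(40, 0, 50)))
  s3 <- s; s3$fluo <- 3 * s$fluo
  expect_equal(promoter_activity(s3)$activity, 3 * promoter_activity(s)$activity)
})

test_that("growth rate matches analytic forms", {
  # exact exponential: rate = ln2 / 60 everywhere
  t <- seq(0, 400, by = 8)
  s <- toy_series(n = length(t), od = 0.01 * 2^(t / 60))
  gr <- growth_rate(s, window = 17)
  expect_equal(gr$rate, rep(log(2) / 60, length(gr$rate)), tolerance = 1e-10)
  # constant OD: zero rate
  sc <- toy_series(n = 30, od = rep(0.08, 30))
  expect_equal(growth_rate(sc, window = 5)$rate, rep(0, 26), tolerance = 1e-12)
  # logistic growth: matches the analytic logistic rate within 1% away from
  # the endpoints
  cfg <- synthetic_config()
  tt <- dynsup:::condition_time_grid(cfg, "A")
  od <- dynsup:::logistic_od(cfg, "A", tt)
  sl <- plate_series("w", "p", "A", 1, tt, od, rep(0, length(tt)))
  grl <- growth_rate(sl, window = 5)
  r <- dynsup:::combo_rate(cfg, "A")
  truth <- r * (1 - od[match(grl$time_min, tt)] / cfg$od_max)
  core <- 5:(length(truth) - 5)
  expect_lt(max(abs(grl$rate[core] - truth[core]) / max(truth)), 0.01)
  # non-positive OD inside a window becomes missing
  odm <- rep(0.05, 20); odm[10] <- 0
  sm <- plate_series("w", "p", "A", 1, seq(0, by = 8, length.out = 20),
                     odm, rep(0, 20))
  expect_true(anyNA(growth_rate(sm, window = 5)$rate))
})

test_that("generation axis counts doublings and ignores the OD unit", {
  # one exact doubling across the curve
  t <- seq(0, 360, by = 8)
  s <- toy_series(n = length(t), od = 0.02 * 2^(t / 360))
  cur <- promoter_activity(s, window = 5)
  expect_equal(max(cur$generations) - min(cur$generations),
               diff(range(cur$time_min)) / 360, tolerance = 1e-9)
  # six generations over 360 min at a 60-min doubling time
  s6 <- toy_series(n = 46, od = 0.01 * 2^(seq(0, 360, by = 8) / 60))
  cur6 <- promoter_activity(s6, window = 5)
  expect_equal(max(cur6$generations), cur6$time_min[length(cur6$time_min)] / 60,
               tolerance = 1e-9)
  expect_equal(min(cur6$generations), cur6$time_min[1] / 60, tolerance = 1e-9)
  # od -> c * od leaves generations unchanged
  s_scaled <- s6; s_scaled$od <- 7.3 * s6$od
  expect_equal(promoter_activity(s_scaled, window = 5)$generations,
               cur6$generations, tolerance = 1e-12)
})

test_that("generation axis from noisy OD stays near the noiseless truth", {
  t <- seq(0, 360, by = 8)
  od0 <- 0.01 * 2^(t / 60)
  errs <- vapply(1:20, function(i) {
    set.seed(500 + i)
    od <- od0 * (1 + rnorm(length(t), 0, 0.01))
    s <- toy_series(n = length(t), od = pmax(od, 1e-6))
    cur <- promoter_activity(s, window = 17)
    max(abs(cur$generations - cur$time_min / 60))
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("resampling intersects ranges and is exact on linear signals", {
  g1 <- seq(0, 6, length.out = 40); g2 <- seq(1, 5, length.out = 40)
  c1 <- as_curve(2 * g1 + 1, g1); c2 <- as_curve(3 * g2 - 1, g2)
  out <- resample_to_common_grid(list(c1, c2), n_points = 25)
  expect_equal(range(out[[1]]$generations), c(1, 5))
  expect_equal(out[[1]]$generations, out[[2]]$generations)
  # linear functions are reproduced exactly at the nodes
  expect_equal(out[[1]]$activity, 2 * out[[1]]$generations + 1, tolerance = 1e-12)
  expect_equal(out[[2]]$activity, 3 * out[[2]]$generations - 1, tolerance = 1e-12)
  # identical curves stay identical
  same <- resample_to_common_grid(list(c1, c1), n_points = 40)
  expect_equal(same[[1]]$activity, same[[2]]$activity)
  # empty intersection errors, naming offenders
  c3 <- as_curve(rep(1, 10), seq(10, 12, length.out = 10))
  expect_error(resample_to_common_grid(list(c1, c3)), "intersection")
})

test_that("activity estimation inverts the simulator's GFP integral", {
  # render a known smooth activity with no noise; the sliding-window
  # estimator should recover it within 2% RMS away from the endpoints
  truth <- generate_truth(2, synthetic_config(n_violators = 0), seed = 77)
  coll <- render_plate(truth, seed = 78, condition_sets = list("C"),
                       days = 1, noise = FALSE)
  prom <- names(truth$promoters)[1]
  s <- coll[[which(vapply(coll, function(x)
    x$promoter == prom, logical(1)))[1]]]
  cur <- promoter_activity(s, window = 5)
  afun <- true_activity_fun(truth, prom, "C")
  core <- 5:(length(cur$activity) - 5)
  rel_rms <- sqrt(mean((cur$activity[core] - afun(cur$generations[core]))^2)) /
    sqrt(mean(afun(cur$generations[core])^2))
  expect_lt(rel_rms, 0.02)
})
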