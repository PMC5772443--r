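two_cell_features <- function() {
  g <- grid_spec(0, 0, 1, 2, 1)
  env <- structure(list(feat = raster_layer(g, c(0, 1))),
                   class = "env_stack")
  build_features(env, 1:2)
}

test_that("features are linear + quadratic, scaled on the background", {
  w <- std_world()
  bg <- sample_background(raster_layer(w$grid, 1), 500, seed = 1)
  f <- build_features(w$env, bg)
  expect_equal(length(f$names), 2 * length(w$env))
  sub <- f$values[bg, ]
  expect_equal(unname(apply(sub, 2, min)), rep(0, ncol(sub)))
  expect_equal(unname(apply(sub, 2, max)), rep(1, ncol(sub)))
  # quadratic features square the raw variable before scaling
  v <- w$env[[1]]$values
  sq_col <- paste0(names(w$env)[1], "_sq")
  sc <- f$scaling[f$scaling$feature == sq_col, ]
  expect_equal(f$values[, sq_col], (v^2 - sc$min) / (sc$max - sc$min))
  # a constant layer is dropped with a warning
  env2 <- w$env
  env2$flat <- raster_layer(w$grid, 0.5)
  expect_warning(f2 <- build_features(env2, bg), "constant")
  expect_equal(length(f2$names), 2 * length(w$env))
})

test_that("background sampling honours the bias file and the seed", {
  g <- grid_spec(0, 0, 1, 30, 30)
  set.seed(2)
  bias <- raster_layer(g, as.numeric(runif(900) < 0.3))
  pos <- which(bias$values == 1)
  s1 <- sample_background(bias, 100, seed = 5)
  s2 <- sample_background(bias, 100, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1 %in% pos))
  # fewer positive cells than requested: all are used
  expect_equal(sample_background(bias, 10000, seed = 5), pos)
  expect_error(sample_background(raster_layer(g, 0), 10), "no positive")
})

test_that("infinite regularisation gives the uniform maximum-entropy model", {
  f <- two_cell_features()
  m <- fit_maxent(c(rep(1L, 3), rep(2L, 4)), 1:2, f,
                  reg_multiplier = 1e9)
  expect_equal(unname(m$lambda), rep(0, length(m$lambda)))
  expect_equal(m$entropy, log(2))
  q <- exp(drop(f$values %*% m$lambda) - m$logZ)
  expect_equal(q, c(0.5, 0.5))
})

test_that("the two-state Gibbs fit reproduces the hand-solved weights", {
  # presence mean 0.8 on a binary feature: q = (0.2, 0.8), lambda sums
  # to log(4) across the (collinear) linear and quadratic features
  f <- two_cell_features()
  m <- suppressWarnings(
    fit_maxent(c(rep(2L, 8), rep(1L, 2)), 1:2, f, reg_multiplier = 0,
               tol = 1e-13, max_iter = 20000))
  q <- exp(drop(f$values %*% m$lambda) - m$logZ)
  expect_equal(q, c(0.2, 0.8), tolerance = 1e-6)
  expect_equal(sum(m$lambda), log(0.8 / 0.2), tolerance = 1e-5)
})

test_that("the unregularised fit matches the presence feature means", {
  w <- std_world()
  set.seed(6)
  bg <- sample_background(raster_layer(w$grid, 1), 300, seed = 6)
  f <- build_features(w$env, bg, names(w$env)[c(1, 4)])
  pres <- sample(bg, 40)
  m <- suppressWarnings(fit_maxent(pres, bg, f, reg_multiplier = 0,
                                   tol = 1e-12, max_iter = 20000))
  q <- exp(drop(f$values[bg, ] %*% m$lambda) - m$logZ)
  expect_equal(sum(q), 1, tolerance = 1e-12)
  e_q <- drop(crossprod(f$values[bg, ], q))
  expect_equal(unname(e_q), unname(colMeans(f$values[pres, ])),
               tolerance = 1e-4)
})

test_that("the penalised objective is non-decreasing and deterministic", {
  w <- std_world()
  set.seed(7)
  bg <- sample_background(raster_layer(w$grid, 1), 400, seed = 7)
  f <- build_features(w$env, bg)
  for (rep in 1:5) {
    pres <- sample(which(!is.na(f$values[, 1])), 25)
    m <- fit_maxent(pres, bg, f)
    expect_false(is.unsorted(m$objective))
    expect_true(m$converged)
  }
  pres <- sample(which(!is.na(f$values[, 1])), 25)
  m1 <- fit_maxent(pres, bg, f)
  m2 <- fit_maxent(pres, bg, f)
  expect_identical(m1$lambda, m2$lambda)
  expect_error(fit_maxent(pres[1:4], bg, f), "fewer than 5")
})

test_that("the logistic transform is calibrated and rank-preserving", {
  w <- std_world()
  bg <- sample_background(raster_layer(w$grid, 1), 400, seed = 8)
  f <- build_features(w$env, bg)
  set.seed(8)
  pres <- sample(bg, 30)
  m <- fit_maxent(pres, bg, f)
  l <- logistic_map(m, f)
  expect_true(all(l$values > 0 & l$values < 1, na.rm = TRUE))
  # a cell at the 'typical' density q = e^{-H} maps to 0.5
  eta <- drop(f$values %*% m$lambda)
  q_tilde <- exp(eta - m$logZ)
  i <- which.min(abs(log(q_tilde) + m$entropy))
  expect_equal(l$values[i],
               plogis(m$entropy + log(q_tilde[i])), tolerance = 1e-12)
  # ordering of the logistic output matches the ordering of lambda.f
  expect_equal(order(l$values), order(eta))
  # lambda = 0 gives a flat map
  m0 <- fit_maxent(pres, bg, f, reg_multiplier = 1e9)
  l0 <- logistic_map(m0, f)
  expect_equal(diff(range(l0$values)), 0)
})

test_that("training AUC is the pairwise win probability with half ties", {
  expect_equal(training_auc(c(0.8, 0.9), c(0.1, 0.2)), 1)
  expect_equal(training_auc(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  expect_equal(training_auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  set.seed(9)
  for (rep in 1:20) {
    pres <- sample(seq(0, 1, 0.1), sample(2:10, 1), replace = TRUE)
    bg <- sample(seq(0, 1, 0.1), sample(2:30, 1), replace = TRUE)
    expect_equal(training_auc(pres, bg), auc_oracle(pres, bg),
                 tolerance = 1e-12)
  }
  # invariant under strictly monotone transforms
  pres <- runif(20); bg <- runif(50)
  expect_equal(training_auc(qlogis(pres), qlogis(bg)),
               training_auc(pres, bg))
})

test_that("the 10% training-presence threshold drops the lowest decile", {
  v <- seq(0.1, 1, 0.1)
  t <- threshold_10pct(v)
  expect_equal(t, 0.2)
  expect_equal(mean(v >= t), 0.9)
  expect_equal(threshold_10pct(rep(0.4, 7)), 0.4)
  expect_equal(threshold_10pct(0.33), 0.33)
  # at least 90% of presences always sit at or above the threshold
  set.seed(10)
  for (rep in 1:20) {
    v <- runif(sample(1:50, 1))
    expect_gte(mean(v >= threshold_10pct(v)), 0.9)
  }
})
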