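test_that("fit_contrast matches hand-computed OLS", {
  X <- cbind(intercept = rep(1, 4), x = c(0, 1, 0, 1))
  expect_equal(fit_contrast(X, c(0, 1, 0, 1), c(0, 1)), 1.0)
  expect_equal(fit_contrast(X, c(1, 1, 1, 1), c(0, 1)), 0.0)
  X2 <- cbind(intercept = rep(1, 4), x = 0:3)
  expect_equal(fit_contrast(X2, c(0, 1, 1, 2), c(0, 1)), 0.6)  # S_xy/S_xx = 3/5
  # rank deficiency names the offending column
  X3 <- cbind(intercept = rep(1, 5), dup = rep(1, 5), x = 1:5)
  expect_error(fit_contrast(X3, rnorm(5), c(0, 0, 1)), "dup")
})

test_that("contrast estimate is invariant to nuisance reparameterisation", {
  set.seed(11)
  X <- cbind(1, rnorm(20), rnorm(20))
  y <- rnorm(20)
  w <- c(0, 1, 0)
  # replace the nuisance column by an invertible recombination that leaves
  # the contrasted column fixed
  X2 <- X %*% rbind(c(1, 0, 0.5), c(0, 1, 0), c(0, 0, 2))
  expect_equal(fit_contrast(X, y, w), fit_contrast(X2, y, w), tolerance = 1e-10)
})

test_that("incremental updates reproduce the batch fit", {
  set.seed(21)
  for (rep in 1:40) {
    p <- sample(2:8, 1)
    t <- sample((p + 2):40, 1)
    X <- cbind(1, matrix(rnorm(t * (p - 1)), t))
    y <- rnorm(t)
    st <- glm_stream_init(p, 1L, t)
    for (i in seq_len(t)) glm_update(st, X[i, ], y[i])
    fit <- glm_fit(st)
    expect_true(fit$ok)
    w <- rnorm(p)
    expect_lt(abs(drop(crossprod(w, fit$beta)) - brute_ols_contrast(X, y, w)),
              1e-8)
    expect_lt(max(abs(fit$residuals - (y - X %*% qr.solve(X, y)))), 1e-8)
  }
})

test_that("estimates are undefined before t >= p and on singular designs", {
  st <- glm_stream_init(3, 2, 10)
  glm_update(st, c(1, 0, 0), c(1, 2))
  expect_false(glm_fit(st)$ok)
  # saturated-at-rank case: duplicate column keeps xtx singular at any t
  st2 <- glm_stream_init(2, 1, 10)
  for (i in 1:6) glm_update(st2, c(1, 1), rnorm(1))
  expect_false(glm_fit(st2)$ok)
})

test_that("non-finite signals flag the voxel degenerate without halting", {
  st <- glm_stream_init(2, 3, 5)
  expect_silent(glm_update(st, c(1, 0.5), c(1, NaN, 2)))
  expect_identical(st$degenerate, c(FALSE, TRUE, FALSE))
  glm_update(st, c(1, 1), c(1, 1, Inf))
  expect_identical(st$degenerate, c(FALSE, TRUE, TRUE))
})

test_that("sandwich variance matches hand and reference computations", {
  # all-zero residuals -> zero variance
  X <- cbind(rep(1, 4))
  expect_equal(sandwich_variance(X, rep(0, 4), 1), 0)
  # intercept-only, residuals (1,-1,1,-1): (1/4) * 4 * (1/4)
  expect_equal(sandwich_variance(X, c(1, -1, 1, -1), 1), 0.25)
  expect_error(sandwich_variance(X, c(1, -1, 1, -1), 1, lag = 4), "lag")
  # cross-check against the reference implementation (HC0 and Newey-West)
  set.seed(31)
  n <- 80
  Xr <- cbind(1, rnorm(n), runif(n))
  y <- Xr %*% c(1, 2, -1) + rnorm(n) * (1 + abs(Xr[, 2]))
  fit <- lm(y ~ Xr - 1)
  w <- c(0, 1, 0)
  expect_equal(sandwich_variance(Xr, resid(fit), w),
               drop(t(w) %*% sandwich::vcovHC(fit, type = "HC0") %*% w),
               tolerance = 1e-10)
  expect_equal(sandwich_variance(Xr, resid(fit), w, lag = 4),
               drop(t(w) %*% sandwich::NeweyWest(fit, lag = 4, prewhite = FALSE,
                                                 adjust = FALSE) %*% w),
               tolerance = 1e-10)
})

test_that("lag-0 sandwich is calibrated against the classical variance", {
  set.seed(41)
  n <- 200; reps <- 500
  X <- cbind(1, scale(1:n), rnorm(n))
  w <- c(0, 1, 0)
  classical <- contrast_design_variance(X, w)        # sigma = 1
  Y <- matrix(rnorm(n * reps), n, reps)
  res <- Y - X %*% qr.solve(X, Y)
  v <- sandwich_variance(X, res, w)
  expect_lt(abs(mean(v) - classical) / classical, 0.1)
})

test_that("sandwich variance ignores signal shifts when an intercept is present", {
  set.seed(51)
  n <- 60
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  r1 <- y - X %*% qr.solve(X, y)
  y2 <- y + 7
  r2 <- y2 - X %*% qr.solve(X, y2)
  expect_equal(sandwich_variance(X, r1, c(0, 1)),
               sandwich_variance(X, r2, c(0, 1)), tolerance = 1e-10)
})

test_that("z-scores behave and flag degenerate variances", {
  expect_equal(zscore(3.1, 1.0), 3.1)
  expect_equal(zscore(0, 5), 0)
  expect_equal(zscore(1.2, 0.04), 6.0)
  expect_true(is.na(zscore(1, 0)))
  expect_true(is.na(zscore(1, -2)))
  expect_equal(zscore(c(1, 2), c(1, 4)), c(1, 1))
})

test_that("null z-scores are standard normal at full duration", {
  # iid noise through the full design + HC0 sandwich; Kolmogorov distance
  set.seed(61)
  p <- make_paper_protocol()
  X <- build_design_matrix(p, design_spec())$X
  n_vox <- 10000
  Y <- matrix(rnorm(238 * n_vox), 238, n_vox)
  beta <- qr.solve(X, Y)
  res <- Y - X %*% beta
  w <- as.numeric(colnames(X) == "easy")
  z <- zscore(drop(crossprod(w, beta)), sandwich_variance(X, res, w))
  d <- suppressWarnings(stats::ks.test(z, "pnorm"))$statistic
  expect_lt(unname(d), 0.03)
})
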