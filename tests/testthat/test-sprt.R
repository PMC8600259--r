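test_that("stopping boundaries follow the Wald formulas", {
  b <- stopping_boundaries(0.001, 0.1)
  expect_equal(unname(b["A"]), 6.8024, tolerance = 1e-4)
  expect_equal(unname(b["B"]), -2.3016, tolerance = 1e-4)
  b2 <- stopping_boundaries(0.1, 0.1)
  expect_equal(unname(b2["A"]), -unname(b2["B"]))
  expect_equal(unname(b2["A"]), 2.1972, tolerance = 1e-4)
  b3 <- stopping_boundaries(0.0001, 0.1)
  expect_equal(unname(b3["A"]), 9.1050, tolerance = 1e-4)
  expect_equal(unname(b3["B"]), -2.3025, tolerance = 1e-4)
  expect_error(stopping_boundaries(0.5, 0.5), "< 1")
})

test_that("the alternative is calibrated from first-stage variance", {
  expect_equal(set_alternative(1.0, 3.10), 3.10)
  expect_equal(set_alternative(0.25, 3.10), 1.55)
  expect_equal(set_alternative(4.0, 2.0), 4.0)
  expect_true(is.na(set_alternative(0, 3.1)))
  expect_true(is.na(set_alternative(-1, 3.1)))
  expect_equal(set_alternative(c(1, 4), 2), c(2, 4))
})

test_that("Wald statistic has the closed form and its symmetries", {
  # estimate at the hypothesis midpoint: the two densities tie
  expect_equal(wald_statistic(0.5, 2, 0, 1), 0)
  expect_equal(wald_statistic(1, 1, 0, 1), 0.5)
  expect_equal(wald_statistic(0, 2, 0, 2), -1.0)
  # strictly increasing in the estimate (one-sided, theta1 > theta0)
  cb <- seq(-3, 3, by = 0.1)
  lam <- wald_statistic(cb, 0.7, 0, 1.3)
  expect_true(all(diff(lam) > 0))
  expect_true(is.na(wald_statistic(1, 0, 0, 1)))
  expect_true(is.na(wald_statistic(1, -1, 0, 1)))
})

test_that("two-sided mode is invariant to a sign flip of the data", {
  cb <- c(-2.5, -0.3, 0, 0.4, 3.1)
  lam <- wald_statistic(cb, 1.3, 0, 2, sided = "two")
  lam_flip <- wald_statistic(-cb, 1.3, 0, 2, sided = "two")
  expect_equal(lam, lam_flip, tolerance = 1e-12)
})

test_that("classification applies the three decision rules and absorbs", {
  cfg <- sprt_config(first_stage_scans = 10, max_scans = 30)
  st <- sprt_state_init(4)
  st <- sprt_start_testing(st, c(1, 1, 1, -1), cfg)  # voxel 4 degenerate
  expect_identical(st$status, c(rep("undecided", 3), "degenerate"))
  expect_equal(st$theta1[1:3], rep(3.1, 3))
  st <- sprt_classify(st, c(7.0, -2.5, 0, NA), scan = 11, cfg)
  expect_identical(st$status, c("active", "nonactive", "undecided", "degenerate"))
  expect_identical(st$decision_scan, c(11L, 11L, NA_integer_, NA_integer_))
  # decided voxels are never revisited, whatever the new statistic says
  st2 <- sprt_classify(st, c(-99, 99, 0.5, 0), scan = 12, cfg)
  expect_identical(st2$status[1:2], c("active", "nonactive"))
  expect_identical(st2$decision_scan[1:2], c(11L, 11L))
  # no classification during the first stage
  expect_error(sprt_classify(st, rep(0, 4), scan = 10, cfg), "first stage")
})

test_that("truncation keeps or force-labels undecided voxels as configured", {
  cfg <- sprt_config(first_stage_scans = 10, max_scans = 12)
  st <- sprt_start_testing(sprt_state_init(2), c(1, 1), cfg)
  st_keep <- sprt_classify(st, c(0.5, -0.5), scan = 12, cfg)
  expect_identical(st_keep$status, c("undecided", "undecided"))
  st_force <- sprt_classify(st, c(0.5, -0.5), scan = 12, cfg,
                            truncation_label = TRUE)
  expect_identical(st_force$status, c("active", "nonactive"))
})

test_that("raising the estimate never demotes a classification", {
  cfg <- sprt_config(first_stage_scans = 5, max_scans = 50)
  b <- stopping_boundaries(cfg$alpha_e, cfg$beta_e)
  v <- 0.8; th <- 2
  cb <- seq(-4, 6, by = 0.05)
  lam <- wald_statistic(cb, v, 0, th)
  cls <- ifelse(lam >= b["A"], 2L, ifelse(lam <= b["B"], 0L, 1L))
  expect_true(all(diff(cls) >= 0))  # nonactive -> undecided -> active only
})

test_that("Bonferroni mode widens the upper boundary only through alpha", {
  cfg <- sprt_config(bonferroni = TRUE, n_comparisons = 1000,
                     first_stage_scans = 10, max_scans = 20)
  b <- rtsprt:::sprt_boundaries(cfg)
  b0 <- stopping_boundaries(0.001 / 1000, 0.1)
  expect_equal(b, b0)
})

test_that("z-rescaling through truncated designs behaves", {
  p <- make_paper_protocol()
  X <- build_design_matrix(p, design_spec())
  cc <- contrast(X, "easy")
  expect_equal(rescale_z_equivalent(X, 154, 154, cc, 3.1), 3.1)
  # the equivalent z grows with the later scan count (variance shrinks)
  zs <- vapply(c(160, 180, 210, 238), function(tl)
    rescale_z_equivalent(X, 154, tl, cc, 3.1), numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_true(all(zs >= 3.1))
  expect_error(rescale_z_equivalent(X, 4, 238, cc, 3.1), "t_early")
})

test_that("config invariants are enforced", {
  expect_error(sprt_config(alpha_e = 0.6, beta_e = 0.5), "< 1")
  expect_error(sprt_config(alpha_e = 0), "in \\(0, 1\\)")
  expect_error(sprt_config(first_stage_scans = 238, max_scans = 238),
               "first_stage_scans")
  cfg <- sprt_config()
  b <- stopping_boundaries(cfg$alpha_e, cfg$beta_e)
  expect_true(b["A"] > 0 && b["B"] < 0)
})
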