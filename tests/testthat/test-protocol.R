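test_that("double-gamma kernel has the canonical shape", {
  dt <- 0.1
  k <- double_gamma_hrf(dt, 32)
  expect_equal(k[1], 0)                       # zero response at t = 0
  expect_equal(max(k), 1)                     # peak-normalised
  peak_t <- (which.max(k) - 1) * dt
  expect_lt(abs(peak_t - 5), 0.2)             # mode of the first gamma
  expect_lt(min(k), 0)                        # undershoot present
  # single positive peak: derivative changes sign once before the undershoot
  pre <- k[seq_len(which.max(k))]
  expect_true(all(diff(pre) >= 0))
  # no undershoot term -> kernel everywhere non-negative
  k0 <- double_gamma_hrf(dt, 32, hrf_params(ratio = 0))
  expect_true(all(k0 >= 0))
  expect_error(double_gamma_hrf(0, 32), "dt")
  expect_error(double_gamma_hrf(0.1, -1), "length")
})

test_that("packaged protocol reproduces the block-completion table", {
  p <- make_paper_protocol()
  comp <- block_completion_scans(p)
  expect_identical(comp$easy, c(21L, 59L, 97L, 135L, 173L, 211L))
  expect_identical(comp$hard, c(40L, 78L, 116L, 154L, 192L, 230L))
  # single 36 s block at t = 0, TR 3 s, no rest convention
  p1 <- stimulus_protocol(tr = 3, max_scans = 20,
                          conditions = list(a = list(onsets = 0, duration = 36)))
  expect_identical(block_completion_scans(p1)$a, 12L)
})

test_that("protocol invariants are enforced", {
  expect_error(stimulus_protocol(3, list(a = list(onsets = c(0, 40),
                                                  duration = 50)),
                                 max_scans = 50), "overlap")
  expect_error(stimulus_protocol(3, list(a = list(onsets = c(10, 5),
                                                  duration = 2)),
                                 max_scans = 50), "increasing")
  expect_error(stimulus_protocol(3, list(a = list(onsets = 140, duration = 36)),
                                 max_scans = 50), "after max_scans")
  expect_error(stimulus_protocol(-3, list(a = list(onsets = 0, duration = 3)),
                                 max_scans = 10), "tr")
})

test_that("design matrix has the expected structure", {
  p <- make_paper_protocol()
  X <- build_design_matrix(p, design_spec())
  expect_equal(X$p, 8)                        # intercept + easy + hard + 5 drifts
  expect_identical(X$column_labels,
                   c("intercept", "easy", "hard", paste0("drift_", 1:5)))
  expect_true(all(is.finite(X$X)))
  expect_true(all(abs(X$X[, paste0("drift_", 1:5)]) <= 1))
  expect_true(max(X$X[, "easy"]) <= 1 + 1e-12)  # unit-peak condition regressors
  expect_error(build_design_matrix(p, design_spec(), t = 0), "1..max_scans")
  expect_error(build_design_matrix(p, design_spec(), t = 500), "1..max_scans")
  # no blocks -> condition column identically zero
  p0 <- stimulus_protocol(3, list(a = list(onsets = numeric(0), duration = 5)),
                          max_scans = 10)
  X0 <- build_design_matrix(p0, design_spec(n_drift = 0), 10)
  expect_identical(unname(X0$X[, "a"]), rep(0, 10))
})

test_that("streaming build is a prefix of the full build", {
  p <- make_paper_protocol()
  full <- build_design_matrix(p, design_spec())$X
  expect_equal(build_design_matrix(p, design_spec(), 78)$X, full[1:78, ])
  for (i in 1:50) {
    prot <- random_protocol(n_cond = sample(1:3, 1))
    spec <- design_spec(n_drift = sample(0:5, 1))
    fullX <- build_design_matrix(prot, spec)$X
    t <- sample(seq_len(prot$max_scans), 1)
    expect_equal(build_design_matrix(prot, spec, t)$X,
                 fullX[seq_len(t), , drop = FALSE])
  }
})

test_that("cosine drift basis matches the stated period rule", {
  expect_equal(drift_periods(714, 5), c(1428, 714, 476, 357, 285.6))
  D <- cosine_drift_regressors(714, 3, 238, 5)
  expect_true(all(abs(D) <= 1))
  # column j completes j half-periods over the run: exact zero sum over 2T
  D2 <- cosine_drift_regressors(714, 3, 476, 5)
  expect_true(all(abs(colSums(D2)) < 1e-8))
  # zero-phase convention starts every column at cos(0) = 1
  Dz <- cosine_drift_regressors(714, 3, 10, 5, phase = "zero")
  expect_equal(unname(Dz[1, ]), rep(1, 5))
  expect_error(cosine_drift_regressors(714, 3, 10, 6), "extend")
  expect_silent(cosine_drift_regressors(714, 3, 10, 6, extend = TRUE))
})

test_that("protocols round-trip through YAML and JSON", {
  p <- make_paper_protocol()
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_protocol(p, f)
    q <- read_protocol(f)
    expect_equal(q$conditions, p$conditions)
    expect_equal(q$tr, p$tr)
    expect_equal(q$max_scans, p$max_scans)
    expect_equal(q$rest, p$rest)
  }
  # the packaged fixture is the same protocol
  fx <- system.file("extdata", "paper_protocol.yaml", package = "rtsprt")
  expect_true(nzchar(fx))
  expect_equal(read_protocol(fx)$conditions, p$conditions)
})
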