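test_that("uncoupled unstimulated cells stay at rest", {
  cfg <- chain_config(n_fibroblasts = 2, pacing_rate_hz = 0.5,
                      G_mm = 0, G_mf = 0, G_ff = 0,
                      stim_amp_nA = 0, n_precondition = 0, n_analysis = 5,
                      dt_ms = 0.01)
  r <- run_chain(cfg, record_traces = TRUE)
  v <- r$traces$V_mV
  myo_rows <- c(1:10, nrow(v))
  expect_lt(max(abs(v[myo_rows, ] - (-84))), 0.5)
  fib_rows <- setdiff(seq_len(nrow(v)), myo_rows)
  expect_lt(max(abs(v[fib_rows, ] - (-24.5))), 0.5)
})

test_that("a homogeneous strand conducts 1:1 at slow pacing", {
  r <- run_chain(chain_quick(0, 1), record_traces = FALSE)
  expect_true(all(r$captured))
  expect_false(r$conduction_failed)
  expect_gt(r$mean_cv_m_s, 0.2)
})

test_that("an uncoupled fibroblast insert blocks conduction every cycle", {
  r <- run_chain(chain_quick(1, 1, G_mf = 0), record_traces = FALSE)
  expect_true(all(!r$captured))
  expect_true(r$conduction_failed)
})

test_that("the upstroke-velocity estimator is exact on an analytic trace", {
  dt <- 0.001
  t <- seq(-40, 40, by = dt)
  A <- 50; tau <- 3
  v <- A * tanh(t / tau)
  expect_equal(dvdt_max(v, dt), A / tau, tolerance = 1e-4)
})

test_that("capture is monotone in rate for the five-fibroblast chain", {
  rates <- c(6.5, 9.5, 10.5, 11.5, 12.5)
  failed <- vapply(rates, function(r)
    run_chain(chain_quick(5, r), record_traces = FALSE)$conduction_failed,
    TRUE)
  # once conduction fails it stays failed at faster pacing
  if (any(failed)) {
    first <- which(failed)[1]
    expect_true(all(failed[first:length(failed)]))
  }
  # and at the protocol's working rates it still conducts
  expect_false(failed[1])
})

test_that("max insertable fibroblast count does not increase with rate", {
  mi <- max_insertable(c(2.5, 10.5), config = chain_quick(0, 1))
  expect_true(mi$max_n[2] <= mi$max_n[1])
  expect_gte(mi$max_n[1], 0)
})

test_that("normalized CV restitution starts at one and decreases", {
  cv <- cv_restitution(c(0.5, 4.5, 8.5), n = 4, config = chain_quick(0, 1))
  expect_equal(cv$cv_norm[cv$rate_hz == 0.5], 1)
  ok <- cv[!cv$failed, ]
  expect_true(all(diff(ok$cv_norm) <= 1e-9))
})

test_that("upstroke velocity of the reporter declines with rate", {
  dv <- dvdt_max_curve(c(0.5, 8.5), n = 5, config = chain_quick(0, 1))
  expect_true(all(is.finite(dv$dvdt_max_mV_ms)))
  expect_lte(dv$dvdt_max_mV_ms[2], dv$dvdt_max_mV_ms[1] + 1e-6)
})

test_that("the limit-cycle criterion is met after preconditioning", {
  cfg <- chain_config(n_fibroblasts = 0, pacing_rate_hz = 2,
                      n_precondition = 30, n_analysis = 3, dt_ms = 0.01)
  r <- run_chain(cfg, record_traces = TRUE)
  expect_gte(r$limit_cycle_cor, 0.99)
  expect_length(r$warnings, 0)
})

test_that("halving the time step changes CV by under one percent", {
  cv <- vapply(c(0.01, 0.005), function(dt) {
    cfg <- chain_config(n_fibroblasts = 4, pacing_rate_hz = 4.5,
                        n_precondition = 8, dt_ms = dt)
    run_chain(cfg, record_traces = FALSE)$mean_cv_m_s
  }, 0)
  expect_lt(abs(cv[2] - cv[1]) / cv[1], 0.01)
})

test_that("model invariants: fibroblasts rest depolarized relative to myocytes", {
  expect_gt(fibroblast_params()[["E"]], myocyte_params("mouse")[["V_rest"]])
  expect_length(run_chain(chain_quick(0, 1),
                          record_traces = FALSE)$captured, 20)
  expect_error(chain_config(n_fibroblasts = 12), "0..9")
})
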