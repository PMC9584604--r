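test_that("an absorbing start state yields a single event spanning the window", {
  sch <- kinetic_scheme(c("mid", "high"), c(0.45, 0.7),
                        matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  p <- simulate_state_path(sch, t_max = 7, start_state = "high", seed = 1)
  expect_equal(nrow(p$events), 1L)
  expect_equal(p$events$label, "high")
  expect_equal(p$events$start, 0)
  expect_equal(p$events$end, 7)
})

test_that("simulated dwells are exponential with the state's total exit rate", {
  sch <- symmetric_scheme(rate = 2)          # total exit rate 2 s^-1
  p <- simulate_state_path(sch, t_max = 6000, start_state = 1, seed = 11)
  ev <- p$events
  d <- (ev$end - ev$start)[-nrow(ev)]        # drop the window-censored dwell
  expect_gt(length(d), 1e4)
  # analytic mean 1/k = 0.5 s within 3 standard errors
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 0.5), 3 * se)
  # full-distribution Kolmogorov-Smirnov check
  ks <- suppressWarnings(stats::ks.test(d, "pexp", 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("a symmetric two-state chain splits occupancy evenly", {
  sch <- symmetric_scheme(rate = 1)
  p <- simulate_state_path(sch, t_max = 5000, start_state = 1, seed = 3)
  ev <- p$events
  occ <- tapply(ev$end - ev$start, ev$label, sum)
  frac <- occ / sum(occ)
  expect_lt(abs(frac[["mid"]] - 0.5), 0.02)
})

test_that("identical seeds give bit-identical paths and traces", {
  sch <- build_scheme("control")
  model <- photophysics_model(donor_bleach_rate = 0.05)
  p1 <- simulate_state_path(sch, 10, "low", seed = 99)
  p2 <- simulate_state_path(sch, 10, "low", seed = 99)
  expect_identical(p1$events, p2$events)
  t1 <- render_trace(p1, model, seed = 7)
  t2 <- render_trace(p2, model, seed = 7)
  expect_identical(t1$fret, t2$fret)
  expect_identical(t1$donor, t2$donor)
  s1 <- simulate_traces(sch, 5, 5, model, seed = 123)
  s2 <- simulate_traces(sch, 5, 5, model, seed = 123)
  expect_identical(lapply(s1, `[[`, "fret"), lapply(s2, `[[`, "fret"))
})

test_that("noiseless frames equal the occupancy-weighted state FRET mean", {
  sch <- build_scheme("control")
  model <- photophysics_model(fret_noise_sigma = 0)
  p <- simulate_state_path(sch, 5, "low", seed = 17)
  tr <- render_trace(p, model)
  # independent frame integration: brute-force overlap of events and frames
  dt <- model$frame_period
  mu <- p$fret_means[p$events$state]
  manual <- vapply(seq_along(tr$fret), function(f) {
    lo <- (f - 1) * dt; hi <- f * dt
    ov <- pmax(0, pmin(p$events$end, hi) - pmax(p$events$start, lo))
    sum(ov * mu) / dt
  }, numeric(1))
  expect_lt(max(abs(tr$fret - manual)), 1e-12)
  # degenerate case: constant mid-state path renders exactly 0.45
  pc <- simulate_state_path(symmetric_scheme(1e-12), 3, "mid", seed = 1)
  trc <- render_trace(pc, model)
  expect_true(all(abs(trc$fret - 0.45) < 1e-12))
})

test_that("donor photobleaching truncates traces with the exponential mean", {
  sch <- symmetric_scheme(1e-12)
  model <- photophysics_model(donor_bleach_rate = 0.2,
                              acceptor_bleach_rate = 0,
                              fret_noise_sigma = 0, frame_period = 0.1)
  seeds <- derive_seeds(5, 1500)
  durs <- vapply(seeds, function(s) {
    p <- simulate_state_path(sch, 100, "mid", seed = s)
    length(render_trace(p, model)$fret) * model$frame_period
  }, numeric(1))
  se <- stats::sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - 5), 3 * se + model$frame_period)
})

test_that("rendered FRET noise has the configured standard deviation", {
  sch <- symmetric_scheme(1e-12)
  model <- photophysics_model(fret_noise_sigma = 0.06)
  p <- simulate_state_path(sch, 200, "mid", seed = 2)
  tr <- render_trace(p, model, seed = 21)
  n <- length(tr$fret)
  expect_gt(n, 1e4)
  se_of_sd <- 0.06 / sqrt(2 * n)
  expect_lt(abs(stats::sd(tr$fret) - 0.06), 3 * se_of_sd)
  # intensities back out the same FRET values exactly
  expect_equal(tr$fret, tr$acceptor / (tr$acceptor + tr$donor))
})

test_that("rendering an empty path is an error", {
  p <- simulate_state_path(symmetric_scheme(1), 1, 1, seed = 1)
  p$events <- p$events[0, ]
  expect_error(render_trace(p, photophysics_model()), "empty")
})

test_that("dose series follows Hill occupancy", {
  free <- symmetric_scheme(1)
  bound <- kinetic_scheme(c("mid", "high"), c(0.45, 0.7),
                          matrix(c(0, 0.01, 0.01, 0), 2, 2, byrow = TRUE))
  model <- photophysics_model()
  # zero dose: every trace from the free scheme
  d0 <- simulate_dose_series(free, bound, ic50 = 4.5, hill = 1,
                             concentrations = 0, n_traces = 50, model,
                             t_max = 0.5, seed = 5)
  expect_true(all(!vapply(d0[[1]], function(tr) tr$meta$bound, TRUE)))
  # at c = IC50 the bound fraction is 1/2 within binomial 3 SE
  dm <- simulate_dose_series(free, bound, ic50 = 4.5, hill = 1,
                             concentrations = 4.5, n_traces = 2000, model,
                             t_max = 0.06, seed = 6)
  bf <- mean(vapply(dm[[1]], function(tr) tr$meta$bound, TRUE))
  expect_lt(abs(bf - 0.5), 3 * sqrt(0.25 / 2000))
  # saturation: c = 1e4 x IC50 at h = 1 gives occupancy 0.9999
  ds <- simulate_dose_series(free, bound, ic50 = 4.5, hill = 1,
                             concentrations = 4.5e4, n_traces = 500, model,
                             t_max = 0.06, seed = 7)
  expect_gte(mean(vapply(ds[[1]], function(tr) tr$meta$bound, TRUE)), 0.99)
  expect_error(simulate_dose_series(free, bound, 4.5, 1, c(-1, 10), 10,
                                    model, 1, seed = 1), ">= 0")
})

test_that("slow conversion fractions follow the exponential CDF", {
  # k = 6e-4 s^-1 over 1000 s: expected converted fraction 1 - exp(-0.6)
  ts <- simulate_slow_process(6e-4, n_traces = 1000, t_max = 1000, seed = 31)
  conv <- vapply(ts, function(tr) {
    any(tr$meta$truth$events$label == "high")
  }, TRUE)
  expected <- 1 - exp(-0.6)
  expect_lt(abs(mean(conv) - expected),
            3 * sqrt(expected * (1 - expected) / 1000))
  # near-zero rate: essentially no conversions
  ts0 <- simulate_slow_process(1e-12, n_traces = 50, t_max = 3600, seed = 32)
  conv0 <- vapply(ts0, function(tr) {
    any(tr$meta$truth$events$label == "high")
  }, TRUE)
  expect_equal(sum(conv0), 0)
  expect_error(simulate_slow_process(1e-3, 10, t_max = -1, seed = 1),
               "t_max")
})
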