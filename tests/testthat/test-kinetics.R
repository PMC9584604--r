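test_that("truncation stops at the first high-FRET dwell of 150 ms or more", {
  # a 3-frame (45 ms) high excursion is retained; the 20-frame (300 ms)
  # dwell triggers truncation at its entry
  labels <- c(rep("mid", 10), rep("high", 3), rep("mid", 5),
              rep("high", 20), rep("mid", 4))
  ideal <- make_ideal(labels)
  out <- truncate_before_first_long_high(ideal)
  expect_true(out$truncated)
  expect_equal(length(out$state_seq), 18L)
  d <- extract_dwells(out)
  expect_equal(d$state, c("mid", "high", "mid"))
  expect_equal(d$next_state[3], "high")     # observed exit into the long dwell
  expect_false(d$censored[3])
  # a dwell of exactly 10 frames (150 ms) triggers truncation (inclusive)
  ideal10 <- make_ideal(c(rep("mid", 5), rep("high", 10), rep("mid", 5)))
  expect_true(truncate_before_first_long_high(ideal10)$truncated)
  # 9 frames does not
  ideal9 <- make_ideal(c(rep("mid", 5), rep("high", 9), rep("mid", 5)))
  out9 <- truncate_before_first_long_high(ideal9)
  expect_false(out9$truncated)
  expect_identical(out9$state_seq, ideal9$state_seq)
  # no high-FRET visit at all: unchanged
  flat <- make_ideal(rep(c("low", "mid"), 10))
  expect_identical(truncate_before_first_long_high(flat), flat)
})

test_that("dwell-table truncation mirrors trace truncation", {
  labels <- c(rep("mid", 10), rep("high", 3), rep("mid", 5),
              rep("high", 20), rep("mid", 4))
  ideal <- make_ideal(labels)
  via_trace <- extract_dwells(truncate_before_first_long_high(ideal))
  via_table <- truncate_dwells(extract_dwells(ideal))
  expect_equal(via_trace$state, via_table$state)
  expect_equal(via_trace$duration_s, via_table$duration_s)
  expect_equal(via_trace$next_state, via_table$next_state)
})

test_that("rate estimator divides transition counts by occupancy", {
  d <- data.frame(
    trace_id = c(1, 1, 1, 1, 2, 2),
    state = c("mid", "high", "mid", "high", "mid", "low"),
    start_s = c(0, 1.5, 1.6, 4.1, 0, 2.5),
    duration_s = c(1.5, 0.1, 2.5, 0.5, 2.5, 1.0),
    next_state = c("high", "mid", "high", NA, "low", NA),
    censored = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  est <- estimate_rate_matrix(d)
  # 2 mid->high transitions over 1.5 + 2.5 + 2.5 = 6.5 s of mid occupancy
  expect_equal(est$counts["mid", "high"], 2)
  expect_equal(unname(est$occupancy["mid"]), 6.5)
  expect_equal(est$k["mid", "high"], 2 / 6.5)
  expect_equal(est$k["mid", "low"], 1 / 6.5)
  # exact identities: k * T = N and k_i = sum_j k_ij
  expect_equal(est$k * est$occupancy, est$counts + 0)
  expect_equal(est$k_total, rowSums(est$k))
  # censored dwell contributes occupancy but no exit
  expect_equal(sum(est$counts["high", ]), 1)
  expect_equal(unname(est$occupancy["high"]), 0.6)
})

test_that("states with zero occupancy get missing rates, not zeros", {
  d <- data.frame(trace_id = 1, state = c("mid", "low"),
                  start_s = c(0, 1), duration_s = c(1, 1),
                  next_state = c("low", NA), censored = c(FALSE, TRUE),
                  stringsAsFactors = FALSE)
  est <- estimate_rate_matrix(d)
  expect_true(all(is.na(est$k["high", c("low", "mid")])))
  # all exits from mid go to low: k_mid->high = 0, k_mid = k_mid->low
  expect_equal(est$k["mid", "high"], 0)
  expect_equal(unname(est$k_total["mid"]), est$k["mid", "low"])
})

test_that("rate estimates and bootstrap are deterministic under a fixed seed", {
  sch <- build_scheme("control")
  ts <- simulate_traces(sch, 40, 6, photophysics_model(), seed = 4,
                        start_state = "low")
  dw <- truth_dwell_table(ts)
  e1 <- estimate_rate_matrix(dw, n_boot = 100, seed = 10)
  e2 <- estimate_rate_matrix(dw, n_boot = 100, seed = 10)
  expect_identical(e1$se, e2$se)
  expect_identical(e1$k, e2$k)
})

test_that("truth-path oracle recovers the generating rates of every preset", {
  model <- photophysics_model()
  for (cond in c("control", "didemnin", "ternatin4")) {
    sch <- build_scheme(cond)
    ts <- simulate_traces(sch, 300, 10, model, seed = 500 + match(
      cond, c("control", "didemnin", "ternatin4")), start_state = "low")
    dw <- truth_dwell_table(ts)
    est <- estimate_rate_matrix(dw, n_boot = 300, seed = 1)
    for (i in sch$states) for (j in sch$states) {
      if (i == j) next
      se <- max(est$se[i, j], 1e-3)   # floor for nearly-zero rates
      expect_lt(abs(est$k[i, j] - sch$rates[i, j]), 3 * se + 1e-3)
    }
    # after truncation the mid-state rates remain unbiased (stopping time)
    dwt <- truncate_dwells(dw)
    estt <- estimate_rate_matrix(dwt, n_boot = 300, seed = 2)
    for (j in c("low", "high")) {
      expect_lt(abs(estt$k["mid", j] - sch$rates["mid", j]),
                3 * max(estt$se["mid", j], 1e-3))
    }
  }
})

test_that("adding drug-stalled traces lowers the pooled mid-to-high rate", {
  model <- photophysics_model()
  ctrl <- simulate_traces(build_scheme("control"), 150, 10, model,
                          seed = 61, start_state = "low")
  drug <- simulate_traces(build_scheme("didemnin"), 150, 10, model,
                          seed = 62, start_state = "low")
  dw_c <- truth_dwell_table(ctrl)
  dw_d <- truth_dwell_table(drug)
  dw_d$trace_id <- dw_d$trace_id + 1000
  k_ctrl <- estimate_rate_matrix(dw_c)$k["mid", "high"]
  k_pool <- estimate_rate_matrix(rbind(dw_c, dw_d))$k["mid", "high"]
  expect_lt(k_pool, k_ctrl)
})

test_that("state lifetimes are inverse decay rates", {
  est <- structure(list(k_total = c(low = 1.90, mid = 1.73, high = 15.45)),
                   class = "rate_matrix_estimate")
  lt <- state_lifetimes(est)
  expect_equal(unname(lt["mid"]), 1 / 1.73)
  est2 <- structure(list(k_total = c(a = 2, b = 0)),
                    class = "rate_matrix_estimate")
  lt2 <- state_lifetimes(est2)
  expect_equal(unname(lt2["a"]), 0.5)
  expect_identical(unname(lt2["b"]), Inf)
})

test_that("transition ratio k_mid_high / k_mid_low matches published arithmetic", {
  mk <- function(cond) {
    sch <- build_scheme(cond)
    structure(list(k = sch$rates, states = sch$states, boot = NULL),
              class = "rate_matrix_estimate")
  }
  expect_equal(transition_ratio(mk("control"))$ratio, 0.74 / 0.99)
  expect_equal(transition_ratio(mk("didemnin"))$ratio, 0.07 / 0.64)
  # symmetric toy scheme gives exactly 1
  k <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3,
              dimnames = rep(list(c("low", "mid", "high")), 2))
  est <- structure(list(k = k, states = colnames(k), boot = NULL),
                   class = "rate_matrix_estimate")
  expect_equal(transition_ratio(est)$ratio, 1)
  # zero denominator is an error, not a number
  k0 <- k; k0["mid", "low"] <- 0
  est0 <- structure(list(k = k0, states = colnames(k0), boot = NULL),
                    class = "rate_matrix_estimate")
  expect_error(transition_ratio(est0), "undefined")
})

test_that("survival curves are normalized, stepwise and exponential when they should be", {
  one <- data.frame(trace_id = 1, state = "mid", start_s = 0,
                    duration_s = 1, next_state = "high", censored = FALSE,
                    stringsAsFactors = FALSE)
  sc <- survival_curve(one, "mid", grid = c(0, 0.5, 0.99, 1.01))
  expect_equal(sc$survival, c(1, 1, 1, 0))
  # S(0) = 1 always
  set.seed(9)
  d <- data.frame(trace_id = rep(1:500, each = 10), state = "mid",
                  start_s = 0, duration_s = rexp(5000, 2),
                  next_state = "low", censored = FALSE,
                  stringsAsFactors = FALSE)
  grid <- seq(0, 1.5, by = 0.05)
  sc2 <- survival_curve(d, "mid", grid = grid)
  expect_equal(sc2$survival[1], 1)
  # log-survival slope approximates -k
  keep <- sc2$survival > 0.05
  slope <- coef(lm(log(sc2$survival[keep]) ~ sc2$time[keep]))[2]
  expect_lt(abs(slope + 2), 0.1)
})

test_that("bootstrap_statistic is correct, robust and deterministic", {
  units <- as.list(1:40)
  const <- bootstrap_statistic(units, function(u) 5, n_boot = 50, seed = 1)
  expect_equal(const$se, 0)
  set.seed(12)
  xs <- as.list(rnorm(200))
  bs <- bootstrap_statistic(xs, function(u) mean(unlist(u)),
                            n_boot = 1000, seed = 2)
  expect_lt(abs(bs$se - 1 / sqrt(200)) / (1 / sqrt(200)), 0.10)
  bs2 <- bootstrap_statistic(xs, function(u) mean(unlist(u)),
                             n_boot = 1000, seed = 2)
  expect_identical(bs$se, bs2$se)
  # statistics undefined on most resamples are an error: resampling with
  # replacement almost surely duplicates a unit, the original does not
  fragile <- function(u) {
    x <- unlist(u)
    if (anyDuplicated(x)) stop("duplicate unit")
    mean(x)
  }
  expect_error(bootstrap_statistic(units, fragile, n_boot = 20, seed = 3),
               "half")
})

test_that("missed-event correction rescales by destination detectability", {
  k <- matrix(c(0, 1.89, 0.01, 0.99, 0, 0.74, 0.24, 15.21, 0), 3, 3,
              byrow = TRUE, dimnames = rep(list(c("low", "mid", "high")), 2))
  est <- structure(list(k = k, k_total = rowSums(k),
                        se = k * 0, se_total = rowSums(k) * 0,
                        states = colnames(k), boot = NULL),
                   class = "rate_matrix_estimate")
  corr <- correct_missed_events(est, dead_time = 0.015)
  kt <- rowSums(k)
  expect_equal(corr$k["mid", "high"], 0.74 / exp(-kt["high"] * 0.015),
               ignore_attr = TRUE)
  expect_equal(corr$k["mid", "low"], 0.99 / exp(-kt["low"] * 0.015),
               ignore_attr = TRUE)
  expect_true(all(corr$k >= est$k))
  # zero dead time is the identity
  same <- correct_missed_events(est, dead_time = 0)
  expect_equal(same$k, est$k)
})
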