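# Kinetic outputs: truncation at the first long high-FRET dwell,
# count/occupancy transition-rate estimation with trace-level bootstrap
# errors, state lifetimes, transition ratios and survival curves.

#' Truncate an idealized trace before its first long high-FRET dwell
#'
#' Returns the prefix of the trace ending at the first frame of the first
#' high-FRET dwell whose duration is at least `min_high_dwell` (inclusive
#' threshold; at 15 ms frames, 150 ms means >= 10 frames). Rates estimated
#' from the truncated data describe dynamics prior to accommodation. The
#' entry into the long dwell is itself an observed mid-to-high transition
#' and is a stopping time of the process, so the prefix's final dwell keeps
#' its observed exit into the high state (recorded via `truncated_next`);
#' dropping it would bias the mid-to-high rate low. If no qualifying dwell
#' exists the trace is returned unchanged.
#'
#' @param ideal an `idealized_trace`.
#' @param min_high_dwell minimum qualifying high-FRET dwell in seconds
#'   (default 0.150).
#' @param high_state label of the high-FRET state.
#' @return an `idealized_trace` (possibly with zero frames when the trace
#'   begins in a qualifying high dwell).
#' @export
truncate_before_first_long_high <- function(ideal, min_high_dwell = 0.150,
                                            high_state = "high") {
  stopifnot(inherits(ideal, "idealized_trace"), min_high_dwell > 0)
  d <- extract_dwells(ideal)
  hit <- which(d$state == high_state &
                 d$duration_s >= min_high_dwell - .duration_eps)
  if (length(hit) == 0) return(ideal)
  j <- hit[1]
  n_keep <- round(d$start_s[j] / ideal$frame_period)
  out <- ideal
  out$state_seq <- ideal$state_seq[seq_len(n_keep)]
  out$fret <- ideal$fret[seq_len(n_keep)]
  out$truncated_next <- high_state
  out$truncated <- TRUE
  out
}

#' Truncate a dwell table before each trace's first long high-FRET dwell
#'
#' Dwell-table counterpart of [truncate_before_first_long_high()], used on
#' truth-path dwell tables. For each trace, dwells from the first
#' qualifying high-FRET dwell onward are dropped; the preceding dwell keeps
#' its observed exit into the high state.
#'
#' @param dwells dwell data.frame (see [extract_dwells()]).
#' @inheritParams truncate_before_first_long_high
#' @return truncated dwell data.frame.
#' @export
truncate_dwells <- function(dwells, min_high_dwell = 0.150,
                            high_state = "high") {
  stopifnot(min_high_dwell > 0)
  parts <- split(dwells, dwells$trace_id)
  out <- lapply(parts, function(d) {
    hit <- which(d$state == high_state &
                   d$duration_s >= min_high_dwell - .duration_eps)
    if (length(hit) == 0) return(d)
    j <- hit[1]
    if (j == 1) return(d[0, ])
    d <- d[seq_len(j - 1), ]
    d$next_state[j - 1] <- high_state
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# per-trace transition counts (among `states`) and per-state occupancy,
# flattened to one row; used by the estimator and its bootstrap
.trace_kinetic_stats <- function(d, states, exclude_censored_exits) {
  ns <- length(states)
  keep <- d$state %in% states
  d <- d[keep, , drop = FALSE]
  occ <- numeric(ns)
  counts <- matrix(0, ns, ns)
  if (nrow(d) > 0) {
    if (!exclude_censored_exits) d <- d[!d$censored, , drop = FALSE]
    si <- match(d$state, states)
    occ <- vapply(seq_len(ns),
                  function(s) sum(d$duration_s[si == s]), numeric(1))
    ex <- !d$censored & !is.na(d$next_state) & d$next_state %in% states
    if (any(ex)) {
      tr <- table(factor(si[ex], levels = seq_len(ns)),
                  factor(match(d$next_state[ex], states),
                         levels = seq_len(ns)))
      counts[] <- as.numeric(tr)
    }
  }
  c(as.numeric(counts), occ)
}

#' Estimate the apparent transition-rate matrix from a dwell table
#'
#' Count/occupancy estimator: \eqn{k_{i \to j} = N_{i \to j} / T_i}, the
#' number of observed i-to-j transitions divided by the total occupancy
#' time in state i. Censored dwells contribute occupancy time but no exit
#' event (set `exclude_censored_exits = FALSE` to drop censored dwells
#' entirely instead). Dark-state dwells and transitions to/from states
#' outside `states` are excluded. States with zero occupancy get `NA`
#' rates, never zero. Standard errors come from resampling whole traces
#' with replacement.
#'
#' @param dwells dwell data.frame (see [extract_dwells()]).
#' @param states state labels to estimate over, in index order (default
#'   `c("low", "mid", "high")`).
#' @param exclude_censored_exits if `TRUE` (default) censored dwells keep
#'   their occupancy but contribute no exit count.
#' @param n_boot number of bootstrap resamples (0 skips the bootstrap).
#' @param seed optional seed for the bootstrap.
#' @return object of class `rate_matrix_estimate`: `k` (rates, s^-1),
#'   `k_total` (row sums), `se`, `se_total`, `counts`, `occupancy`,
#'   `n_traces`, and (when bootstrapped) `boot`, the per-resample flattened
#'   rate matrices.
#' @export
estimate_rate_matrix <- function(dwells, states = c("low", "mid", "high"),
                                 exclude_censored_exits = TRUE,
                                 n_boot = 0, seed = NULL) {
  stopifnot(nrow(dwells) > 0)
  ns <- length(states)
  parts <- split(dwells, dwells$trace_id)
  M <- t(vapply(parts, .trace_kinetic_stats, numeric(ns * ns + ns),
                states = states,
                exclude_censored_exits = exclude_censored_exits))
  tot <- colSums(M)
  counts <- matrix(tot[seq_len(ns * ns)], ns, ns,
                   dimnames = list(states, states))
  occupancy <- setNames(tot[ns * ns + seq_len(ns)], states)
  if (sum(counts) == 0)
    stop("no uncensored transitions among the requested states")
  k <- counts / occupancy          # divides each row i by occupancy[i]
  k[occupancy == 0, ] <- NA_real_
  diag(k) <- 0
  k_total <- rowSums(k)

  se <- matrix(NA_real_, ns, ns, dimnames = dimnames(counts))
  se_total <- setNames(rep(NA_real_, ns), states)
  boot <- NULL
  if (n_boot > 0 && length(parts) >= 2) {
    if (!is.null(seed)) set.seed(seed)
    n_tr <- nrow(M)
    boot <- matrix(NA_real_, n_boot, ns * ns)
    for (b in seq_len(n_boot)) {
      w <- tabulate(sample.int(n_tr, n_tr, replace = TRUE), nbins = n_tr)
      s <- as.numeric(w %*% M)
      cb <- matrix(s[seq_len(ns * ns)], ns, ns)
      ob <- s[ns * ns + seq_len(ns)]
      kb <- cb / ob
      kb[ob == 0, ] <- NA_real_
      diag(kb) <- 0
      boot[b, ] <- as.numeric(kb)
    }
    se[] <- apply(boot, 2, stats::sd, na.rm = TRUE)
    diag(se) <- 0
    bt <- vapply(seq_len(n_boot), function(b)
      rowSums(matrix(boot[b, ], ns, ns)), numeric(ns))
    se_total[] <- apply(bt, 1, stats::sd, na.rm = TRUE)
  }
  structure(list(k = k, k_total = k_total, se = se, se_total = se_total,
                 counts = counts, occupancy = occupancy,
                 n_traces = length(parts), n_boot = n_boot,
                 states = states, boot = boot),
            class = "rate_matrix_estimate")
}

#' @export
print.rate_matrix_estimate <- function(x, ...) {
  cat(sprintf("Apparent rate matrix (s^-1) from %d traces:\n", x$n_traces))
  print(round(x$k, 4))
  cat("Per-state decay rates k_i (s^-1):\n")
  print(round(x$k_total, 4))
  invisible(x)
}

#' First-order missed-event (dead-time) correction of a rate estimate
#'
#' Sojourns shorter than the camera's effective dead time (about one frame)
#' cannot be resolved by idealization, so transition counts into
#' short-lived states are systematically undercounted: a sojourn in
#' destination state j survives detection with probability
#' \eqn{\exp(-k_j \tau_d)} under exponential dwells. This applies the
#' standard first-order correction of dwell-time kinetics,
#' \deqn{k^{corr}_{i \to j} = k_{i \to j} / \exp(-k_j \tau_d),}
#' using the apparent total decay rate \eqn{k_j} of the destination state
#' and a dead time of one frame period. Occupancy inflation from absorbed
#' short sojourns is second order and neglected. Bootstrap replicates, when
#' present, are corrected the same way so standard errors propagate.
#'
#' @param est a [estimate_rate_matrix()] result.
#' @param dead_time effective dead time in seconds (normally the frame
#'   period of the underlying traces).
#' @return a `rate_matrix_estimate` with corrected `k`, `k_total`, `se`,
#'   `se_total`; counts and occupancy are kept as observed.
#' @export
correct_missed_events <- function(est, dead_time) {
  stopifnot(inherits(est, "rate_matrix_estimate"), dead_time >= 0)
  ns <- length(est$states)
  kt <- est$k_total
  fac <- exp(-ifelse(is.finite(kt), kt, 0) * dead_time)
  k <- est$k
  for (j in seq_len(ns)) k[, j] <- est$k[, j] / fac[j]
  diag(k) <- 0
  est$k <- k
  est$k_total <- rowSums(k)
  if (!is.null(est$boot)) {
    boot <- est$boot
    for (b in seq_len(nrow(boot))) {
      kb <- matrix(boot[b, ], ns, ns)
      ktb <- rowSums(kb)
      fb <- exp(-ifelse(is.finite(ktb), ktb, 0) * dead_time)
      for (j in seq_len(ns)) kb[, j] <- kb[, j] / fb[j]
      boot[b, ] <- as.numeric(kb)
    }
    est$boot <- boot
    est$se[] <- apply(boot, 2, stats::sd, na.rm = TRUE)
    diag(est$se) <- 0
    bt <- vapply(seq_len(nrow(boot)), function(b)
      rowSums(matrix(boot[b, ], ns, ns)), numeric(ns))
    est$se_total[] <- apply(bt, 1, stats::sd, na.rm = TRUE)
  }
  est$dead_time <- dead_time
  est
}

#' Mean state lifetimes from a rate-matrix estimate
#'
#' Lifetime of state i is \eqn{1 / k_i}, the inverse of its total decay
#' rate. States with zero decay rate get infinite lifetime.
#'
#' @param est a [estimate_rate_matrix()] result.
#' @return named numeric vector of lifetimes in seconds.
#' @export
state_lifetimes <- function(est) {
  stopifnot(inherits(est, "rate_matrix_estimate"))
  out <- 1 / est$k_total
  out[est$k_total == 0] <- Inf
  out
}

#' Ratio of mid-to-high over mid-to-low transition rates
#'
#' The proofreading-to-initial-selection balance
#' \eqn{k_{2 \to 3} / k_{2 \to 1}}: how often the mid-FRET (GA) state
#' resolves toward accommodation versus back toward codon recognition.
#' A bootstrap standard error is computed from the estimate's stored
#' bootstrap replicates when available.
#'
#' @param est a [estimate_rate_matrix()] result with states
#'   `low`, `mid`, `high`.
#' @return list with `ratio` and `se` (`NA` when no bootstrap was run).
#' @export
transition_ratio <- function(est) {
  stopifnot(inherits(est, "rate_matrix_estimate"))
  st <- est$states
  i <- match("mid", st); jh <- match("high", st); jl <- match("low", st)
  if (anyNA(c(i, jh, jl))) stop("estimate lacks low/mid/high states")
  denom <- est$k[i, jl]
  if (!is.finite(denom) || denom == 0)
    stop("mid-to-low rate is zero or undefined; ratio undefined")
  ratio <- est$k[i, jh] / denom
  se <- NA_real_
  if (!is.null(est$boot)) {
    ns <- length(st)
    num_b <- est$boot[, (jh - 1) * ns + i]
    den_b <- est$boot[, (jl - 1) * ns + i]
    rb <- num_b / den_b
    rb <- rb[is.finite(rb)]
    if (length(rb) >= 2) se <- stats::sd(rb)
  }
  list(ratio = ratio, se = se)
}

#' Empirical survival curve of dwell durations in one state
#'
#' \eqn{S(t)} is the fraction of uncensored dwells in `state` with duration
#' greater than t, so \eqn{S(0) = 1}. An optional bootstrap band resamples
#' whole traces with replacement.
#'
#' @param dwells dwell data.frame.
#' @param state state label.
#' @param grid time points in seconds (default: 200 points spanning the
#'   observed durations).
#' @param n_boot bootstrap resamples for the per-time standard error.
#' @param seed optional bootstrap seed.
#' @return object of class `survival_curve`: data.frame with columns
#'   `time`, `survival`, `se`.
#' @export
survival_curve <- function(dwells, state, grid = NULL, n_boot = 0,
                           seed = NULL) {
  d <- dwells[dwells$state == state & !dwells$censored, , drop = FALSE]
  if (nrow(d) == 0) stop("no uncensored dwells in state ", state)
  if (is.null(grid))
    grid <- seq(0, max(d$duration_s), length.out = 200)
  surv <- vapply(grid, function(t) mean(d$duration_s > t), numeric(1))
  se <- rep(NA_real_, length(grid))
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    ids <- unique(d$trace_id)
    durs <- split(d$duration_s, d$trace_id)
    sb <- matrix(NA_real_, n_boot, length(grid))
    for (b in seq_len(n_boot)) {
      x <- unlist(durs[sample.int(length(ids), replace = TRUE)],
                  use.names = FALSE)
      sb[b, ] <- vapply(grid, function(t) mean(x > t), numeric(1))
    }
    se <- apply(sb, 2, stats::sd)
  }
  structure(data.frame(time = grid, survival = surv, se = se),
            class = c("survival_curve", "data.frame"))
}

#' Bootstrap a statistic over resampling units
#'
#' Resamples whole units (traces, or per-trace dwell groups) with
#' replacement and reports the standard deviation of the statistic across
#' resamples as its standard error, matching the trace-level bootstrap used
#' for all reported uncertainties. Resamples on which the statistic is
#' undefined (error or non-finite) are dropped and counted; more than 50%
#' drops is an error.
#'
#' @param units list of resampling units.
#' @param statistic function taking a list of units and returning a numeric
#'   scalar (or fixed-length vector).
#' @param n_boot number of bootstrap samples (default 1000).
#' @param seed optional integer seed; fixed seed gives identical results.
#' @return list with `estimate`, `se`, `n_boot`, `n_dropped`.
#' @export
bootstrap_statistic <- function(units, statistic, n_boot = 1000,
                                seed = NULL) {
  stopifnot(is.list(units), length(units) >= 2, n_boot >= 1)
  if (!is.null(seed)) set.seed(seed)
  est <- statistic(units)
  n <- length(units)
  reps <- matrix(NA_real_, n_boot, length(est))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    s <- tryCatch(statistic(units[sample.int(n, n, replace = TRUE)]),
                  error = function(e) NULL)
    if (is.null(s) || length(s) != length(est) || any(!is.finite(s))) {
      dropped <- dropped + 1L
    } else {
      reps[b, ] <- s
    }
  }
  if (dropped > n_boot / 2)
    stop("statistic undefined on more than half of the bootstrap resamples")
  se <- apply(reps, 2, stats::sd, na.rm = TRUE)
  if (length(est) == 1) se <- unname(se[1])
  list(estimate = est, se = se, n_boot = n_boot, n_dropped = dropped)
}
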