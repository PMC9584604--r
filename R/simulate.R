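# Stochastic simulation of state paths and rendering into donor/acceptor
# intensity traces with camera frame integration, Gaussian FRET noise and
# single-step photobleaching.

#' Photophysics / detection model for trace rendering
#'
#' @param total_intensity mean summed donor+acceptor counts per frame
#'   (arbitrary units).
#' @param fret_noise_sigma standard deviation of per-frame FRET
#'   (dimensionless). Default 0.06, comparable to the width of the observed
#'   ~0.2 / 0.45 / 0.7 state distributions.
#' @param donor_bleach_rate,acceptor_bleach_rate single-step photobleaching
#'   rate constants in s^-1; either bleach ends the usable trace.
#' @param frame_period camera integration time in seconds (0.015 for the
#'   fast acquisitions, 1 for slow-timescale movies).
#' @param background added counts per frame per channel.
#' @return object of class `photophysics_model`.
#' @export
photophysics_model <- function(total_intensity = 500,
                               fret_noise_sigma = 0.06,
                               donor_bleach_rate = 0,
                               acceptor_bleach_rate = 0,
                               frame_period = 0.015,
                               background = 0) {
  stopifnot(frame_period > 0, fret_noise_sigma >= 0,
            donor_bleach_rate >= 0, acceptor_bleach_rate >= 0,
            total_intensity > 0, background >= 0)
  structure(list(total_intensity = total_intensity,
                 fret_noise_sigma = fret_noise_sigma,
                 donor_bleach_rate = donor_bleach_rate,
                 acceptor_bleach_rate = acceptor_bleach_rate,
                 frame_period = frame_period,
                 background = background),
            class = "photophysics_model")
}

#' Simulate a state path from a kinetic scheme (Gillespie algorithm)
#'
#' Exact stochastic simulation of the continuous-time Markov chain: the
#' dwell in state i is exponential with rate \eqn{k_i} (the total exit
#' rate), and the next state is j with probability
#' \eqn{k_{i \to j} / k_i}. The path terminates at `t_max` or on entering
#' an absorbing state (which then occupies the remainder of the window).
#'
#' @param scheme a [kinetic_scheme()].
#' @param t_max observation window in seconds (> 0).
#' @param start_state starting state index or label.
#' @param seed optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @return object of class `state_path`: list with `events` (data.frame of
#'   `state` index, `label`, `start`, `end` in seconds), `t_end`,
#'   `fret_means`, `states`, `seed`. Dwells occupy half-open intervals
#'   `[start, end)` and tile `[0, t_end]` contiguously.
#' @export
simulate_state_path <- function(scheme, t_max, start_state = 1, seed = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"), t_max > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.character(start_state))
    start_state <- match(start_state, scheme$states)
  n_states <- length(scheme$states)
  if (is.na(start_state) || start_state < 1 || start_state > n_states)
    stop("invalid start_state")

  k_total <- scheme$k_total
  rates <- scheme$rates
  # grow in blocks; paths rarely exceed a few hundred events
  cap <- 64L
  st <- integer(cap); t0 <- numeric(cap); t1 <- numeric(cap)
  i <- 0L
  s <- as.integer(start_state)
  t <- 0
  while (t < t_max) {
    k <- k_total[s]
    dwell <- if (k > 0) rexp(1L, k) else Inf
    t_next <- min(t + dwell, t_max)
    i <- i + 1L
    if (i > cap) {
      cap <- cap * 2L
      length(st) <- cap; length(t0) <- cap; length(t1) <- cap
    }
    st[i] <- s; t0[i] <- t; t1[i] <- t_next
    if (!is.finite(dwell) || t + dwell >= t_max) break
    t <- t_next
    s <- sample.int(n_states, 1L, prob = rates[s, ])
  }
  idx <- seq_len(i)
  structure(
    list(events = data.frame(state = st[idx], label = scheme$states[st[idx]],
                             start = t0[idx], end = t1[idx],
                             stringsAsFactors = FALSE),
         t_end = t_max,
         states = scheme$states,
         fret_means = scheme$fret_means,
         seed = seed),
    class = "state_path"
  )
}

# piecewise-constant integral of the state FRET mean along a path,
# evaluated at arbitrary times in [0, t_end]
.path_fret_integral <- function(path, times) {
  ev <- path$events
  mu <- unname(path$fret_means[ev$state])
  cum <- cumsum(c(0, mu * (ev$end - ev$start)))
  i <- findInterval(times, ev$start)
  i[i < 1L] <- 1L
  cum[i] + (times - ev$start[i]) * mu[i]
}

# state occupying the path at given times (used for per-frame truth labels)
.path_state_at <- function(path, times) {
  i <- findInterval(times, path$events$start)
  i[i < 1L] <- 1L
  path$events$state[i]
}

#' Render a state path into a noisy donor/acceptor intensity trace
#'
#' Each frame's noiseless FRET is the occupancy-time-weighted mean of the
#' state FRET means within that frame (camera integration). Gaussian noise
#' of sd `fret_noise_sigma` is added, and donor/acceptor intensities are
#' back-computed from `total_intensity` so that
#' `fret == acceptor / (acceptor + donor)` holds exactly when
#' `background == 0`. Independent exponential photobleaching clocks are
#' drawn for each fluorophore; the trace is truncated at the first complete
#' frame before either bleach (no donor-only tail is modeled). The true
#' path is retained in the trace metadata.
#'
#' @param path a [simulate_state_path()] result.
#' @param model a [photophysics_model()].
#' @param seed optional integer seed.
#' @param meta named list of extra metadata (condition label,
#'   concentration, ids, ...).
#' @return object of class `fret_trace`: `donor`, `acceptor`, `fret`
#'   per-frame vectors, `frame_period`, and `meta` (including `truth`,
#'   the generating path, and per-frame `truth_state` labels taken at frame
#'   midpoints).
#' @export
render_trace <- function(path, model, seed = NULL, meta = list()) {
  stopifnot(inherits(path, "state_path"),
            inherits(model, "photophysics_model"))
  if (nrow(path$events) == 0) stop("empty state path")
  if (!is.null(seed)) set.seed(seed)
  dt <- model$frame_period
  tb_d <- if (model$donor_bleach_rate > 0) rexp(1L, model$donor_bleach_rate) else Inf
  tb_a <- if (model$acceptor_bleach_rate > 0) rexp(1L, model$acceptor_bleach_rate) else Inf
  t_use <- min(path$t_end, tb_d, tb_a)
  n <- floor(t_use / dt + .duration_eps)
  if (n < 1) {
    z <- numeric(0)
    return(structure(list(donor = z, acceptor = z, fret = z,
                          frame_period = dt,
                          meta = c(meta, list(truth = path,
                                              truth_state = character(0),
                                              t_bleach = min(tb_d, tb_a),
                                              seed = seed))),
                     class = "fret_trace"))
  }
  edges <- (0:n) * dt
  Fi <- .path_fret_integral(path, edges)
  fret_true <- diff(Fi) / dt
  fret <- fret_true + if (model$fret_noise_sigma > 0)
    rnorm(n, 0, model$fret_noise_sigma) else 0
  acceptor <- model$total_intensity * fret + model$background
  donor <- model$total_intensity * (1 - fret) + model$background
  tot <- acceptor + donor
  fret_obs <- ifelse(tot > 0, acceptor / tot, NA_real_)
  truth_state <- path$states[.path_state_at(path, edges[-(n + 1)] + dt / 2)]
  structure(list(donor = donor, acceptor = acceptor, fret = fret_obs,
                 frame_period = dt,
                 meta = c(meta, list(truth = path,
                                     truth_state = truth_state,
                                     t_bleach = min(tb_d, tb_a),
                                     seed = seed))),
            class = "fret_trace")
}

#' @export
length.fret_trace <- function(x) length(x$fret)

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("smFRET trace: %d frames at %g s/frame (%.3g s)\n",
              length(x), x$frame_period, length(x) * x$frame_period))
  invisible(x)
}

#' Bundle traces into a trace set
#'
#' @param traces list of [render_trace()] results.
#' @return list of traces with class `trace_set`; traces are assigned
#'   sequential `trace_id`s in their metadata if absent.
#' @export
trace_set <- function(traces) {
  stopifnot(is.list(traces), all(vapply(traces, inherits, TRUE, "fret_trace")))
  for (i in seq_along(traces))
    if (is.null(traces[[i]]$meta$trace_id))
      traces[[i]]$meta$trace_id <- i
  structure(traces, class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("Trace set: %d traces\n", length(x)))
  invisible(x)
}

#' @export
`[.trace_set` <- function(x, i) {
  structure(unclass(x)[i], class = "trace_set")
}

#' Simulate many traces from one scheme
#'
#' Simulates `n_traces` independent state paths and renders each into a
#' noisy trace. One top-level seed spawns per-trace substreams (see
#' [derive_seeds()]), so results are reproducible trace by trace.
#'
#' @inheritParams simulate_state_path
#' @param n_traces number of traces.
#' @param model a [photophysics_model()].
#' @param seed integer top-level seed.
#' @param meta named list of shared metadata stored on every trace.
#' @return a [trace_set()].
#' @export
simulate_traces <- function(scheme, n_traces, t_max, model, seed,
                            start_state = 1, meta = list()) {
  stopifnot(n_traces >= 1)
  seeds <- derive_seeds(seed, n_traces)
  traces <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    path <- simulate_state_path(scheme, t_max, start_state, seed = seeds[i])
    traces[[i]] <- render_trace(path, model, seed = NULL,
                                meta = c(meta, list(trace_id = i)))
  }
  trace_set(traces)
}

#' Simulate a drug dose series
#'
#' Drug occupancy follows a Hill law: at concentration c each molecule is
#' independently drug-bound with probability \eqn{c^h / (c^h + IC_{50}^h)}
#' and its trace is generated from `scheme_bound`, otherwise from
#' `scheme_free`.
#'
#' @param scheme_free,scheme_bound kinetic schemes for drug-free and
#'   drug-bound molecules.
#' @param ic50 half-maximal occupancy concentration in nM (> 0).
#' @param hill Hill coefficient (> 0).
#' @param concentrations numeric vector of concentrations in nM (>= 0).
#' @param n_traces traces per concentration.
#' @param model a [photophysics_model()].
#' @param t_max observation window in seconds.
#' @param seed integer top-level seed.
#' @param start_state starting state index or label.
#' @return named list (one element per concentration) of [trace_set()]s;
#'   each trace's metadata records `concentration_nM` and `bound`.
#' @export
simulate_dose_series <- function(scheme_free, scheme_bound, ic50, hill,
                                 concentrations, n_traces, model, t_max,
                                 seed, start_state = 1) {
  stopifnot(ic50 > 0, hill > 0, n_traces > 0)
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  conc_seeds <- derive_seeds(seed, length(concentrations))
  out <- vector("list", length(concentrations))
  names(out) <- format(concentrations, trim = TRUE)
  for (ci in seq_along(concentrations)) {
    c_nM <- concentrations[ci]
    p_bound <- if (c_nM == 0) 0 else c_nM^hill / (c_nM^hill + ic50^hill)
    seeds <- derive_seeds(conc_seeds[ci], n_traces)
    bound <- runif(n_traces) < p_bound
    traces <- vector("list", n_traces)
    for (i in seq_len(n_traces)) {
      sch <- if (bound[i]) scheme_bound else scheme_free
      path <- simulate_state_path(sch, t_max, start_state, seed = seeds[i])
      traces[[i]] <- render_trace(path, model, seed = NULL,
                                  meta = list(trace_id = i,
                                              concentration_nM = c_nM,
                                              bound = bound[i]))
    }
    out[[ci]] <- trace_set(traces)
  }
  attr(out, "concentrations") <- concentrations
  out
}

#' Simulate slow irreversible accommodation at 1 s resolution
#'
#' Each trace starts in the mid-FRET (GA) state and converts irreversibly
#' to the high-FRET accommodated state with hazard `k_slow`; the high state
#' is absorbing (cycloheximide blocks classical-to-hybrid excursions after
#' accommodation). Used for both sneak-through (accommodation under
#' saturating drug) and washout (drug-dissociation-limited accommodation)
#' scenarios, which differ only in the value of `k_slow`.
#'
#' @param k_slow conversion rate constant in s^-1 (> 0).
#' @param n_traces number of traces.
#' @param t_max movie length in seconds (> 0).
#' @param model a [photophysics_model()]; defaults to noise sd 0.06 at
#'   1 s frames with no photobleaching.
#' @param seed integer top-level seed.
#' @return a [trace_set()].
#' @export
simulate_slow_process <- function(k_slow, n_traces, t_max,
                                  model = photophysics_model(frame_period = 1),
                                  seed = 1) {
  stopifnot(k_slow > 0)
  if (t_max <= 0) stop("t_max must be > 0")
  r <- matrix(c(0, k_slow, 0, 0), 2, 2, byrow = TRUE)
  sch <- kinetic_scheme(c("mid", "high"), c(0.45, 0.7), r)
  simulate_traces(sch, n_traces, t_max, model, seed, start_state = "mid",
                  meta = list(k_slow = k_slow))
}
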