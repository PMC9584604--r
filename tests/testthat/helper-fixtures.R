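# Shared fixtures: all test inputs are generated in code.

# a symmetric two-state scheme (k12 = k21 = rate)
symmetric_scheme <- function(rate = 1) {
  kinetic_scheme(c("mid", "high"), c(0.45, 0.7),
                 matrix(c(0, rate, rate, 0), 2, 2, byrow = TRUE))
}

# build a fret_trace directly from a FRET vector
make_trace <- function(fret, frame_period = 0.015, total = 500,
                       trace_id = 1L) {
  structure(list(donor = total * (1 - fret), acceptor = total * fret,
                 fret = fret, frame_period = frame_period,
                 meta = list(trace_id = trace_id)),
            class = "fret_trace")
}

# build an idealized_trace directly from state labels
make_ideal <- function(labels, frame_period = 0.015,
                       all_labels = c("dark", "low", "mid", "high"),
                       fret = NULL, trace_id = 1L) {
  idx <- match(labels, all_labels)
  stopifnot(!anyNA(idx))
  if (is.null(fret))
    fret <- c(dark = 0, low = 0.2, mid = 0.45, high = 0.7)[labels]
  fretkin:::new_idealized_trace(idx, all_labels, unname(fret), frame_period,
                                trace_id = trace_id)
}

# exhaustive-enumeration Viterbi oracle: scores every possible state path
brute_viterbi <- function(obs, means, sds, A, pi0) {
  S <- length(means)
  T_ <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  ll <- log(pi0[paths[, 1]])
  for (t in seq_len(T_)) {
    ll <- ll + stats::dnorm(obs[t], means[paths[, t]], sds[paths[, t]],
                            log = TRUE)
    if (t > 1) ll <- ll + log(A[cbind(paths[, t - 1], paths[, t])])
  }
  list(loglik = max(ll), paths = paths[ll >= max(ll) - 1e-12, , drop = FALSE])
}

# joint log-probability of a given path under a model (reference formula)
path_loglik <- function(obs, path, means, sds, A, pi0) {
  n <- length(path)
  ll <- log(pi0[path[1]]) +
    sum(stats::dnorm(obs, means[path], sds[path], log = TRUE))
  if (n > 1) ll <- ll + sum(log(A[cbind(path[-n], path[-1])]))
  ll
}
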