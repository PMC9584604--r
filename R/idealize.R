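# Trace idealization: segmental k-means (SKM) training of a Gaussian-
# emission hidden Markov model, alternating Viterbi decoding with
# re-estimation of the transition matrix (and, optionally, the emission
# parameters) from the decoded path.

#' Gaussian-emission HMM for FRET idealization
#'
#' The default model has four states: a zero-FRET dark state (absorbing
#' pre-arrival and post-bleach frames so they do not corrupt low-FRET
#' statistics) plus the low (0.2), mid (0.45) and high (0.7) selection
#' states. Emission means are fixed by default; re-estimation is opt-in.
#'
#' @param means named numeric vector of per-state emission means.
#' @param sigmas per-state emission sd (recycled if scalar).
#' @param transition per-frame stochastic matrix; default has self
#'   probability 0.95 with the remainder split evenly (weakly informative).
#' @param initial initial state probabilities; default uniform.
#' @param fixed_means if `TRUE` (default) emission means and sigmas are held
#'   fixed during SKM; if `FALSE` they are re-estimated from the decoded
#'   path.
#' @return object of class `hmm_model`.
#' @export
hmm_model <- function(means = c(dark = 0, low = 0.2, mid = 0.45, high = 0.7),
                      sigmas = 0.06, transition = NULL, initial = NULL,
                      fixed_means = TRUE) {
  n <- length(means)
  stopifnot(n >= 2)
  if (is.null(names(means))) names(means) <- paste0("S", seq_len(n))
  sigmas <- rep_len(sigmas, n)
  stopifnot(all(sigmas > 0))
  if (is.null(transition)) {
    transition <- matrix((1 - 0.95) / (n - 1), n, n)
    diag(transition) <- 0.95
  }
  stopifnot(is.matrix(transition), nrow(transition) == n, ncol(transition) == n,
            all(transition >= 0),
            all(abs(rowSums(transition) - 1) < 1e-10))
  if (is.null(initial)) initial <- rep(1 / n, n)
  stopifnot(length(initial) == n, all(initial >= 0),
            abs(sum(initial) - 1) < 1e-10)
  structure(list(states = names(means),
                 means = unname(means),
                 sigmas = unname(sigmas),
                 transition = unname(transition),
                 initial = unname(initial),
                 fixed_means = fixed_means),
            class = "hmm_model")
}

# frames whose summed intensity is <= 0 carry no usable signal and are
# masked: their emission term is dropped from decoding and likelihoods
.trace_mask <- function(trace) {
  tot <- trace$donor + trace$acceptor
  !(is.finite(tot) & tot > 0)
}

#' Viterbi decoding of a trace under an HMM
#'
#' Returns the state sequence maximizing the joint log-probability of
#' states and Gaussian emissions. Ties are broken toward the lower state
#' index. Frames with summed intensity <= 0 are masked (no emission term);
#' any other non-finite FRET frame is an error.
#'
#' @param trace a `fret_trace` (or any list with `fret`, `donor`,
#'   `acceptor` fields).
#' @param model an [hmm_model()].
#' @return integer vector of 1-based state indices, one per frame.
#' @export
viterbi_path <- function(trace, model) {
  stopifnot(inherits(model, "hmm_model"))
  fret <- trace$fret
  if (length(fret) == 0) stop("empty trace")
  mask <- .trace_mask(trace)
  if (any(!mask & !is.finite(fret)))
    stop("non-finite FRET in unmasked frames; mask or trim the trace first")
  obs <- fret
  obs[mask] <- 0  # value is ignored under the mask but must be finite
  viterbi_decode_cpp(obs, mask, model$means, model$sigmas,
                     log(model$transition), log(model$initial))
}

# joint log-probability of a decoded path and the observations
.joint_loglik <- function(obs, mask, path, model) {
  ll <- log(model$initial[path[1]])
  n <- length(path)
  if (n > 1)
    ll <- ll + sum(log(model$transition[cbind(path[-n], path[-1])]))
  keep <- !mask
  if (any(keep))
    ll <- ll + sum(stats::dnorm(obs[keep], model$means[path[keep]],
                                model$sigmas[path[keep]], log = TRUE))
  ll
}

# maximum-likelihood re-estimation of model parameters from a decoded path;
# rows/states absent from the path keep their previous values
.reestimate <- function(obs, mask, path, model) {
  n_states <- length(model$states)
  n <- length(path)
  A <- model$transition
  if (n > 1) {
    counts <- matrix(0, n_states, n_states)
    tr <- table(factor(path[-n], levels = seq_len(n_states)),
                factor(path[-1], levels = seq_len(n_states)))
    counts[] <- as.numeric(tr)
    tot <- rowSums(counts)
    for (i in which(tot > 0)) A[i, ] <- counts[i, ] / tot[i]
  }
  model$transition <- A
  if (!model$fixed_means) {
    for (s in seq_len(n_states)) {
      sel <- path == s & !mask
      if (sum(sel) >= 2) {
        x <- obs[sel]
        model$means[s] <- mean(x)
        model$sigmas[s] <- max(sqrt(mean((x - mean(x))^2)), 1e-4)
      }
    }
  }
  model
}

#' Idealize a trace by segmental k-means (SKM)
#'
#' Alternates Viterbi decoding with maximum-likelihood re-estimation of the
#' per-frame transition matrix (and of emission means/sds when
#' `fixed_means = FALSE`) from the decoded path. Each half-step can only
#' increase the joint log-probability, so the iteration converges; it stops
#' when the decoded path is unchanged, when the relative log-probability
#' change falls below `tol`, or at `max_iter` (then flagged unconverged).
#'
#' @param trace a `fret_trace`.
#' @param model an [hmm_model()].
#' @param max_iter maximum SKM iterations.
#' @param tol relative joint log-probability convergence tolerance.
#' @return object of class `idealized_trace`: `state_seq` (1-based index
#'   per frame), `state_labels`, `fret` (raw observed FRET), `frame_period`,
#'   fitted `model`, `loglik` trajectory, `converged`, `n_iter`, `trace_id`.
#' @export
skm_idealize <- function(trace, model = hmm_model(), max_iter = 100,
                         tol = 1e-6) {
  stopifnot(inherits(model, "hmm_model"))
  fret <- trace$fret
  if (length(fret) == 0) stop("empty trace")
  mask <- .trace_mask(trace)
  if (any(!mask & !is.finite(fret)))
    stop("non-finite FRET in unmasked frames; mask or trim the trace first")
  obs <- fret
  obs[mask] <- 0

  path <- viterbi_decode_cpp(obs, mask, model$means, model$sigmas,
                             log(model$transition), log(model$initial))
  ll <- .joint_loglik(obs, mask, path, model)
  loglik <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    model <- .reestimate(obs, mask, path, model)
    new_path <- viterbi_decode_cpp(obs, mask, model$means, model$sigmas,
                                   log(model$transition), log(model$initial))
    new_ll <- .joint_loglik(obs, mask, new_path, model)
    loglik <- c(loglik, new_ll)
    if (identical(new_path, path) ||
        abs(new_ll - ll) <= tol * abs(ll)) {
      path <- new_path
      converged <- TRUE
      break
    }
    path <- new_path
    ll <- new_ll
  }
  new_idealized_trace(path, model$states, fret, trace$frame_period,
                      trace_id = trace$meta$trace_id, model = model,
                      loglik = loglik, converged = converged, n_iter = iter)
}

new_idealized_trace <- function(state_seq, state_labels, fret, frame_period,
                                trace_id = NULL, model = NULL,
                                loglik = NULL, converged = TRUE,
                                n_iter = 0L, truncated_next = NULL,
                                truncated = FALSE) {
  structure(list(state_seq = as.integer(state_seq),
                 state_labels = state_labels,
                 fret = fret,
                 frame_period = frame_period,
                 trace_id = trace_id,
                 model = model,
                 loglik = loglik,
                 converged = converged,
                 n_iter = n_iter,
                 truncated_next = truncated_next,
                 truncated = truncated),
            class = "idealized_trace")
}

#' @export
print.idealized_trace <- function(x, ...) {
  cat(sprintf("Idealized trace: %d frames at %g s/frame%s%s\n",
              length(x$state_seq), x$frame_period,
              if (x$truncated) ", truncated" else "",
              if (!x$converged) ", NOT converged" else ""))
  invisible(x)
}

#' Idealize every trace of a set
#'
#' @param traces a [trace_set()].
#' @param model an [hmm_model()] used as the starting point for each trace.
#' @param ... passed to [skm_idealize()].
#' @return list of `idealized_trace` objects (empty traces are skipped,
#'   with their count in attribute `"n_skipped"`).
#' @export
idealize_traces <- function(traces, model = hmm_model(), ...) {
  keep <- vapply(traces, function(tr) length(tr$fret) > 0, TRUE)
  ideals <- lapply(unclass(traces)[keep], skm_idealize, model = model, ...)
  attr(ideals, "n_skipped") <- sum(!keep)
  ideals
}

#' Extract dwells from an idealized trace
#'
#' Run-length encodes the state sequence into dwells. Runs shorter than
#' `min_frames` are merged into their longer neighbor (default 1: no
#' merging). The first and last dwells are flagged censored: their exits
#' are not used for rate estimation (entry into the first dwell is
#' unobserved in a real recording; the last dwell has no observed exit) —
#' except that a truncated trace's final dwell keeps its observed exit into
#' the high-FRET state (see [truncate_before_first_long_high()]).
#'
#' @param ideal an `idealized_trace`.
#' @param min_frames minimum run length in frames; shorter runs are merged.
#' @return data.frame with columns `trace_id`, `state` (label), `start_s`,
#'   `duration_s`, `next_state` (label or `NA`), `censored`.
#' @export
extract_dwells <- function(ideal, min_frames = 1) {
  stopifnot(inherits(ideal, "idealized_trace"))
  seq_ <- ideal$state_seq
  if (length(seq_) == 0) return(empty_dwell_table())
  if (min_frames > 1) {
    repeat {
      r <- rle(seq_)
      if (length(r$lengths) <= 1 || all(r$lengths >= min_frames)) break
      # merge the shortest offending run into its longer neighbor
      j <- which(r$lengths < min_frames)
      j <- j[which.min(r$lengths[j])][1]
      left <- if (j > 1) r$lengths[j - 1] else -Inf
      right <- if (j < length(r$lengths)) r$lengths[j + 1] else -Inf
      tgt <- if (left >= right) j - 1 else j + 1
      ends <- cumsum(r$lengths)
      idx <- (ends[j] - r$lengths[j] + 1):ends[j]
      seq_[idx] <- r$values[tgt]
    }
  }
  r <- rle(seq_)
  n <- length(r$lengths)
  dt <- ideal$frame_period
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  labels <- ideal$state_labels[r$values]
  next_state <- c(labels[-1], NA_character_)
  censored <- rep(FALSE, n)
  censored[1] <- TRUE
  censored[n] <- TRUE
  if (!is.null(ideal$truncated_next)) {
    next_state[n] <- ideal$truncated_next
    if (n > 1) censored[n] <- FALSE
  }
  data.frame(trace_id = if (is.null(ideal$trace_id)) NA_integer_
             else ideal$trace_id,
             state = labels,
             start_s = starts * dt,
             duration_s = r$lengths * dt,
             next_state = next_state,
             censored = censored,
             stringsAsFactors = FALSE)
}

empty_dwell_table <- function() {
  data.frame(trace_id = integer(0), state = character(0),
             start_s = numeric(0), duration_s = numeric(0),
             next_state = character(0), censored = logical(0),
             stringsAsFactors = FALSE)
}

#' Dwell table for a list of idealized traces
#'
#' @param ideals list of `idealized_trace` objects.
#' @param min_frames passed to [extract_dwells()].
#' @return combined dwell data.frame.
#' @export
dwell_table <- function(ideals, min_frames = 1) {
  do.call(rbind, lapply(ideals, extract_dwells, min_frames = min_frames))
}

#' Dwell table from true simulated state paths
#'
#' Bypasses rendering and idealization: converts the generating paths of a
#' trace set (or a list of `state_path` objects) directly into a dwell
#' table. Because the process genuinely starts at time zero, the first
#' dwell's exit is observed and only dwells cut at the window end are
#' censored. This is the oracle used to separate estimator bias from
#' idealization bias.
#'
#' @param x a [trace_set()] (paths taken from trace metadata) or a list of
#'   `state_path` objects.
#' @return dwell data.frame as in [extract_dwells()].
#' @export
truth_dwell_table <- function(x) {
  paths <- if (inherits(x, "trace_set"))
    lapply(unclass(x), function(tr) tr$meta$truth)
  else x
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    ev <- paths[[i]]$events
    n <- nrow(ev)
    labels <- paths[[i]]$states[ev$state]
    out[[i]] <- data.frame(
      trace_id = i,
      state = labels,
      start_s = ev$start,
      duration_s = ev$end - ev$start,
      next_state = c(labels[-1], NA_character_),
      censored = c(rep(FALSE, n - 1), TRUE),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
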