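# Very slow rate constants (sneak-through accommodation under saturating
# drug; washout-triggered accommodation reporting drug dissociation):
# first-event times from 1 Hz movies and censored exponential MLE.

#' First accommodation time per trace
#'
#' For each idealized trace, the entry time of its first qualifying
#' high-FRET dwell; traces without one are right-censored at the trace end
#' (movie end or photobleach). The qualification threshold is `min_dwell`
#' scaled to the frame period: the effective threshold is
#' `max(min_dwell, min_frames * frame_period)`. The two-frame persistence
#' floor exists because single-frame high-FRET excursions at 1 s resolution
#' are indistinguishable from noise outliers, while true accommodation is
#' irreversible (cycloheximide-stabilized) and persists to the movie end,
#' so requiring a second frame costs nothing.
#'
#' @param ideals list of `idealized_trace` objects.
#' @param min_dwell minimum qualifying high-FRET dwell in seconds
#'   (default 0.300).
#' @param min_frames minimum qualifying dwell in frames (default 2).
#' @param high_state label of the high-FRET state.
#' @return data.frame with columns `trace_id`, `time_s` (event or censoring
#'   time) and `event` (logical).
#' @export
first_accommodation_times <- function(ideals, min_dwell = 0.300,
                                      min_frames = 2,
                                      high_state = "high") {
  out <- lapply(seq_along(ideals), function(i) {
    ideal <- ideals[[i]]
    thr <- max(min_dwell, min_frames * ideal$frame_period)
    d <- extract_dwells(ideal)
    hit <- which(d$state == high_state &
                   d$duration_s >= thr - .duration_eps)
    if (length(hit) > 0) {
      data.frame(trace_id = i, time_s = d$start_s[hit[1]], event = TRUE)
    } else {
      data.frame(trace_id = i,
                 time_s = length(ideal$state_seq) * ideal$frame_period,
                 event = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Censored exponential MLE of a slow conversion rate
#'
#' Maximum-likelihood estimate of the exponential hazard under right
#' censoring: \eqn{k = (\mathrm{number\ of\ events}) / (\mathrm{summed\
#' observed\ time})}, where every trace contributes its event or censoring
#' time. With zero events only an upper bound is reported (the 95% bound
#' 3 / total observed time; the "rule of three"). The standard error comes
#' from resampling traces with replacement.
#'
#' @param times per-trace event or censoring times in seconds.
#' @param events logical: `TRUE` where an event was observed. `times` and
#'   `events` may also be given as the data.frame returned by
#'   [first_accommodation_times()].
#' @param n_boot bootstrap samples (default 1000).
#' @param seed optional bootstrap seed.
#' @return object of class `exponential_fit`: `rate` (s^-1, `NA` when no
#'   events), `se_rate`, `rate_upper_bound` (only with zero events),
#'   `amplitude` (observed event fraction), `n_events`, `n_total`,
#'   `total_time_s`.
#' @export
fit_exponential_accumulation <- function(times, events = NULL, n_boot = 1000,
                                         seed = NULL) {
  if (is.data.frame(times)) {
    events <- times$event
    times <- times$time_s
  }
  stopifnot(length(times) == length(events), all(times >= 0))
  total_time <- sum(times)
  n_events <- sum(events)
  if (total_time <= 0) stop("total observed time is zero")
  if (n_events == 0) {
    return(structure(list(rate = NA_real_, se_rate = NA_real_,
                          rate_upper_bound = 3 / total_time,
                          amplitude = 0, n_events = 0L,
                          n_total = length(times),
                          total_time_s = total_time),
                     class = "exponential_fit"))
  }
  rate <- n_events / total_time
  se <- NA_real_
  if (n_boot > 0 && length(times) >= 2) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(times)
    reps <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      tt <- sum(times[idx])
      if (tt > 0) reps[b] <- sum(events[idx]) / tt
    }
    se <- stats::sd(reps, na.rm = TRUE)
  }
  structure(list(rate = rate, se_rate = se, rate_upper_bound = NA_real_,
                 amplitude = n_events / length(times),
                 n_events = as.integer(n_events),
                 n_total = length(times),
                 total_time_s = total_time),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  if (is.na(x$rate)) {
    cat(sprintf("Exponential fit: no events in %d traces; rate < %.3g s^-1 (95%% bound)\n",
                x$n_total, x$rate_upper_bound))
  } else {
    cat(sprintf("Exponential fit: k = %.3g s^-1 (SE %.3g), %d/%d events over %.4g s\n",
                x$rate, x$se_rate, x$n_events, x$n_total, x$total_time_s))
  }
  invisible(x)
}

#' Fold change between two fitted rates
#'
#' Ratio `fit_a$rate / fit_b$rate` with a delta-method standard error
#' propagated from the two bootstrap SEs (rates treated as independent).
#'
#' @param fit_a,fit_b [fit_exponential_accumulation()] results (or any
#'   lists with `rate` and `se_rate` fields).
#' @return list with `ratio` and `se`.
#' @export
rate_fold_change <- function(fit_a, fit_b) {
  a <- fit_a$rate; b <- fit_b$rate
  if (!is.finite(a) || !is.finite(b) || b == 0)
    stop("both rates must be finite and the denominator nonzero")
  ratio <- a / b
  se <- NA_real_
  if (is.finite(fit_a$se_rate) && is.finite(fit_b$se_rate))
    se <- ratio * sqrt((fit_a$se_rate / a)^2 + (fit_b$se_rate / b)^2)
  list(ratio = ratio, se = se)
}
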