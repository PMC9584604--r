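# Accommodated fractions and Hill dose-response fitting.

# per-trace indicator: does the trace contain a qualifying high-FRET dwell?
.accommodated_flags <- function(ideals, min_dwell, high_state) {
  vapply(ideals, function(ideal) {
    d <- extract_dwells(ideal)
    any(d$state == high_state &
          d$duration_s >= min_dwell - .duration_eps)
  }, logical(1))
}

#' Accommodated fraction of a trace set
#'
#' A molecule counts as accommodated when its idealized trace contains at
#' least one high-FRET dwell lasting `min_dwell` seconds or more (inclusive
#' threshold; 300 ms is 20 frames at 15 ms). The standard error comes from
#' resampling traces with replacement.
#'
#' @param ideals list of `idealized_trace` objects.
#' @param min_dwell minimum qualifying high-FRET dwell in seconds
#'   (default 0.300).
#' @param high_state label of the high-FRET state.
#' @param n_boot bootstrap samples for the SE (default 1000).
#' @param seed optional bootstrap seed.
#' @return list with `fraction`, `se`, `n`, `n_accommodated`.
#' @export
accommodated_fraction <- function(ideals, min_dwell = 0.300,
                                  high_state = "high", n_boot = 1000,
                                  seed = NULL) {
  if (length(ideals) == 0) stop("empty input")
  acc <- .accommodated_flags(ideals, min_dwell, high_state)
  n <- length(acc)
  frac <- mean(acc)
  se <- NA_real_
  if (n_boot > 0 && n >= 2) {
    if (!is.null(seed)) set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(b)
      mean(acc[sample.int(n, n, replace = TRUE)]), numeric(1))
    se <- stats::sd(reps)
  }
  list(fraction = frac, se = se, n = n, n_accommodated = sum(acc))
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of
#' \deqn{f(c) = floor + (ceiling - floor) / (1 + (c / IC_{50})^h)}
#' to observed fractions versus concentration. The fit is performed on
#' log10 concentration (zero doses get a surrogate one decade below the
#' smallest nonzero dose) with a multi-start initialization grid: IC50
#' log-spaced over the sampled range crossed with Hill slopes 0.5, 1 and 2.
#' Floor and ceiling are fitted, not pinned.
#'
#' @param concentrations doses in nM (>= 0), at least 4 distinct values.
#' @param fractions observed response fraction per dose, in \[0, 1\].
#' @param weights optional least-squares weights (e.g. inverse binomial
#'   variances); default unweighted.
#' @param start optional named start values (`floor`, `ceiling`, `h`,
#'   `lic50` = log10 IC50 in nM) replacing the multi-start grid.
#' @return object of class `dose_response_fit`: `ic50` (nM), `hill_slope`,
#'   `floor`, `ceiling`, `converged`, plus the data. `se_ic50` is `NA`
#'   until filled in by a bootstrap (see [fit_dose_response()]).
#' @export
fit_hill <- function(concentrations, fractions, weights = NULL,
                     start = NULL) {
  stopifnot(length(concentrations) == length(fractions))
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (length(unique(concentrations)) < 4)
    stop("need at least 4 distinct concentrations")
  if (diff(range(fractions)) < 0.02)
    stop("flat response: IC50 unidentifiable")
  cs <- concentrations
  if (any(cs == 0)) cs[cs == 0] <- min(cs[cs > 0]) / 10
  lc <- log10(cs)
  dat <- data.frame(lc = lc, f = fractions)
  w <- if (is.null(weights)) rep(1, nrow(dat)) else weights
  lower <- c(floor = 0, ceiling = 0, h = 1e-3, lic50 = min(lc) - 3)
  upper <- c(floor = 1, ceiling = 1, h = 10, lic50 = max(lc) + 3)
  starts <- if (!is.null(start)) list(as.list(start)) else {
    grid <- expand.grid(lic50 = seq(min(lc), max(lc), length.out = 5),
                        h = c(0.5, 1, 2))
    lapply(seq_len(nrow(grid)), function(i)
      list(floor = max(min(fractions), 0),
           ceiling = min(max(fractions), 1),
           h = grid$h[i], lic50 = grid$lic50[i]))
  }
  best <- NULL
  best_rss <- Inf
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        f ~ floor + (ceiling - floor) / (1 + 10^(h * (lc - lic50))),
        data = dat, start = s, weights = w,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * resid(fit)^2)
    if (rss < best_rss) {
      best <- fit
      best_rss <- rss
    }
  }
  if (is.null(best))
    stop("Hill fit failed to converge from every start value")
  p <- coef(best)
  if (p[["ceiling"]] - p[["floor"]] < 0.02)
    stop("fitted response span is degenerate: IC50 unidentifiable")
  structure(list(ic50 = 10^p[["lic50"]],
                 hill_slope = p[["h"]],
                 floor = p[["floor"]],
                 ceiling = p[["ceiling"]],
                 se_ic50 = NA_real_,
                 concentrations = concentrations,
                 fractions = fractions,
                 n_traces = NULL,
                 converged = TRUE,
                 rss = best_rss),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Hill fit: IC50 = %.3g nM (SE %.3g), slope = %.3g, floor = %.3g, ceiling = %.3g\n",
              x$ic50, x$se_ic50, x$hill_slope, x$floor, x$ceiling))
  invisible(x)
}

#' Dose-response fit from idealized trace sets with bootstrap errors
#'
#' Computes the accommodated fraction at each concentration, fits the Hill
#' equation, and obtains the IC50 standard error by resampling traces with
#' replacement within each dose and refitting (each refit starts from the
#' point estimate).
#'
#' @param ideals_by_conc named list: one list of `idealized_trace` objects
#'   per concentration.
#' @param concentrations doses in nM, same length and order as
#'   `ideals_by_conc`.
#' @param min_dwell accommodation threshold in seconds (default 0.300).
#' @param high_state label of the high-FRET state.
#' @param n_boot bootstrap samples (default 1000).
#' @param seed optional bootstrap seed.
#' @return a `dose_response_fit` with `se_ic50` and per-dose `n_traces`
#'   filled in.
#' @export
fit_dose_response <- function(ideals_by_conc, concentrations,
                              min_dwell = 0.300, high_state = "high",
                              n_boot = 1000, seed = NULL) {
  stopifnot(length(ideals_by_conc) == length(concentrations))
  flags <- lapply(ideals_by_conc, .accommodated_flags,
                  min_dwell = min_dwell, high_state = high_state)
  fractions <- vapply(flags, mean, numeric(1))
  fit <- fit_hill(concentrations, fractions)
  fit$n_traces <- vapply(flags, length, integer(1))
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    start <- c(floor = fit$floor, ceiling = fit$ceiling,
               h = fit$hill_slope, lic50 = log10(fit$ic50))
    reps <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      fb <- vapply(flags, function(a)
        mean(a[sample.int(length(a), replace = TRUE)]), numeric(1))
      rb <- tryCatch(fit_hill(concentrations, fb, start = start),
                     error = function(e) NULL)
      if (!is.null(rb)) reps[b] <- rb$ic50
    }
    if (sum(is.na(reps)) > n_boot / 2)
      stop("Hill fit undefined on more than half of the bootstrap resamples")
    fit$se_ic50 <- stats::sd(reps, na.rm = TRUE)
    fit$n_boot <- n_boot
  }
  fit
}
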