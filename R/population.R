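# Ensemble summaries: post-synchronized FRET contour histograms and
# transition density plots (TDPs).

#' Post-synchronize idealized traces to the first appearance of FRET
#'
#' Shifts each trace so that frame 0 is its first frame assigned to a
#' non-dark state; when the model has no dark state, the first frame with
#' raw FRET above `fret_threshold` is used instead. Traces with no such
#' frame are dropped and counted in attribute `"n_dropped"`.
#'
#' @param ideals list of `idealized_trace` objects.
#' @param fret_threshold raw-FRET fallback threshold (default 0.12).
#' @param dark_state label of the dark state, if modeled.
#' @return list of shifted `idealized_trace` objects.
#' @export
postsynchronize <- function(ideals, fret_threshold = 0.12,
                            dark_state = "dark") {
  if (length(ideals) == 0) stop("empty input")
  out <- list()
  dropped <- 0L
  for (ideal in ideals) {
    has_dark <- dark_state %in% ideal$state_labels
    first <- if (has_dark) {
      di <- match(dark_state, ideal$state_labels)
      which(ideal$state_seq != di)[1]
    } else {
      which(ideal$fret > fret_threshold)[1]
    }
    if (is.na(first) || length(ideal$state_seq) == 0) {
      dropped <- dropped + 1L
      next
    }
    keep <- first:length(ideal$state_seq)
    ideal$state_seq <- ideal$state_seq[keep]
    ideal$fret <- ideal$fret[keep]
    out[[length(out) + 1L]] <- ideal
  }
  attr(out, "n_dropped") <- dropped
  out
}

new_histogram2d <- function(x_edges, y_edges, counts, normalized, n_traces) {
  structure(list(x_edges = x_edges, y_edges = y_edges, counts = counts,
                 normalized = normalized, n_traces = n_traces),
            class = "fret_histogram2d")
}

#' @export
print.fret_histogram2d <- function(x, ...) {
  cat(sprintf("2-D histogram: %d x %d bins, %d traces%s\n",
              nrow(x$counts), ncol(x$counts), x$n_traces,
              if (x$normalized) ", column-normalized" else ""))
  invisible(x)
}

#' Post-synchronized FRET occupancy contour histogram
#'
#' Two-dimensional histogram of raw FRET versus time since synchronization,
#' compiled over all aligned traces. Columns (time slices) are normalized
#' to unit mass where occupied, so each column is the FRET distribution at
#' that time.
#'
#' @param aligned list of post-synchronized `idealized_trace` objects (see
#'   [postsynchronize()]).
#' @param time_window window length in seconds (default 10).
#' @param fret_bins FRET bin edges (default 45 bins over \[-0.1, 1\]).
#' @param normalize normalize each time column to 1?
#' @return a `fret_histogram2d`; `counts` has one row per FRET bin and one
#'   column per frame, `x_edges` are frame-time edges in seconds and
#'   `y_edges` the FRET bin edges.
#' @export
contour_histogram <- function(aligned, time_window = 10,
                              fret_bins = seq(-0.1, 1.0, length.out = 46),
                              normalize = TRUE) {
  if (length(aligned) == 0) stop("empty input")
  dt <- aligned[[1]]$frame_period
  n_frames <- max(1L, floor(time_window / dt + .duration_eps))
  counts <- matrix(0, length(fret_bins) - 1L, n_frames)
  for (ideal in aligned) {
    n <- min(length(ideal$fret), n_frames)
    if (n == 0) next
    f <- ideal$fret[seq_len(n)]
    fb <- findInterval(f, fret_bins, rightmost.closed = TRUE)
    ok <- which(fb >= 1 & fb <= nrow(counts))
    for (t in ok) counts[fb[t], t] <- counts[fb[t], t] + 1
  }
  if (normalize) {
    cs <- colSums(counts)
    nz <- cs > 0
    counts[, nz] <- sweep(counts[, nz, drop = FALSE], 2, cs[nz], "/")
  }
  new_histogram2d(x_edges = (0:n_frames) * dt, y_edges = fret_bins,
                  counts = counts, normalized = normalize,
                  n_traces = length(aligned))
}

#' Transition density plot
#'
#' For every idealized transition, one point at (mean raw FRET of the
#' preceding dwell, mean raw FRET of the following dwell), binned on a
#' FRET x FRET grid. Dwell-mean raw FRET (rather than model means) keeps
#' the emission noise structure visible. Transitions into or out of the
#' dark state are excluded.
#'
#' @param ideals list of `idealized_trace` objects.
#' @param fret_bins bin edges for both axes.
#' @param dark_state label of the dark state.
#' @return a `fret_histogram2d` with rows = FRET before, columns = FRET
#'   after; total counts equal the number of non-dark transitions.
#' @export
transition_density <- function(ideals,
                               fret_bins = seq(-0.1, 1.0, length.out = 46),
                               dark_state = "dark") {
  if (length(ideals) == 0) stop("empty input")
  nb <- length(fret_bins) - 1L
  counts <- matrix(0, nb, nb)
  n_transitions <- 0L
  for (ideal in ideals) {
    if (length(ideal$state_seq) == 0) next
    r <- rle(ideal$state_seq)
    if (length(r$lengths) < 2) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    labels <- ideal$state_labels[r$values]
    fmean <- vapply(seq_along(r$lengths), function(i)
      mean(ideal$fret[starts[i]:ends[i]]), numeric(1))
    for (i in seq_len(length(r$lengths) - 1L)) {
      if (labels[i] == dark_state || labels[i + 1L] == dark_state) next
      bi <- findInterval(fmean[i], fret_bins, rightmost.closed = TRUE)
      bj <- findInterval(fmean[i + 1L], fret_bins, rightmost.closed = TRUE)
      if (bi >= 1 && bi <= nb && bj >= 1 && bj <= nb) {
        counts[bi, bj] <- counts[bi, bj] + 1
        n_transitions <- n_transitions + 1L
      }
    }
  }
  h <- new_histogram2d(x_edges = fret_bins, y_edges = fret_bins,
                       counts = counts, normalized = FALSE,
                       n_traces = length(ideals))
  h$n_transitions <- n_transitions
  h
}

#' Sum TDP counts inside a FRET-to-FRET region
#'
#' Convenience accessor, e.g. the mid-to-high region of a transition
#' density plot.
#'
#' @param tdp a [transition_density()] result.
#' @param from,to length-2 numeric ranges (FRET before / FRET after).
#' @return total counts in the region.
#' @export
tdp_region_counts <- function(tdp, from, to) {
  mids_x <- (tdp$x_edges[-1] + tdp$x_edges[-length(tdp$x_edges)]) / 2
  mids_y <- (tdp$y_edges[-1] + tdp$y_edges[-length(tdp$y_edges)]) / 2
  ri <- mids_x >= from[1] & mids_x <= from[2]
  rj <- mids_y >= to[1] & mids_y <= to[2]
  sum(tdp$counts[ri, rj])
}
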