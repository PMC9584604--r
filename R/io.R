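# Trace and configuration I/O: one CSV per trace plus an index TSV;
# YAML/JSON run configuration with lossless round-trips.

#' Write a trace set to disk
#'
#' One CSV per trace with columns `time_s`, `donor`, `acceptor`, `fret`
#' and, when the generating path is available, `truth_state`; plus an
#' `index.tsv` mapping trace id to file, condition, concentration, frame
#' period and seed.
#'
#' @param traces a [trace_set()].
#' @param dir output directory (created if absent).
#' @return invisibly, the index data.frame.
#' @export
write_traces <- function(traces, dir) {
  stopifnot(inherits(traces, "trace_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(traces)
  idx <- data.frame(
    trace_id = integer(n), file = character(n), condition = character(n),
    concentration_nM = numeric(n), frame_period = numeric(n),
    seed = integer(n), n_frames = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tr <- traces[[i]]
    id <- if (is.null(tr$meta$trace_id)) i else tr$meta$trace_id
    file <- sprintf("trace_%05d.csv", id)
    df <- data.frame(time_s = (seq_along(tr$fret) - 1) * tr$frame_period,
                     donor = tr$donor, acceptor = tr$acceptor,
                     fret = tr$fret)
    if (!is.null(tr$meta$truth_state))
      df$truth_state <- tr$meta$truth_state
    write.csv(df, file.path(dir, file), row.names = FALSE)
    idx$trace_id[i] <- id
    idx$file[i] <- file
    idx$condition[i] <- if (is.null(tr$meta$condition)) NA_character_
                        else tr$meta$condition
    idx$concentration_nM[i] <- if (is.null(tr$meta$concentration_nM))
      NA_real_ else tr$meta$concentration_nM
    idx$frame_period[i] <- tr$frame_period
    idx$seed[i] <- if (is.null(tr$meta$seed)) NA_integer_
                   else tr$meta$seed
    idx$n_frames[i] <- length(tr$fret)
  }
  write.table(idx, file.path(dir, "index.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(idx)
}

#' Read a trace set from disk
#'
#' Reads the layout written by [write_traces()]. A missing `fret` column is
#' recomputed from donor and acceptor intensities. Malformed files raise a
#' parse error naming the file; a non-positive frame period is rejected.
#'
#' @param dir directory containing `index.tsv` and per-trace CSVs.
#' @return a [trace_set()].
#' @export
read_traces <- function(dir) {
  idx_path <- file.path(dir, "index.tsv")
  if (!file.exists(idx_path)) stop("no index.tsv in ", dir)
  idx <- read.delim(idx_path, stringsAsFactors = FALSE)
  traces <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    path <- file.path(dir, idx$file[i])
    if (idx$frame_period[i] <= 0 || !is.finite(idx$frame_period[i]))
      stop("parse error in ", idx_path, ": non-positive frame_period for ",
           idx$file[i])
    df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                   error = function(e)
                     stop("parse error in ", path, ": ",
                          conditionMessage(e), call. = FALSE))
    for (col in c("donor", "acceptor"))
      if (is.null(df[[col]]) || !is.numeric(df[[col]]))
        stop("parse error in ", path, ": missing numeric column ", col)
    fret <- if (!is.null(df$fret)) df$fret else {
      tot <- df$donor + df$acceptor
      ifelse(tot > 0, df$acceptor / tot, NA_real_)
    }
    meta <- list(trace_id = idx$trace_id[i])
    if (!is.na(idx$condition[i])) meta$condition <- idx$condition[i]
    if (!is.na(idx$concentration_nM[i]))
      meta$concentration_nM <- idx$concentration_nM[i]
    if (!is.na(idx$seed[i])) meta$seed <- idx$seed[i]
    if (!is.null(df$truth_state)) meta$truth_state <- df$truth_state
    traces[[i]] <- structure(
      list(donor = df$donor, acceptor = df$acceptor, fret = fret,
           frame_period = idx$frame_period[i], meta = meta),
      class = "fret_trace")
  }
  trace_set(traces)
}

#' Write a dwell table as TSV
#'
#' @param dwells dwell data.frame.
#' @param path output file.
#' @export
write_dwells <- function(dwells, path) {
  write.table(dwells, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a 2-D histogram as a TSV matrix plus a JSON edge sidecar
#'
#' @param hist a `fret_histogram2d`.
#' @param path output TSV; edges go to `<path>.json`.
#' @export
write_histogram <- function(hist, path) {
  write.table(hist$counts, path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  jsonlite::write_json(list(x_edges = hist$x_edges, y_edges = hist$y_edges,
                            normalized = hist$normalized,
                            n_traces = hist$n_traces),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate and normalize a run configuration
#'
#' @param config named list with elements `condition` (preset label),
#'   `n_traces`, `t_max`, `frame_period`, `fret_noise_sigma`,
#'   `donor_bleach_rate`, `acceptor_bleach_rate`, `include_dark_arrival`,
#'   `arrival_rate`, `min_high_dwell`, `min_accommodated_dwell`, `n_boot`,
#'   `seed`, `max_iter`. Missing entries take the defaults below.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  defaults <- list(condition = "control", n_traces = 100, t_max = 10,
                   frame_period = 0.015, fret_noise_sigma = 0.06,
                   donor_bleach_rate = 0, acceptor_bleach_rate = 0,
                   include_dark_arrival = FALSE, arrival_rate = 0.5,
                   min_high_dwell = 0.150, min_accommodated_dwell = 0.300,
                   n_boot = 1000, seed = 1, max_iter = 100)
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, TRUE)])
  stopifnot(cfg$n_traces >= 1, cfg$t_max > 0, cfg$frame_period > 0,
            cfg$min_high_dwell > 0, cfg$min_accommodated_dwell > 0,
            cfg$n_boot >= 1)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else stop("config must be .yaml, .yml or .json: ", path)
  run_config(raw)
}

#' Write a run configuration
#'
#' @param config a [run_config()].
#' @param path output file (`.yaml`/`.yml` or `.json`); round-trips
#'   losslessly through [read_run_config()].
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else stop("config must be .yaml, .yml or .json: ", path)
  invisible(path)
}

# small stable content hash (FNV-1a, 32 bit, arithmetic in doubles) used
# for provenance records
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
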