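# Trial containers and CSV plumbing. A trial is one head-curvature recording
# (or a window of one) with optional pulse metadata; a trial set bundles
# trials with a manifest and, for synthetic data, the generating ground truth.

#' Construct a head-curvature trial record
#'
#' @param worm_id,trial_id identifiers.
#' @param t time (s), strictly increasing.
#' @param K head curvature (dimensionless scaled curvature, body-coordinate
#'   0.1-0.3 average by convention).
#' @param pulse_start,pulse_end pulse window (s) or `NA` for free locomotion.
#' @param side illumination side label.
#' @param censored whether the trial is excluded from analysis (e.g. the worm
#'   stopped moving forward).
#' @return an object of class `trial_record`.
#' @export
trial_record <- function(worm_id, trial_id, t, K,
                         pulse_start = NA_real_, pulse_end = NA_real_,
                         side = "both", censored = FALSE) {
  if (length(t) != length(K)) stop("t and K must have equal length")
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  if (any(!is.finite(K))) stop("K must be finite")
  if (!is.na(pulse_start) &&
      (pulse_start < t[1] || pulse_end > t[length(t)] || pulse_end <= pulse_start))
    stop("pulse window must lie within the time range")
  structure(list(worm_id = worm_id, trial_id = trial_id, t = t, K = K,
                 pulse_start = pulse_start, pulse_end = pulse_end,
                 side = side, censored = isTRUE(censored)),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("Trial %s/%s: %.3g s at ~%.3g Hz, pulse %s, censored: %s\n",
              x$worm_id, x$trial_id, diff(range(x$t)),
              1 / median(diff(x$t)),
              if (is.na(x$pulse_start)) "none"
              else sprintf("[%.2f, %.2f] s (%s)", x$pulse_start, x$pulse_end,
                           x$side),
              x$censored))
  invisible(x)
}

trial_set <- function(trials, truth = NULL, config = NULL) {
  structure(list(trials = trials, truth = truth, config = config),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Trial set: %d trials from %d worms (%d censored)%s\n",
              length(x$trials),
              length(unique(vapply(x$trials, `[[`, character(1), "worm_id"))),
              sum(vapply(x$trials, `[[`, logical(1), "censored")),
              if (is.null(x$truth)) "" else ", with ground truth"))
  invisible(x)
}

#' @rdname trial_record
#' @param x a `trial_set`.
#' @return `trial_manifest()`: the manifest data frame of a trial set.
#' @export
trial_manifest <- function(x) {
  do.call(rbind, lapply(x$trials, function(tr)
    data.frame(worm_id = tr$worm_id, trial_id = tr$trial_id,
               pulse_start_s = tr$pulse_start, pulse_end_s = tr$pulse_end,
               side = tr$side, censored = tr$censored)))
}

csv_header_note <- "# units: time in seconds, curvature dimensionless (K = kappa * L), angles in radians"

write_csv_commented <- function(df, path, note = csv_header_note) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(note, con)
  write.csv(df, con, row.names = FALSE)
}

read_csv_commented <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Write / read a trial set as CSV files plus a manifest
#'
#' One CSV per trial (columns `t_s`, `K`) plus `manifest.csv` with columns
#' `worm_id, trial_id, file, pulse_start_s, pulse_end_s, side, censored`.
#' Ground truth (when present) is written as `truth.json` and the generating
#' configuration as `config.yaml`.
#'
#' @param x a `trial_set`.
#' @param dir output directory (created if needed).
#' @return `write_trial_set()` returns `dir` invisibly; `read_trial_set()`
#'   returns a `trial_set`.
#' @export
write_trial_set <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- trial_manifest(x)
  man$file <- sprintf("trial_%s_%s.csv", man$worm_id, man$trial_id)
  for (i in seq_along(x$trials)) {
    tr <- x$trials[[i]]
    write_csv_commented(data.frame(t_s = tr$t, K = tr$K),
                        file.path(dir, man$file[i]))
  }
  write_csv_commented(man, file.path(dir, "manifest.csv"))
  if (!is.null(x$truth))
    jsonlite::write_json(x$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(x$config))
    yaml::write_yaml(unclass_config(x$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_trial_set
#' @export
read_trial_set <- function(dir) {
  man <- read_csv_commented(file.path(dir, "manifest.csv"))
  trials <- lapply(seq_len(nrow(man)), function(i) {
    d <- read_csv_commented(file.path(dir, man$file[i]))
    trial_record(man$worm_id[i], man$trial_id[i], d$t_s, d$K,
                 pulse_start = man$pulse_start_s[i],
                 pulse_end = man$pulse_end_s[i],
                 side = man$side[i], censored = man$censored[i])
  })
  truth <- NULL
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) truth <- jsonlite::read_json(tp, simplifyVector = TRUE)
  trial_set(trials, truth = truth)
}

#' Write / read a simulated trajectory as CSV
#'
#' Columns `t_s, K, Kdot, Ma, Mt`; switch events go to a companion file
#' `<stem>_events.csv` with columns `t_s, sign`.
#'
#' @param traj an `osc_traj`.
#' @param path CSV path (the events file shares its stem).
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   a data frame with attribute `events`.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t_s = traj$t, K = traj$K, Kdot = traj$Kdot)
  if (!is.null(traj$Ma)) { df$Ma <- traj$Ma; df$Mt <- traj$Mt }
  write_csv_commented(df, path)
  ev <- attr(traj, "events")
  if (!is.null(ev) && nrow(ev))
    write_csv_commented(data.frame(t_s = ev$t, sign = ev$sign),
                        sub("\\.csv$", "_events.csv", path))
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read_csv_commented(path)
  names(df)[names(df) == "t_s"] <- "t"
  evp <- sub("\\.csv$", "_events.csv", path)
  ev <- if (file.exists(evp)) {
    e <- read_csv_commented(evp)
    data.frame(t = e$t_s, sign = e$sign)
  } else data.frame(t = numeric(0), sign = integer(0))
  structure(df, events = ev, oscillatory = nrow(ev) >= 2,
            class = c("osc_traj", "data.frame"))
}

#' Write / read a kymogram (curvature over body coordinate and time)
#'
#' Dense CSV with the body coordinate of each column in the header row
#' (`K_<coord>`) and the time in the first column.
#'
#' @param t time (s).
#' @param kymogram matrix, rows = time, columns = body coordinate.
#' @param coords body coordinate per column.
#' @param path CSV path.
#' @export
write_kymogram <- function(t, kymogram, coords, path) {
  df <- data.frame(t_s = t, kymogram)
  names(df) <- c("t_s", sprintf("K_%g", coords))
  write_csv_commented(df, path)
  invisible(path)
}

#' @rdname write_kymogram
#' @return `read_kymogram()`: list with `t`, `kymogram`, `coords`.
#' @export
read_kymogram <- function(path) {
  df <- read_csv_commented(path)
  coords <- as.numeric(sub("^K_", "", names(df)[-1]))
  list(t = df[[1]], kymogram = as.matrix(df[, -1, drop = FALSE]),
       coords = coords)
}
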