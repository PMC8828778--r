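#' Single-cell inter-locus distance trace
#'
#' Time series of the minimum 2D distance between the two fluorescent
#' chromatin dots of one cell, sampled on a uniform grid (default 10-min
#' frames). `NA` distances mark frames where one or both dots were not
#' detected. `division_frames` are 1-based frame indices at which the budneck
#' marker has disappeared (the division happened during the preceding frame
#' interval).
#'
#' @param times Strictly increasing, uniformly spaced times in minutes.
#' @param distance Distances in micrometres (NA = undetected), same length.
#' @param cell_id Cell label.
#' @param budded Optional logical, per frame or single value.
#' @param division_frames Integer frame indices (1-based) of marker
#'   disappearance.
#' @return A `cici_trace` list.
#' @export
distance_trace <- function(times, distance, cell_id = 1L, budded = NA,
                           division_frames = integer(0)) {
  times <- as.numeric(times)
  distance <- as.numeric(distance)
  if (length(times) != length(distance)) {
    stop("`times` and `distance` must have equal length", call. = FALSE)
  }
  if (length(times) < 1L) stop("empty trace", call. = FALSE)
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || max(dt) - min(dt) > 1e-6 * max(dt))) {
    stop("`times` must be strictly increasing and uniformly spaced", call. = FALSE)
  }
  if (any(distance < 0, na.rm = TRUE)) stop("distances must be >= 0", call. = FALSE)
  division_frames <- sort(unique(as.integer(division_frames)))
  if (length(division_frames) &&
      (min(division_frames) < 1L || max(division_frames) > length(times))) {
    stop("`division_frames` out of range", call. = FALSE)
  }
  out <- list(cell_id = cell_id, times = times, distance = distance,
              budded = budded, division_frames = division_frames,
              frame_interval = if (length(dt)) dt[1] else NA_real_)
  class(out) <- "cici_trace"
  out
}

#' Trace quality control: the 80% signal rule
#'
#' A trace is analyzable only if dots are clearly detected (distance defined)
#' in at least 80% of its frames.
#'
#' @param trace A [distance_trace].
#' @param min_fraction Minimum fraction of frames with signal.
#' @return List with `fraction_frames_with_signal` and `passes`.
#' @export
qc_trace <- function(trace, min_fraction = 0.8) {
  stopifnot(inherits(trace, "cici_trace"))
  frac <- mean(!is.na(trace$distance))
  list(fraction_frames_with_signal = frac, passes = frac >= min_fraction)
}

# Core event state machine over a distance vector.
#
# Formation: first run of >= min_run consecutive frames with defined
# distance <= coloc (NA breaks a run). Disruption, scanning frames after a
# formation: the first frame where either (a) defined distance > hard, or
# (b) the frame is a "loss" (defined distance > coloc) and the count of
# losses within the trailing window of `window` consecutive frame positions
# reaches `losses` ("sliding"), or within `window` frames of the first loss
# ("anchored"). NA frames are neither co-localized nor lost. After a
# disruption the formation scan restarts at the next frame.
run_event_machine <- function(distance, coloc = 0.4, hard = 0.6,
                              window = 4L, losses = 2L, min_run = 3L,
                              window_mode = c("sliding", "anchored")) {
  window_mode <- match.arg(window_mode)
  n <- length(distance)
  co <- !is.na(distance) & distance <= coloc
  lost <- !is.na(distance) & distance > coloc
  over <- !is.na(distance) & distance > hard

  formation <- integer(0)
  disruption <- integer(0)
  i <- 1L
  repeat {
    # ---- formation scan from i
    f <- NA_integer_
    run <- 0L
    j <- i
    while (j <= n) {
      run <- if (co[j]) run + 1L else 0L
      if (run == min_run) {
        f <- j - min_run + 1L
        break
      }
      j <- j + 1L
    }
    if (is.na(f)) break
    formation <- c(formation, f)

    # ---- disruption scan from the frame after the formation frame
    d <- NA_integer_
    first_loss <- NA_integer_
    for (j in seq.int(f + 1L, length.out = max(n - f, 0L))) {
      if (over[j]) { d <- j; break }
      if (lost[j]) {
        if (window_mode == "sliding") {
          lo <- max(f + 1L, j - window + 1L)
          if (sum(lost[lo:j]) >= losses) { d <- j; break }
        } else {
          if (is.na(first_loss)) first_loss <- j
          if (j <= first_loss + window - 1L &&
              sum(lost[first_loss:j]) >= losses) { d <- j; break }
          if (j > first_loss + window - 1L) first_loss <- j  # re-anchor
        }
      }
    }
    if (is.na(d)) break
    disruption <- c(disruption, d)
    i <- d + 1L
    if (i > n) break
  }
  list(formation_frames = formation, disruption_frames = disruption)
}

#' Call contact formation in a distance trace
#'
#' Formation is the first frame of the earliest run of at least `min_run`
#' consecutive frames with distance at or below `coloc_threshold`; frames
#' with undetected dots break a run. The formation time is the time of that
#' first frame.
#'
#' @param trace A [distance_trace].
#' @param coloc_threshold Co-localization threshold, micrometres.
#' @param min_run Minimum consecutive co-localized frames.
#' @return List with `formation_frame` (1-based index or NA) and
#'   `formation_time` (minutes or NA).
#' @export
call_formation <- function(trace, coloc_threshold = 0.4, min_run = 3L) {
  stopifnot(inherits(trace, "cici_trace"))
  ev <- run_event_machine(trace$distance, coloc = coloc_threshold,
                          min_run = min_run)
  f <- if (length(ev$formation_frames)) ev$formation_frames[1] else NA_integer_
  list(formation_frame = f,
       formation_time = if (is.na(f)) NA_real_ else trace$times[f])
}

#' Call contact disruptions after a formation
#'
#' After formation, the contact is disrupted at the first frame where the
#' distance exceeds `hard_threshold`, or at the second loss of
#' co-localization within any `window` consecutive frames. After each
#' disruption a new formation may be called and the scan repeats, so several
#' disruption frames can be returned.
#'
#' @param trace A [distance_trace].
#' @param formation_frame 1-based formation frame (as from [call_formation]).
#' @param coloc_threshold,hard_threshold Thresholds in micrometres.
#' @param window Window length in frames.
#' @param losses_required Losses within the window that constitute disruption.
#' @param window_mode `"sliding"` (default; any `window`-frame window) or
#'   `"anchored"` (window anchored at the first loss).
#' @return Integer vector of disruption frames (possibly empty).
#' @export
call_disruption <- function(trace, formation_frame, coloc_threshold = 0.4,
                            hard_threshold = 0.6, window = 4L,
                            losses_required = 2L,
                            window_mode = c("sliding", "anchored")) {
  stopifnot(inherits(trace, "cici_trace"))
  n <- length(trace$distance)
  if (is.na(formation_frame) || formation_frame < 1L || formation_frame > n) {
    stop("`formation_frame` out of range", call. = FALSE)
  }
  # the state machine on the suffix re-discovers the given formation at its
  # first frame (the formation run is >= min_run co-localized frames), then
  # alternates disruption / re-formation exactly as the full-trace scan would
  d <- trace$distance[formation_frame:n]
  ev <- run_event_machine(d, coloc = coloc_threshold, hard = hard_threshold,
                          window = window, losses = losses_required,
                          min_run = 3L, window_mode = match.arg(window_mode))
  ev$disruption_frames + formation_frame - 1L
}

#' Call all formation and disruption events in a trace
#'
#' Runs the full state machine (formation by the `min_run` rule, disruption
#' by the hard-threshold or losses-in-window rule, repeating) and returns
#' every event with frames and times.
#'
#' @inheritParams call_disruption
#' @param min_run Minimum consecutive co-localized frames for formation.
#' @return A `cici_events` list: `cell_id`, `formation_frames`,
#'   `formation_times`, `disruption_frames`, `disruption_times`.
#' @export
call_events <- function(trace, coloc_threshold = 0.4, hard_threshold = 0.6,
                        window = 4L, losses_required = 2L, min_run = 3L,
                        window_mode = c("sliding", "anchored")) {
  stopifnot(inherits(trace, "cici_trace"))
  ev <- run_event_machine(trace$distance, coloc = coloc_threshold,
                          hard = hard_threshold, window = window,
                          losses = losses_required, min_run = min_run,
                          window_mode = match.arg(window_mode))
  out <- list(cell_id = trace$cell_id,
              formation_frames = ev$formation_frames,
              formation_times = trace$times[ev$formation_frames],
              disruption_frames = ev$disruption_frames,
              disruption_times = trace$times[ev$disruption_frames])
  class(out) <- "cici_events"
  out
}

# division time = midpoint of the frame interval over which the budneck
# marker disappears: the marker is last seen at frame d-1 and gone at frame d
division_times <- function(trace) {
  if (!length(trace$division_frames)) return(numeric(0))
  trace$times[trace$division_frames] - trace$frame_interval / 2
}

#' Disruption times relative to cell division
#'
#' For each disruption, the signed time to the nearest subsequent division
#' (negative = disruption before division). Division time is the midpoint of
#' the frame interval over which the budneck marker disappears. Disruptions
#' with no later division are referenced to the nearest preceding division
#' and flagged.
#'
#' @param events A `cici_events` object from [call_events].
#' @param trace The matching [distance_trace] (must carry division frames).
#' @return Data frame with `disruption_time`, `relative_time_min`,
#'   `division_time`, `flagged_no_later_division`.
#' @export
disruption_relative_to_division <- function(events, trace) {
  stopifnot(inherits(events, "cici_events"), inherits(trace, "cici_trace"))
  if (!length(trace$division_frames)) {
    stop("trace has no division frames", call. = FALSE)
  }
  divs <- division_times(trace)
  if (!length(events$disruption_times)) {
    return(data.frame(disruption_time = numeric(0), relative_time_min = numeric(0),
                      division_time = numeric(0), flagged_no_later_division = logical(0)))
  }
  res <- lapply(events$disruption_times, function(td) {
    later <- divs[divs >= td]
    if (length(later)) {
      data.frame(disruption_time = td, relative_time_min = td - later[1],
                 division_time = later[1], flagged_no_later_division = FALSE)
    } else {
      prev <- max(divs[divs < td])
      data.frame(disruption_time = td, relative_time_min = td - prev,
                 division_time = prev, flagged_no_later_division = TRUE)
    }
  })
  do.call(rbind, res)
}

#' Did the contact persist through cell division?
#'
#' `TRUE` iff a formation was called before the division, the trace continues
#' at least `min_post_frames` frames past the division frame, and no
#' disruption is called in the window from one frame before the division to
#' `post_window` frames after it. `NA` when the preconditions fail.
#'
#' @param events A `cici_events` object.
#' @param trace The matching [distance_trace].
#' @param division_frame Division frame to assess (default: first).
#' @param post_window Frames after division in which a disruption counts as a
#'   division-coincident disruption.
#' @param min_post_frames Required post-division trace length.
#' @return `TRUE`, `FALSE`, or `NA`.
#' @export
persistence_through_division <- function(events, trace,
                                         division_frame = NULL,
                                         post_window = 4L,
                                         min_post_frames = 3L) {
  stopifnot(inherits(events, "cici_events"), inherits(trace, "cici_trace"))
  if (is.null(division_frame)) {
    if (!length(trace$division_frames)) stop("trace has no division frames", call. = FALSE)
    division_frame <- trace$division_frames[1]
  }
  n <- length(trace$distance)
  if (n - division_frame < min_post_frames) return(NA)
  f <- events$formation_frames
  if (!length(f) || min(f) >= division_frame) return(NA)
  # contact must be in the formed state going into the division
  last_f <- max(f[f < division_frame])
  d_before <- events$disruption_frames[events$disruption_frames > last_f &
                                       events$disruption_frames < division_frame - 1L]
  if (length(d_before)) return(NA)  # contact already gone well before division
  hit <- events$disruption_frames[events$disruption_frames >= division_frame - 1L &
                                  events$disruption_frames <= division_frame + post_window]
  !length(hit)
}

#' Histogram of formation times
#'
#' Left-closed bins `[0, bw)`, `[bw, 2 bw)`, ... spanning all observations.
#'
#' @param times Non-negative formation times in minutes.
#' @param bin_width Bin width in minutes.
#' @return Data frame with `bin_left`, `bin_right`, `count`; zero rows for
#'   empty input.
#' @export
formation_time_histogram <- function(times, bin_width = 10) {
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("`times` must be non-negative and finite", call. = FALSE)
  }
  if (!length(times)) {
    return(data.frame(bin_left = numeric(0), bin_right = numeric(0),
                      count = integer(0)))
  }
  k <- floor(times / bin_width)
  counts <- tabulate(k + 1L, nbins = max(k) + 1L)
  data.frame(bin_left = bin_width * (seq_along(counts) - 1L),
             bin_right = bin_width * seq_along(counts),
             count = counts)
}

#' Read / write distance traces as CSV
#'
#' Long-format CSV with columns `cell_id`, `time_min`, `distance_um`
#' (empty = undetected), optional `budded`, and `division` (0/1 flag at the
#' marker-disappearance frame).
#'
#' @param path CSV file path.
#' @return `read_traces`: a list of [distance_trace] objects.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "time_min", "distance_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("traces CSV missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$time_min), ]
    distance_trace(
      times = d$time_min,
      distance = d$distance_um,
      cell_id = d$cell_id[1],
      budded = if ("budded" %in% names(df)) d$budded else NA,
      division_frames = if ("division" %in% names(df)) which(d$division == 1) else integer(0)
    )
  })
}

#' @rdname read_traces
#' @param traces List of [distance_trace] objects.
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    division <- integer(length(tr$times))
    division[tr$division_frames] <- 1L
    data.frame(cell_id = tr$cell_id, time_min = tr$times,
               distance_um = tr$distance,
               budded = if (length(tr$budded) == length(tr$times)) tr$budded else NA,
               division = division)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
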