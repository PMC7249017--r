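#' Event sequences
#'
#' An `event_sequence` holds the ordered characteristic times detected in a
#' trial (movement start, amplitude peak / phase reversals, movement end;
#' or heel-off / toe-off / heel-strike / foot-flat for gait) together with
#' the cycle index table the feature formulas consume. Event times are
#' `(index - 1) / sample_rate`, i.e. sample-resolution, no sub-sample
#' interpolation.
#'
#' @param events data.frame with columns `kind`, `index`, `time`.
#' @param cycles data.frame of per-cycle sample indices (grammar-dependent
#'   columns), or `NULL`.
#' @param kind Segmentation grammar name.
#' @param sample_rate Hz.
#' @return An object of class `event_sequence`.
#' @export
event_sequence <- function(events, cycles = NULL, kind = "tapping_biphasic",
                           sample_rate = 100) {
  if (nrow(events) > 1 && any(diff(events$time) <= 0))
    stopf("event times must strictly increase")
  structure(list(events = events, cycles = cycles, kind = kind,
                 sample_rate = sample_rate), class = "event_sequence")
}

#' @export
print.event_sequence <- function(x, ...) {
  cat(sprintf("<event_sequence> %s: %d events, %d cycles\n", x$kind,
              nrow(x$events), if (is.null(x$cycles)) 0L else nrow(x$cycles)))
  if (nrow(x$events)) print(utils::head(x$events, 8))
  invisible(x)
}

#' Event times of a given kind
#' @param ev An `event_sequence`.
#' @param kind Event kind, e.g. `"T_end"`.
#' @return Numeric vector of times in seconds.
#' @export
event_times <- function(ev, kind) ev$events$time[ev$events$kind == kind]

empty_events <- function() {
  data.frame(kind = character(0), index = integer(0), time = numeric(0))
}

# first index >= from satisfying cond (logical vector), or NA
next_idx <- function(cond, from) {
  if (from > length(cond)) return(NA_integer_)
  k <- which(cond[from:length(cond)])
  if (!length(k)) NA_integer_ else from + k[1L] - 1L
}

REFRACTORY_S <- 0.05  # minimum spacing between detections; max plausible tap
                      # rate is far below 20 Hz, so this only suppresses
                      # noise-induced double triggers

#' Segment a biphasic tapping-type signal
#'
#' Detects repetitive open/close cycles on the dominant-axis angular
#' velocity. Each cycle is: `T_start`, the first sample with
#' `omega >= start_th` (deg/s, positive); a mid event at the first following
#' downward zero-crossing (maximum movement amplitude, direction reversal);
#' and `T_end`, the first sample with `omega >= end_th` (negative threshold)
#' *after* omega has dropped below `end_th` — the arming step prevents the
#' end rule from firing at the zero-crossing itself. Trailing incomplete
#' cycles are discarded; cycles never overlap. Serves the finger/hand/foot
#' tapping grammars and pronation-supination.
#'
#' @param omega Conditioned dominant-axis angular velocity, deg/s (sign
#'   convention: leading lobe positive).
#' @param start_th Positive start threshold, deg/s.
#' @param end_th Non-positive end threshold, deg/s.
#' @param sample_rate Hz.
#' @param mid_kind Label for the mid event (`"T_TF"`, `"T_OC"`, `"T_PS"`,
#'   `"T_HS"`, `"T_TO"`, `"T_HE"` depending on the task).
#' @return An [event_sequence()] with cycle triples (`start`, `mid`, `end`).
#'   A flat or sub-threshold signal yields zero cycles (not an error).
#' @export
segment_tapping <- function(omega, start_th, end_th, sample_rate = 100,
                            mid_kind = "T_mid") {
  stopifnot(start_th > 0, end_th <= 0)
  r <- max(1L, round(REFRACTORY_S * sample_rate))
  n <- length(omega)
  ge_start <- omega >= start_th
  neg <- omega < 0
  below_end <- omega < end_th
  ge_end <- omega >= end_th
  starts <- integer(0); mids <- integer(0); ends <- integer(0)
  i <- 1L
  repeat {
    s <- next_idx(ge_start, i); if (is.na(s)) break
    m <- next_idx(neg, s + 1L); if (is.na(m)) break
    d <- next_idx(below_end, m); if (is.na(d)) break
    e <- next_idx(ge_end, d + 1L); if (is.na(e)) break
    starts <- c(starts, s); mids <- c(mids, m); ends <- c(ends, e)
    i <- e + r
  }
  idx <- as.vector(rbind(starts, mids, ends))
  events <- data.frame(
    kind = rep(c("T_start", mid_kind, "T_end"), length(starts)),
    index = idx, time = (idx - 1) / sample_rate)
  cycles <- data.frame(start = starts, mid = mids, end = ends)
  event_sequence(events, cycles, "tapping_biphasic", sample_rate)
}

#' Segment alternating heel-toe tapping
#'
#' The first threshold exceedance (`|omega| >= th`) fixes which movement
#' comes first; thereafter heel-strike events (`T_HS`, downward
#' zero-crossing closing a positive lobe) and toe-off events (`T_TO`, upward
#' zero-crossing closing a negative lobe) alternate. Each lobe must exceed
#' the threshold before its terminating zero-crossing counts.
#'
#' @param omega Conditioned angular velocity, deg/s.
#' @param th Threshold, deg/s (20 for the heel-toe task).
#' @param sample_rate Hz.
#' @return An [event_sequence()] of alternating `T_HS`/`T_TO` events.
#' @export
segment_heel_toe <- function(omega, th = 20, sample_rate = 100) {
  r <- max(1L, round(REFRACTORY_S * sample_rate))
  kinds <- character(0); idx <- integer(0)
  i <- 1L
  repeat {
    a <- next_idx(abs(omega) >= th, i); if (is.na(a)) break
    if (omega[a] > 0) {
      e <- next_idx(omega < 0, a + 1L); if (is.na(e)) break
      kinds <- c(kinds, "T_HS")
    } else {
      e <- next_idx(omega > 0, a + 1L); if (is.na(e)) break
      kinds <- c(kinds, "T_TO")
    }
    idx <- c(idx, e)
    i <- e + r
  }
  events <- data.frame(kind = kinds, index = idx,
                       time = (idx - 1) / sample_rate)
  event_sequence(events, NULL, "heel_toe", sample_rate)
}

#' Segment a gait (walking) trial into strides
#'
#' Per stride, on the sagittal-plane foot angular velocity: `T_start` at
#' heel-off (`omega < -th_ho`), `T_TO` at the next upward zero-crossing
#' (toe-off), `T_HS` at the next downward zero-crossing (heel-strike), and
#' `T_end` at foot-flat, the first sample with `omega > -th_ff` after the
#' heel-strike lobe has dropped below `-th_ff`. Strides are ordered and
#' non-overlapping; a trailing incomplete stride is discarded.
#'
#' @param omega Conditioned foot sagittal angular velocity, deg/s.
#' @param th_ho Heel-off threshold, deg/s (50 for gait).
#' @param th_ff Foot-flat threshold, deg/s (3).
#' @param sample_rate Hz.
#' @return An [event_sequence()] with stride quadruples
#'   (`start`, `to`, `hs`, `end`).
#' @export
segment_gait <- function(omega, th_ho = 50, th_ff = 3, sample_rate = 100) {
  r <- max(1L, round(REFRACTORY_S * sample_rate))
  heel_off <- omega < -th_ho
  pos <- omega > 0
  neg <- omega < 0
  below_ff <- omega <= -th_ff
  above_ff <- omega > -th_ff
  S <- integer(0); TO <- integer(0); HS <- integer(0); E <- integer(0)
  i <- 1L
  repeat {
    s <- next_idx(heel_off, i); if (is.na(s)) break
    to <- next_idx(pos, s + 1L); if (is.na(to)) break
    hs <- next_idx(neg, to + 1L); if (is.na(hs)) break
    d <- next_idx(below_ff, hs); if (is.na(d)) break
    e <- next_idx(above_ff, d + 1L); if (is.na(e)) break
    S <- c(S, s); TO <- c(TO, to); HS <- c(HS, hs); E <- c(E, e)
    i <- e + r
  }
  idx <- as.vector(rbind(S, TO, HS, E))
  events <- data.frame(
    kind = rep(c("T_start", "T_TO", "T_HS", "T_end"), length(S)),
    index = idx, time = (idx - 1) / sample_rate)
  cycles <- data.frame(start = S, to = TO, hs = HS, end = E)
  event_sequence(events, cycles, "gait", sample_rate)
}

#' Segment a 360-degree rotation into turning steps
#'
#' For a clockwise rotation (right-foot pivot) each step starts when the
#' vertical-axis angular velocity drops to `omega <= -th` and ends when it
#' returns to `omega >= -th_v`; the anticlockwise direction mirrors the
#' signs.
#'
#' @param omega Conditioned vertical-axis angular velocity, deg/s (raw sign).
#' @param direction `"clockwise"` or `"anticlockwise"`.
#' @param th Step threshold, deg/s (50).
#' @param th_v Rest threshold, deg/s (5).
#' @param sample_rate Hz.
#' @return An [event_sequence()] with step pairs (`start`, `end`).
#' @export
segment_rotation <- function(omega, direction = c("clockwise", "anticlockwise"),
                             th = 50, th_v = 5, sample_rate = 100) {
  direction <- match.arg(direction)
  x <- if (direction == "clockwise") -omega else omega
  r <- max(1L, round(REFRACTORY_S * sample_rate))
  S <- integer(0); E <- integer(0)
  i <- 1L
  repeat {
    s <- next_idx(x >= th, i); if (is.na(s)) break
    e <- next_idx(x <= th_v, s + 1L); if (is.na(e)) break
    S <- c(S, s); E <- c(E, e)
    i <- e + r
  }
  idx <- as.vector(rbind(S, E))
  events <- data.frame(kind = rep(c("T_start", "T_end"), length(S)),
                       index = idx, time = (idx - 1) / sample_rate)
  cycles <- data.frame(start = S, end = E)
  event_sequence(events, cycles, "rotation", sample_rate)
}

#' Segment arm swing during gait
#'
#' `T_start` at the first `|omega| >= th_gt`; thereafter alternating
#' `T_front` / `T_back` events at direction reversals, detected when the
#' signal re-enters the `±turn_bound` band after the corresponding lobe has
#' exceeded `th_gt`.
#'
#' @param omega Conditioned arm angular velocity, deg/s (forward positive).
#' @param th_gt Swing threshold, deg/s (10).
#' @param turn_bound Reversal band, deg/s (2).
#' @param sample_rate Hz.
#' @return An [event_sequence()] of `T_start` then alternating
#'   `T_front`/`T_back` events.
#' @export
segment_arm_swing <- function(omega, th_gt = 10, turn_bound = 2,
                              sample_rate = 100) {
  r <- max(1L, round(REFRACTORY_S * sample_rate))
  kinds <- character(0); idx <- integer(0)
  s0 <- next_idx(abs(omega) >= th_gt, 1L)
  if (!is.na(s0)) {
    kinds <- "T_start"; idx <- s0
    i <- s0
    positive_phase <- omega[s0] > 0
    repeat {
      if (positive_phase) {
        a <- next_idx(omega >= th_gt, i); if (is.na(a)) break
        e <- next_idx(omega <= turn_bound, a + 1L); if (is.na(e)) break
        kinds <- c(kinds, "T_front")
      } else {
        a <- next_idx(omega <= -th_gt, i); if (is.na(a)) break
        e <- next_idx(omega >= -turn_bound, a + 1L); if (is.na(e)) break
        kinds <- c(kinds, "T_back")
      }
      idx <- c(idx, e)
      positive_phase <- !positive_phase
      i <- e + r
    }
  }
  events <- data.frame(kind = kinds, index = idx,
                       time = (idx - 1) / sample_rate)
  event_sequence(events, NULL, "arm_swing", sample_rate)
}

#' Static analysis window for tremor tasks
#'
#' The protocol records 3 s of static baseline before the task; for the
#' tremor tasks (and the spectral analysis of the leg-agility task) the
#' analysed window starts 3 s after acquisition onset and ends 10 s later,
#' clipped to the recording length.
#'
#' @param rec An [imu_recording()] of exercise HRST, POST or HEHE.
#' @return `c(start, end)` in seconds (relative to the first sample).
#' @export
static_window <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  if (!rec$exercise %in% c("HRST", "POST", "HEHE"))
    stopf("static_window applies to HRST, POST and HEHE, not %s", rec$exercise)
  dur <- (n_samples(rec) - 1) / rec$sample_rate
  if (dur < 3) stopf("recording shorter than the 3 s static lead-in")
  c(3, min(13, dur))
}

#' Segment a conditioned recording with its task grammar
#'
#' Dispatches to the grammar-specific segmenter using the exercise registry:
#' sign conventions (negative-leading tasks, left-side mirroring for
#' pronation-supination, arm swing and rotation direction) are applied to
#' the dominant axis first, so one state machine per grammar serves both
#' sides.
#'
#' @param rec A conditioned [imu_recording()] (see [condition_recording()]).
#' @param cfg Matching `exercise_config` (defaults to the registry).
#' @return An [event_sequence()]; static tremor tasks return an empty one.
#' @export
segment_recording <- function(rec, cfg = exercise_registry()[[rec$exercise]]) {
  fs <- rec$sample_rate
  th <- cfg$thresholds
  mid_kind <- switch(rec$exercise, THFF = "T_TF", OPCL = "T_OC",
                     PSUP = "T_PS", TTHP = "T_HS", HTTP = "T_TO",
                     HEHE = "T_HE", "T_mid")
  switch(cfg$segmentation_kind,
    tapping_biphasic = {
      omega <- dominant_signal(rec, cfg)
      segment_tapping(omega, start_th = abs(th[[1]]),
                      end_th = -abs(th[[2]]), sample_rate = fs,
                      mid_kind = mid_kind)
    },
    heel_toe = segment_heel_toe(dominant_signal(rec, cfg),
                                th = th[["TH_TO"]], sample_rate = fs),
    gait = segment_gait(dominant_signal(rec, cfg), th_ho = th[["TH_HO"]],
                        th_ff = th[["TH_FF"]], sample_rate = fs),
    rotation = segment_rotation(rec$gyro[, cfg$axis],
                                direction = if (rec$side == "right")
                                  "clockwise" else "anticlockwise",
                                th = th[["TH_RO"]], th_v = th[["TH_ROv"]],
                                sample_rate = fs),
    arm_swing = segment_arm_swing(dominant_signal(rec, cfg),
                                  th_gt = th[["TH_GT"]],
                                  turn_bound = th[["turn_bound"]],
                                  sample_rate = fs),
    static = event_sequence(empty_events(), NULL, "static", fs)
  )
}
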