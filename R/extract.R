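#' Extract all task parameters from one trial
#'
#' Runs the per-trial pipeline: task-specific conditioning, event
#' segmentation, and the task's kinematic or spectral feature set. Feature
#' names are prefixed with the task code (e.g. `TT_Taps`, `PT_Perc2G`) and
#' cover the task's full schema; parameters whose formula is degenerate for
#' the trial (too few cycles) are `NA`, never silently zero.
#'
#' @param rec A raw [imu_recording()].
#' @param cfg Matching `exercise_config` (defaults to the registry entry).
#' @return Named numeric vector over the task's schema, with attribute
#'   `n_cycles`.
#' @export
extract_features <- function(rec, cfg = exercise_registry()[[rec$exercise]]) {
  stopifnot(inherits(rec, "imu_recording"))
  fs <- rec$sample_rate
  ex <- rec$exercise
  n_cycles <- 0L
  # spectral-only tasks filter their own source signals from the raw data
  feats <- if (ex == "HEHE") {
    hehe_features(rec, cfg)
  } else if (cfg$segmentation_kind == "static") {
    tremor_task_features(rec, cfg)
  } else {
    cond <- if (isTRUE(rec$conditioned)) rec
            else condition_recording(rec, cfg, channels = "needed")
    ev <- segment_recording(cond, cfg)
    n_cycles <- if (is.null(ev$cycles)) nrow(ev$events) else nrow(ev$cycles)
    omega <- dominant_signal(cond, cfg)
    switch(cfg$segmentation_kind,
      tapping_biphasic = tapping_features(
        ev, omega, cond$accel, fs,
        velocities = ex %in% c("THFF", "OPCL", "PSUP")),
      heel_toe = heto_features(ev, omega, cond$accel, fs),
      gait = gait_features(ev, omega, cond$accel, fs),
      rotation = rotation_features(ev),
      arm_swing = arm_swing_features(ev, omega, cond$accel, fs))
  }
  schema <- exercise_parameters()[[ex]]
  # pronation-supination prints its phase velocities as ws/wp
  if (ex == "PSUP") {
    names(feats)[names(feats) == "wo"] <- "ws"
    names(feats)[names(feats) == "wc"] <- "wp"
  }
  miss <- setdiff(schema, names(feats))
  if (length(miss))
    stopf("%s features missing from extraction: %s", ex,
          paste(miss, collapse = ", "))
  out <- unlist(feats[schema])
  names(out) <- paste(cfg$prefix, schema, sep = "_")
  attr(out, "n_cycles") <- n_cycles
  out
}

#' Build the subject-level feature table
#'
#' Extracts features for every trial and aggregates to one row per subject:
#' within subject, exercise and side, the two trial values are averaged
#' (a single trial is used as-is); left and right parameters are kept as
#' separate columns because disease onset is typically unilateral. The
#' result has exactly the 174-column schema of [feature_schema()] when all
#' exercises are present.
#'
#' @param recordings List of raw [imu_recording()]s.
#' @param meta Optional data.frame with `subject_id`, `group` columns;
#'   defaults to the `group` carried by the recordings.
#' @return A `feature_table`: list with `features` (subjects x features
#'   matrix) and `label` (factor `HC`/`PD`).
#' @export
build_subject_table <- function(recordings, meta = NULL) {
  reg <- exercise_registry()
  schema <- feature_schema()
  rows <- lapply(recordings, function(rec) {
    f <- extract_features(rec, reg[[rec$exercise]])
    data.frame(subject_id = rec$subject_id,
               name = paste(names(f), rec$side, sep = "_"),
               value = as.numeric(f),
               group = rec$group %||% NA_character_)
  })
  long <- do.call(rbind, rows)
  subjects <- unique(long$subject_id)
  mat <- matrix(NA_real_, nrow = length(subjects), ncol = nrow(schema),
                dimnames = list(subjects, schema$name))
  agg <- aggregate(value ~ subject_id + name, data = long, FUN = mean,
                   na.action = stats::na.pass, na.rm = TRUE)
  agg$value[is.nan(agg$value)] <- NA_real_
  keep <- agg$name %in% schema$name
  mat[cbind(match(agg$subject_id[keep], subjects),
            match(agg$name[keep], schema$name))] <- agg$value[keep]
  if (is.null(meta)) {
    grp <- long$group[match(subjects, long$subject_id)]
  } else {
    grp <- meta$group[match(subjects, meta$subject_id)]
  }
  feature_table(mat, factor(grp, levels = GROUPS))
}

#' Construct a feature table object
#'
#' @param features Numeric matrix, subjects x features, with schema column
#'   names and subject row names.
#' @param label Factor of cohort labels (`HC`/`PD`), one per row.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, label) {
  stopifnot(is.matrix(features), nrow(features) == length(label))
  if (anyDuplicated(colnames(features)))
    stopf("feature names must be unique")
  structure(list(features = features, label = label),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features (%s)\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s: %d", levels(x$label), table(x$label)),
                    collapse = ", ")))
  invisible(x)
}

# columns of a table belonging to an evaluation condition
condition_columns <- function(tab, condition = c("FULL", "FEET", "HANDS")) {
  condition <- match.arg(condition)
  schema <- feature_schema()
  keep <- schema$name[schema$name %in% colnames(tab$features)]
  if (condition != "FULL")
    keep <- intersect(keep, schema$name[schema$condition == condition])
  keep
}
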