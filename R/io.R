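#' Read an inertial recording from disk
#'
#' A recording is stored as a CSV body (`<path>.csv`, columns
#' `t, ax, ay, az, gx, gy, gz`, header required) plus a JSON metadata sidecar
#' (`<path>.json` with `subject_id`, `exercise`, `side`, `trial`,
#' `sample_rate`, `units`, `sensor_unit` and optionally `group`).
#' Acceleration declared in g and angular rate declared in rad/s are
#' converted to the package units (m/s^2, deg/s). Gzipped CSV bodies
#' (`<path>.csv.gz`) are read transparently.
#'
#' @param path Path stem without extension (or the `.csv` path itself).
#' @return A validated [imu_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path) {
  stem <- sub("\\.csv(\\.gz)?$", "", path)
  csv <- if (file.exists(paste0(stem, ".csv"))) paste0(stem, ".csv")
         else paste0(stem, ".csv.gz")
  json <- paste0(stem, ".json")
  if (!file.exists(csv)) stopf("recording body not found: %s", csv)
  if (!file.exists(json)) stopf("metadata sidecar not found: %s", json)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  need <- c("subject_id", "exercise", "side", "trial", "sample_rate")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stopf("sidecar missing fields: %s", paste(miss, collapse = ", "))
  body <- read.csv(csv)
  cols <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  miss <- setdiff(cols, names(body))
  if (length(miss)) stopf("recording CSV missing columns: %s", paste(miss, collapse = ", "))
  accel <- as.matrix(body[, c("ax", "ay", "az")])
  gyro <- as.matrix(body[, c("gx", "gy", "gz")])
  units <- meta$units %||% list(accel = "m/s2", gyro = "deg/s")
  au <- units$accel %||% "m/s2"
  gu <- units$gyro %||% "deg/s"
  if (au == "g") accel <- accel * 9.80665
  else if (!au %in% c("m/s2", "m/s^2")) stopf("unknown acceleration unit: %s", au)
  if (gu == "rad/s") gyro <- gyro * 180 / pi
  else if (gu != "deg/s") stopf("unknown angular-rate unit: %s", gu)
  imu_recording(meta$subject_id, meta$exercise, meta$side, meta$trial,
                accel = accel, gyro = gyro, sample_rate = meta$sample_rate,
                time = body$t, sensor_unit = meta$sensor_unit,
                group = meta$group)
}

#' Write an inertial recording to disk
#'
#' Inverse of [read_recording()]: writes `<path>.csv` and `<path>.json`.
#' Samples round-trip to better than 1e-9 (full double precision is written).
#'
#' @param rec An [imu_recording()].
#' @param path Path stem without extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  stem <- sub("\\.csv(\\.gz)?$", "", path)
  body <- data.frame(t = rec$time,
                     ax = rec$accel[, 1], ay = rec$accel[, 2], az = rec$accel[, 3],
                     gx = rec$gyro[, 1], gy = rec$gyro[, 2], gz = rec$gyro[, 3])
  con <- file(paste0(stem, ".csv"), "w")
  on.exit(close(con))
  writeLines(paste(names(body), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(body, format, digits = 17, trim = TRUE,
                                     scientific = FALSE), sep = ",")), con)
  meta <- list(subject_id = rec$subject_id, exercise = rec$exercise,
               side = rec$side, trial = rec$trial,
               sample_rate = rec$sample_rate,
               units = list(accel = "m/s2", gyro = "deg/s"),
               sensor_unit = rec$sensor_unit)
  if (!is.null(rec$group)) meta$group <- rec$group
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a subject-level feature table
#'
#' CSV with columns `subject_id`, `group`, then one column per feature name
#' of the 174-parameter schema (see [feature_schema()]).
#'
#' @param tab A `feature_table` (see [build_subject_table()]).
#' @param path CSV file path.
#' @return For the writer, `path` invisibly; for the reader, a `feature_table`.
#' @export
write_feature_table <- function(tab, path) {
  df <- cbind(data.frame(subject_id = rownames(tab$features),
                         group = as.character(tab$label)),
              as.data.frame(tab$features))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  feats <- as.matrix(df[, setdiff(names(df), c("subject_id", "group")), drop = FALSE])
  rownames(feats) <- df$subject_id
  feature_table(feats, factor(df$group, levels = GROUPS))
}
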