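#' The 174-parameter feature schema
#'
#' Enumerates every feature the pipeline produces: 39 lower-limb and 48
#' upper-limb parameters per side (87 per side, 174 in total). Column names
#' follow `<PREFIX>_<Param>_<side>` (e.g. `TT_Taps_right`, `PT_Perc2G_left`).
#' The Greek phase-velocity symbols are transliterated (`wo`, `wc`, `ws`,
#' `wp`, `wf`, `wb`).
#'
#' @param sides Which sides to enumerate (default both).
#' @return A data.frame with columns `name`, `exercise`, `prefix`,
#'   `parameter`, `side`, `condition` (`"FEET"` or `"HANDS"`).
#' @examples
#' nrow(feature_schema())                     # 174
#' table(feature_schema()$condition) / 2      # 39 feet + 48 hands per side
#' @export
feature_schema <- function(sides = SIDES) {
  params <- exercise_parameters()
  reg <- exercise_registry()
  rows <- lapply(EXERCISES, function(ex) {
    cfg <- reg[[ex]]
    data.frame(exercise = ex, prefix = cfg$prefix,
               parameter = params[[ex]], condition = cfg$condition)
  })
  base <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(sides, function(s) cbind(base, side = s)))
  out$name <- paste(out$prefix, out$parameter, out$side, sep = "_")
  out[, c("name", "exercise", "prefix", "parameter", "side", "condition")]
}

# Parameter lists per task; order follows the published parameter tables.
exercise_parameters <- function() {
  tap <- c("Taps", "Freq", "Exc", "CVfreq", "CVexc", "IAV")
  hand <- c("Taps", "Freq", "Exc", "wo", "wc", "CVfreq", "CVexc", "IAV")
  list(
    TTHP = tap,
    HTTP = tap,
    HETO = c("Taps", "FreqT", "FreqH", "FreqHT", "ExcT", "ExcH",
             "CVfreq", "CVexcT", "CVexcH", "IAV"),
    HEHE = c("Power", "Peak", "Freq", "IAV"),
    ROTA = c("Time", "Strd", "Freq", "STT", "RS"),
    GTAF = c("Time", "Strd", "Freq", "StrdT", "SWT", "STT", "RS", "Ang"),
    THFF = hand,
    OPCL = hand,
    PSUP = c("Taps", "Freq", "Exc", "ws", "wp", "CVfreq", "CVexc", "IAV"),
    HRST = c("PwrA", "PwrG", "FreqA", "FreqG", "Perc1A", "Perc1G", "IAV"),
    POST = c("PwrA", "PwrG", "FreqA", "FreqG", "Perc1A", "Perc1G",
             "Perc2A", "Perc2G", "IAV"),
    GTAH = c("Taps", "HFreq", "Exc", "wf", "wb", "CVfreq", "CVexc", "IAV")
  )
}
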