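#' Run the full analysis pipeline
#'
#' Extracts the subject-level feature table from a set of recordings (or a
#' directory of recording files), runs feature selection and benchmarks the
#' requested classifiers under 10-fold cross-validation.
#'
#' @param recordings List of [imu_recording()]s, or a directory containing
#'   recording CSV/JSON pairs (see [read_recording()]).
#' @param classifiers Classifiers to benchmark (default all five).
#' @param alpha Significance level of the rank-sum screen.
#' @param rho_cut Spearman pruning cutoff.
#' @param seed Integer seed for fold assignment and classifier randomness.
#' @param k Cross-validation folds.
#' @param rf_exponents Tree-count exponents searched for the random forest.
#' @return List with `table` (feature table), `selection`
#'   (`selection_result`) and `report` (`evaluation_report`).
#' @examples
#' \donttest{
#' cohort <- gen_cohort(cohort_spec(n_hc = 4, n_pd = 4, seed = 7))
#' res <- run_pipeline(cohort$recordings, classifiers = "SVM_L", seed = 7)
#' res$report
#' }
#' @export
run_pipeline <- function(recordings,
                         classifiers = c("RF", "SVM_L", "SVM_G", "SVM_P", "NB"),
                         alpha = 0.05, rho_cut = 0.85, seed = 1, k = 10,
                         rf_exponents = 1:12) {
  if (is.character(recordings) && length(recordings) == 1L) {
    stems <- unique(sub("\\.csv(\\.gz)?$", "",
                        list.files(recordings, pattern = "\\.csv(\\.gz)?$",
                                   full.names = TRUE)))
    recordings <- lapply(stems, read_recording)
  }
  tab <- build_subject_table(recordings)
  sel <- select_features(tab, alpha = alpha, rho_cut = rho_cut)
  rep <- run_benchmark(tab, sel, classifiers = classifiers, k = k,
                       seed = seed, rf_exponents = rf_exponents)
  list(table = tab, selection = sel, report = rep)
}
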