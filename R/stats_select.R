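#' Normality screen (Lilliefors-corrected Kolmogorov-Smirnov)
#'
#' Per-feature normality p-value on the pooled non-missing values, with
#' mean and SD estimated from the data (Lilliefors correction). Recorded to
#' justify the nonparametric group comparison; it does not gate any later
#' step.
#'
#' @param tab A `feature_table`.
#' @return Named numeric vector of p-values (`NA` for degenerate features).
#' @export
normality_screen <- function(tab) {
  vapply(colnames(tab$features), function(nm) {
    x <- tab$features[, nm]
    x <- x[is.finite(x)]
    if (length(x) < 5 || sd(x) == 0) return(NA_real_)
    tryCatch(nortest::lillie.test(x)$p.value, error = function(e) NA_real_)
  }, numeric(1))
}

#' Wilcoxon rank-sum screen of every feature
#'
#' Two-sided rank-sum test of HC versus PD per feature; exact for group
#' sizes up to 10, normal approximation with continuity and tie correction
#' otherwise. Features missing in more than half of either group are
#' excluded from screening (flagged, not silently dropped).
#'
#' @param tab A `feature_table`.
#' @param alpha Significance level (default 0.05).
#' @return A data.frame (`feature_screen`) with columns `name`, `condition`,
#'   `side`, `p_value`, `significant`, `excluded`, `normality_p`.
#' @export
ranksum_screen <- function(tab, alpha = 0.05) {
  stopifnot(nlevels(droplevels(tab$label)) == 2)
  schema <- feature_schema()
  norm_p <- normality_screen(tab)
  hc <- tab$label == "HC"; pd <- tab$label == "PD"
  res <- lapply(colnames(tab$features), function(nm) {
    x <- tab$features[hc, nm]; y <- tab$features[pd, nm]
    miss_x <- mean(!is.finite(x)); miss_y <- mean(!is.finite(y))
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    excluded <- miss_x > 0.5 || miss_y > 0.5 || length(x) < 2 || length(y) < 2
    p <- NA_real_
    if (!excluded) {
      exact <- min(length(x), length(y)) <= 10
      p <- suppressWarnings(
        wilcox.test(x, y, alternative = "two.sided", exact = exact,
                    correct = TRUE)$p.value)
    }
    i <- match(nm, schema$name)
    data.frame(name = nm,
               condition = if (is.na(i)) NA_character_ else schema$condition[i],
               side = if (is.na(i)) NA_character_ else schema$side[i],
               p_value = p,
               significant = isTRUE(p < alpha),
               excluded = excluded,
               normality_p = unname(norm_p[nm]))
  })
  out <- do.call(rbind, res)
  class(out) <- c("feature_screen", "data.frame")
  out
}

#' Bonferroni correction over each limb panel
#'
#' Adds `significant_bonferroni = (p < alpha / m)`. The correction family
#' is each feature's limb panel — by default `m` is the number of screened
#' lower-limb features (78 when complete) for FEET parameters and of
#' upper-limb features (96) for HANDS parameters — so that the FULL
#' condition is the union of the two panels.
#'
#' @param screens Result of [ranksum_screen()].
#' @param alpha Family-wise error level (default 0.05).
#' @param m Optional named vector `c(FEET =, HANDS =)` overriding the
#'   family sizes.
#' @return The screens with `significant_bonferroni` and `m` columns added.
#' @export
bonferroni_correct <- function(screens, alpha = 0.05, m = NULL) {
  if (is.null(m)) {
    tested <- !screens$excluded
    m <- c(FEET = sum(tested & screens$condition == "FEET"),
           HANDS = sum(tested & screens$condition == "HANDS"))
  }
  screens$m <- unname(m[screens$condition])
  screens$significant_bonferroni <-
    screens$significant & screens$p_value < alpha / screens$m
  screens
}

#' Greedy Spearman correlation pruning
#'
#' Candidates are visited in ascending rank-sum p (lexicographic name
#' tie-break); a feature is kept iff its absolute Spearman rho with every
#' already-kept feature is below `rho_cut`, or the correlation is not
#' significant (p >= `alpha`). When two features are strongly correlated
#' only the most significant one survives.
#'
#' @param tab A `feature_table`.
#' @param candidates Candidate feature names (subset of columns).
#' @param screens [ranksum_screen()] output supplying the ordering p-values.
#' @param rho_cut Correlation cutoff (default 0.85).
#' @param alpha Correlation-significance level (default 0.05).
#' @return Character vector of kept feature names.
#' @export
spearman_prune <- function(tab, candidates, screens, rho_cut = 0.85,
                           alpha = 0.05) {
  if (!length(candidates)) return(character(0))
  p <- screens$p_value[match(candidates, screens$name)]
  ord <- order(p, candidates)
  candidates <- candidates[ord]
  kept <- character(0)
  for (nm in candidates) {
    x <- tab$features[, nm]
    ok <- TRUE
    for (k in kept) {
      y <- tab$features[, k]
      use <- is.finite(x) & is.finite(y)
      if (sum(use) < 3) next
      ct <- suppressWarnings(
        cor.test(x[use], y[use], method = "spearman", exact = FALSE))
      if (is.finite(ct$estimate) && abs(ct$estimate) >= rho_cut &&
          is.finite(ct$p.value) && ct$p.value < alpha) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, nm)
  }
  kept
}

#' Assemble the four feature datasets per evaluation condition
#'
#' `PS`: rank-sum significant features; `PS_B`: additionally Bonferroni
#' significant; `PC` / `PC_B`: the corresponding sets after Spearman
#' pruning, run separately within each limb-and-side panel. Each dataset is
#' materialised for the FEET, HANDS and FULL conditions (FULL is the union
#' of the limb panels), so `PS_B` is nested in `PS`, `PC` in `PS` and
#' `PC_B` in `PS_B`.
#'
#' @param tab A `feature_table`.
#' @param screens Output of [bonferroni_correct()].
#' @param rho_cut Spearman cutoff (default 0.85).
#' @param alpha Correlation-significance level (default 0.05).
#' @return A `selection_result`: list with `screens` and `datasets`
#'   (`datasets[[dataset]][[condition]]` is a character vector).
#' @export
assemble_datasets <- function(tab, screens, rho_cut = 0.85, alpha = 0.05) {
  schema <- feature_schema()
  panel <- function(cond, side) schema$name[schema$condition == cond &
                                            schema$side == side]
  sig <- screens$name[screens$significant & !screens$excluded]
  sig_b <- screens$name[screens$significant_bonferroni & !screens$excluded]
  prune_union <- function(cands) {
    kept <- character(0)
    for (cond in c("FEET", "HANDS")) for (sd in SIDES) {
      fam <- intersect(cands, panel(cond, sd))
      kept <- c(kept, spearman_prune(tab, fam, screens, rho_cut, alpha))
    }
    kept
  }
  pc <- prune_union(sig)
  pc_b <- prune_union(sig_b)
  per_condition <- function(feats) {
    list(FEET = intersect(feats, schema$name[schema$condition == "FEET"]),
         HANDS = intersect(feats, schema$name[schema$condition == "HANDS"]),
         FULL = feats)
  }
  datasets <- list(PS = per_condition(sig), PS_B = per_condition(sig_b),
                   PC = per_condition(pc), PC_B = per_condition(pc_b))
  for (ds in names(datasets))
    if (!length(datasets[[ds]]$FULL))
      warning(sprintf("dataset %s is empty", ds), call. = FALSE)
  structure(list(screens = screens, datasets = datasets,
                 kept_after_correlation = pc,
                 kept_after_correlation_bonferroni = pc_b),
            class = "selection_result")
}

#' Run the full feature-selection stage
#'
#' Rank-sum screening, Bonferroni correction and Spearman pruning in one
#' call.
#'
#' @param tab A `feature_table`.
#' @param alpha Significance level (default 0.05).
#' @param rho_cut Spearman cutoff (default 0.85).
#' @param m Optional Bonferroni family sizes, see [bonferroni_correct()].
#' @return A `selection_result`.
#' @export
select_features <- function(tab, alpha = 0.05, rho_cut = 0.85, m = NULL) {
  screens <- ranksum_screen(tab, alpha)
  screens <- bonferroni_correct(screens, alpha, m)
  assemble_datasets(tab, screens, rho_cut, alpha)
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n")
  for (ds in names(x$datasets)) {
    n <- vapply(x$datasets[[ds]], length, integer(1))
    cat(sprintf("  %-5s FEET %3d  HANDS %3d  FULL %3d\n",
                ds, n[["FEET"]], n[["HANDS"]], n[["FULL"]]))
  }
  invisible(x)
}
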