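make_table <- function(mat, groups) {
  colnames(mat) <- feature_schema()$name[seq_len(ncol(mat))]
  rownames(mat) <- sprintf("s%02d", seq_len(nrow(mat)))
  feature_table(mat, factor(groups, levels = c("HC", "PD")))
}

test_that("subject values average the two trials", {
  prof <- clean_profile(rate = 2, amp = 100)
  prof2 <- clean_profile(rate = 2.5, amp = 100)
  r1 <- gen_tapping(prof, "THFF", "right", trial = 1, subject_id = "a",
                    group = "HC", seed = 1)
  r2 <- gen_tapping(prof2, "THFF", "right", trial = 2, subject_id = "a",
                    group = "HC", seed = 2)
  f1 <- extract_features(r1); f2 <- extract_features(r2)
  tab <- build_subject_table(list(r1, r2))
  expect_equal(unname(tab$features["a", "TF_Freq_right"]),
               mean(c(f1[["TF_Freq"]], f2[["TF_Freq"]])))
  # a single trial is used as-is
  tab1 <- build_subject_table(list(r1))
  expect_equal(unname(tab1$features["a", "TF_Taps_right"]),
               unname(f1[["TF_Taps"]]))
})

test_that("the rank-sum screen matches the exhaustive permutation oracle", {
  n <- 6
  mat <- matrix(0, n, 2)
  mat[, 1] <- c(1, 2, 3, 10, 11, 12)
  mat[, 2] <- c(5, 1, 4, 2, 6, 3)
  tab <- make_table(mat, rep(c("HC", "PD"), each = 3))
  sc <- ranksum_screen(tab)
  expect_equal(sc$p_value[1], 0.1, tolerance = 1e-12)
  expect_equal(sc$p_value[1],
               oracle_ranksum_p(c(1, 2, 3), c(10, 11, 12)),
               tolerance = 1e-12)
  expect_false(sc$significant[1])

  # identical groups give p = 1
  mat2 <- matrix(rep(c(1, 2, 3, 4), 2), 8, 2)
  tab2 <- make_table(mat2, rep(c("HC", "PD"), each = 4))
  expect_equal(ranksum_screen(tab2)$p_value[1], 1)

  # strongly separated cohorts at n = 40 + 40 are overwhelmingly significant
  set.seed(3)
  mat3 <- cbind(c(rnorm(40), rnorm(40, 5)), rnorm(80))
  tab3 <- make_table(mat3, rep(c("HC", "PD"), each = 40))
  sc3 <- ranksum_screen(tab3)
  expect_lt(sc3$p_value[1], 1e-6)
  expect_gt(sc3$p_value[2], 0.001)
})

test_that("normality screening flags skewed features and not normal ones", {
  set.seed(8)
  mat <- cbind(exp(rnorm(80, sd = 1.5)), rnorm(80))
  tab <- make_table(mat, rep(c("HC", "PD"), each = 40))
  np <- normality_screen(tab)
  expect_lt(np[[1]], 0.05)
  # constant feature is degenerate
  matc <- cbind(mat, 1)[, c(1, 2, 3)]
  matc[, 3] <- 1
  expect_true(is.na(normality_screen(make_table(matc,
    rep(c("HC", "PD"), each = 40)))[[3]]))
})

test_that("Bonferroni thresholds use the limb-panel family size", {
  set.seed(2)
  sch <- feature_schema()
  mat <- matrix(rnorm(20 * 174), 20, 174)
  tab <- make_table(mat, rep(c("HC", "PD"), each = 10))
  sc <- bonferroni_correct(ranksum_screen(tab))
  expect_equal(unique(sc$m[sc$condition == "FEET"]), 78)
  expect_equal(unique(sc$m[sc$condition == "HANDS"]), 96)
  expect_true(all(sc$significant_bonferroni ==
                    (sc$significant & sc$p_value < 0.05 / sc$m)))
  # alpha 0.05, m 78 -> threshold ~6.41e-4
  expect_equal(0.05 / 78, 6.41e-4, tolerance = 1e-3)
  # m = 1 reduces to the uncorrected flags
  sc1 <- bonferroni_correct(ranksum_screen(tab), m = c(FEET = 1, HANDS = 1))
  expect_equal(sc1$significant_bonferroni, sc1$significant)
})

test_that("correlation pruning keeps the most significant of a clique", {
  set.seed(5)
  n <- 80
  a <- rnorm(n)
  mat <- cbind(a + c(rnorm(40, 1), rnorm(40, 2.5)),  # A: informative
               NA, rnorm(n))                          # C: independent
  mat[, 2] <- mat[, 1]                                # B identical to A
  tab <- make_table(mat, rep(c("HC", "PD"), each = 40))
  sc <- ranksum_screen(tab)
  kept <- spearman_prune(tab, colnames(tab$features), sc)
  nm <- colnames(tab$features)
  expect_length(kept, 2)
  expect_true(nm[3] %in% kept)
  expect_true(sum(nm[1:2] %in% kept) == 1)
  # the survivor of the A/B pair is the lexicographic tie-break (equal p)
  expect_equal(sort(c(kept)), sort(c(min(nm[1:2]), nm[3])))

  # mutually independent noise columns all survive
  set.seed(6)
  matn <- matrix(rnorm(80 * 8), 80, 8)
  tabn <- make_table(matn, rep(c("HC", "PD"), each = 40))
  keptn <- spearman_prune(tabn, colnames(tabn$features),
                          ranksum_screen(tabn))
  expect_length(keptn, 8)
})

test_that("pruning soundness: kept features are pairwise below the cutoff", {
  set.seed(12)
  n <- 60
  base <- matrix(rnorm(n * 4), n, 4)
  mat <- cbind(base,
               base[, 1] + rnorm(n, sd = 0.05),
               base[, 2] + rnorm(n, sd = 0.05),
               base[, 3] * 2 + rnorm(n, sd = 0.1))
  tab <- make_table(mat, rep(c("HC", "PD"), each = 30))
  sc <- ranksum_screen(tab)
  kept <- spearman_prune(tab, colnames(tab$features), sc)
  rho <- cor(tab$features[, kept], method = "spearman")
  expect_true(all(abs(rho[upper.tri(rho)]) < 0.85))
  # every dropped feature correlates >= 0.85 with some kept feature
  dropped <- setdiff(colnames(tab$features), kept)
  for (d in dropped) {
    r <- abs(cor(tab$features[, d], tab$features[, kept],
                 method = "spearman"))
    expect_gte(max(r), 0.85)
  }
})

test_that("dataset assembly nests PS_B in PS and prunes per panel", {
  set.seed(21)
  sch <- feature_schema()
  mat <- matrix(rnorm(40 * 174), 40, 174)
  # inject group separation of varying strength into a third of the features
  idx <- seq(1, 174, by = 3)
  shift <- rep(c(0.8, 1.5, 3), length.out = length(idx))
  for (k in seq_along(idx))
    mat[21:40, idx[k]] <- mat[21:40, idx[k]] + shift[k]
  tab <- make_table(mat, rep(c("HC", "PD"), each = 20))
  sel <- select_features(tab)
  ds <- sel$datasets
  for (cond in c("FEET", "HANDS", "FULL")) {
    expect_true(all(ds$PS_B[[cond]] %in% ds$PS[[cond]]))
    expect_true(all(ds$PC[[cond]] %in% ds$PS[[cond]]))
    expect_true(all(ds$PC_B[[cond]] %in% ds$PS_B[[cond]]))
  }
  for (d in names(ds))
    expect_setequal(ds[[d]]$FULL, c(ds[[d]]$FEET, ds[[d]]$HANDS))
  # no significant features -> empty datasets with warnings
  tab0 <- make_table(matrix(rep(seq_len(40), 4), 40, 4),
                     rep(c("HC", "PD"), 20))
  w <- capture_warnings(sel0 <- select_features(tab0))
  expect_true(any(grepl("empty", w)))
  expect_length(sel0$datasets$PS$FULL, 0)
})

test_that("features missing in most of a group are excluded, not tested", {
  set.seed(31)
  mat <- cbind(rnorm(20), rnorm(20))
  mat[1:8, 1] <- NA   # 80% of HC missing
  tab <- make_table(mat, rep(c("HC", "PD"), each = 10))
  sc <- ranksum_screen(tab)
  expect_true(sc$excluded[1])
  expect_true(is.na(sc$p_value[1]))
  expect_false(sc$excluded[2])
})
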