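test_that("ROC AUC matches hand-worked and degenerate cases", {
  expect_equal(roc_auc(c(-10, -9, -1, -2), c(TRUE, TRUE, FALSE, FALSE)), 100)
  expect_equal(roc_auc(rep(1, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)), 50)
  # 3 concordant pairs of 4
  expect_equal(roc_auc(c(-3, -1, -2, 0), c(TRUE, TRUE, FALSE, FALSE)), 75)
  # higher-is-better orientation
  expect_equal(roc_auc(c(5, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
                       lower_is_better = FALSE), 100)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "at least one")
})

test_that("ROC AUC equals the brute-force pair-concordance oracle", {
  set.seed(123)
  for (trial in 1:120) {
    n <- sample(5:60, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels)) labels[1] <- TRUE
    if (all(labels)) labels[1] <- FALSE
    scores <- if (trial %% 3 == 0) {
      sample(seq(-5, 5), n, replace = TRUE)  # heavy ties
    } else rnorm(n)
    expect_equal(roc_auc(scores, labels), auc_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("ROC curves step correctly and integrate to the AUC", {
  perfect <- roc_curve(c(-10, -9, -1, -2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect, data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1)))
  tied <- roc_curve(rep(0, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(tied, data.frame(fpr = c(0, 1), tpr = c(0, 1)))
  mixed <- roc_curve(c(-3, -1, -2, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(trapz_area(mixed), 0.75)
  expect_true(all(diff(mixed$fpr) >= 0) && all(diff(mixed$tpr) >= 0))
  set.seed(99)
  for (trial in 1:50) {
    n <- sample(4:80, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    curve <- roc_curve(scores, labels)
    expect_equal(curve$fpr[1], 0); expect_equal(curve$tpr[1], 0)
    expect_equal(curve$fpr[nrow(curve)], 1)
    expect_equal(curve$tpr[nrow(curve)], 1)
    expect_equal(100 * trapz_area(curve), roc_auc(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("label inversion and monotone transforms behave as proven", {
  set.seed(11)
  for (trial in 1:30) {
    n <- 40
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- rnorm(n)
    auc <- roc_auc(scores, labels)
    expect_equal(roc_auc(scores, !labels), 100 - auc, tolerance = 1e-12)
    mono <- 3 * scores + 7
    expect_equal(roc_auc(mono, labels), auc, tolerance = 1e-12)
    mono2 <- exp(scores)  # strictly increasing
    expect_equal(roc_auc(mono2, labels), auc, tolerance = 1e-12)
    expect_equal(enrichment_factor(mono, labels, 0.1),
                 enrichment_factor(scores, labels, 0.1))
  }
})

test_that("enrichment factors match direct counting", {
  scores <- c(rep(-1, 10), rep(1, 90))
  labels <- c(rep(TRUE, 10), rep(FALSE, 90))
  expect_equal(enrichment_factor(scores, labels, 0.1), 10)
  # zero actives in the top slice
  expect_equal(enrichment_factor(scores, !labels, 0.05), 0)
  # random scores have EF about 1 in expectation
  set.seed(17)
  efs <- replicate(300, {
    s <- rnorm(100)
    enrichment_factor(s, labels, 0.2)
  })
  expect_lt(abs(mean(efs) - 1), 0.15)
  expect_error(enrichment_factor(scores, labels, 0), "top_fraction")
})

test_that("activity cliffs report similar potent/weak pairs only", {
  comp <- data.frame(
    compound_id = c("iso_a", "iso_b", "far", "mild"),
    chemotype = "BMS")
  acts <- data.frame(
    compound_id = c("iso_a", "iso_b", "far", "mild"),
    receptor = "hCCR2", site = "orthosteric", measure = "IC50",
    value_M = 10^-c(9, 7, 4, 8.5), pactivity = c(9, 7, 4, 8.5))
  fps <- list(iso_a = 1:10, iso_b = 1:10,        # 2D-identical stereoisomers
              far = 200:210,                     # dissimilar, huge delta
              mild = c(1:9, 30L))                # similar, small delta vs iso_a
  lib <- screening_library(comp, acts, fps, thresholds = c(BMS = 7.5))
  cliffs <- find_activity_cliffs(lib, "hCCR2", "orthosteric")
  expect_equal(nrow(cliffs), 1L)
  expect_setequal(c(cliffs$compound_a, cliffs$compound_b), c("iso_a", "iso_b"))
  expect_equal(cliffs$similarity, 1)
  expect_equal(cliffs$delta_pactivity, 2)  # the ~100-fold cliff
  # lowering both floors admits more pairs, sorted by delta descending
  all_pairs <- find_activity_cliffs(lib, "hCCR2", "orthosteric",
                                    min_similarity = 0, min_delta = 0)
  expect_true(all(diff(all_pairs$delta_pactivity) <= 0))
})

test_that("atom attribution sums are verified within tolerance", {
  expect_true(verify_atom_attribution(c(-1.0, -2.5), -3.5)$pass)
  bad <- verify_atom_attribution(c(-1.0), -3.5, tolerance = 0.01)
  expect_false(bad$pass)
  expect_equal(bad$discrepancy, 2.5)
  expect_true(verify_atom_attribution(numeric(), 0)$pass)
})

test_that("screen evaluation bundles ROC, AUC and enrichment consistently", {
  scores <- setNames(c(-9, -8, -2, -1), c("a1", "a2", "d1", "d2"))
  labels <- setNames(c(TRUE, TRUE, FALSE, FALSE), names(scores))
  ev <- evaluate_screen(scores, labels, top_fractions = 0.5)
  expect_s3_class(ev, "screen_evaluation")
  expect_equal(ev$auc, 100)
  expect_equal(unname(ev$enrichment), 2)
  expect_equal(ev$n_actives, 2)
  expect_equal(100 * trapz_area(ev$roc), ev$auc, tolerance = 1e-9)
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (trial in 1:20) {
    n <- 60
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- rnorm(n)
    ours <- roc_auc(scores, labels)
    ref <- 100 * as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, direction = ">",
      quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})
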