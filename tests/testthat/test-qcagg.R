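pred_row <- function(probs, patch_id = "p1", case_id = "c1",
                     true_class = "DLBCL", classes = TRAINING_CLASSES) {
  df <- data.frame(patch_id = patch_id, case_id = case_id,
                   true_class = true_class)
  for (i in seq_along(classes)) df[[paste0("p_", classes[i])]] <- probs[i]
  df
}

test_that("probability aggregation sums tumor-free origins and preserves mass", {
  rec <- pred_row(c(0.2, 0.3, 0.2, 0.2, 0.1), true_class = "LN_LUNG")
  agg <- aggregate_probs(rec)
  expect_equal(agg$p_SLL_CLL, 0.2)
  expect_equal(agg$p_DLBCL, 0.3)
  expect_equal(agg$p_TUMOR_FREE_LN, 0.5)
  expect_equal(agg$true_class, "TUMOR_FREE_LN")
  # identity map leaves vectors unchanged
  idmap <- default_class_map(TRAINING_CLASSES, eval_of = character(0))
  agg_id <- aggregate_probs(rec, idmap)
  expect_equal(as.numeric(agg_id[paste0("p_", TRAINING_CLASSES)]),
               c(0.2, 0.3, 0.2, 0.2, 0.1))
  expect_error(aggregate_probs(rec, c(SLL_CLL = "SLL_CLL")), "cover")
})

test_that("aggregation keeps 1000 random simplex vectors normalized", {
  withr::with_seed(13, {
    g <- matrix(rgamma(1000 * 5, 0.4), 1000, 5)
    P <- g / rowSums(g)
  })
  recs <- data.frame(patch_id = sprintf("p%04d", 1:1000), case_id = "c",
                     true_class = "SLL_CLL")
  for (i in 1:5) recs[[paste0("p_", TRAINING_CLASSES[i])]] <- P[, i]
  agg <- aggregate_probs(recs)
  sums <- rowSums(as.matrix(agg[, paste0("p_", EVAL_CLASSES)]))
  expect_lt(max(abs(sums - 1)), 1e-9)
  # componentwise re-addition oracle
  expect_equal(agg$p_TUMOR_FREE_LN, P[, 3] + P[, 4] + P[, 5])
})

test_that("patch-level QC drops patches strictly below the threshold", {
  classes <- c("A", "B", "C")
  recs <- rbind(
    pred_row(c(0.34, 0.33, 0.33), "p1", classes = classes),
    pred_row(c(0.60, 0.20, 0.20), "p2", classes = classes),
    pred_row(c(0.45, 0.30, 0.25), "p3", classes = classes))
  out <- apply_pqc(recs, 0.5, classes)
  expect_equal(out$records$patch_id, "p2")
  expect_equal(out$pqc_not_met_pct, 200 / 3)
  all_in <- apply_pqc(recs, 0, classes)
  expect_equal(nrow(all_in$records), 3)
  expect_equal(all_in$pqc_not_met_pct, 0)
  # boundary: exactly at threshold survives
  at <- apply_pqc(pred_row(c(0.5, 0.25, 0.25), classes = classes), 0.5,
                  classes)
  expect_equal(nrow(at$records), 1)
  expect_error(apply_pqc(recs, 1.2, classes), "\\[0, 1\\]")
})

test_that("PQC survivor counts match a linear-scan oracle on a large fixture", {
  fx <- generate_prediction_fixture(
    fixture_manifest(100), 100,
    prediction_fixture_config(patch_accuracy = 0.8, seed = 7))
  agg <- aggregate_probs(fx)
  out <- apply_pqc(agg, 0.9)
  want <- 0L
  P <- as.matrix(agg[, paste0("p_", EVAL_CLASSES)])
  for (i in seq_len(nrow(P))) if (max(P[i, ]) >= 0.9) want <- want + 1L
  expect_equal(nrow(out$records), want)
  expect_equal(out$pqc_not_met_pct, 100 * (nrow(P) - want) / nrow(P))
})

test_that("case voting follows majority, strict CQC and the stated tie-breaks", {
  classes <- c("A", "B")
  recs <- rbind(
    pred_row(c(0.9, 0.1), "p1", "case1", "A", classes),
    pred_row(c(0.8, 0.2), "p2", "case1", "A", classes),
    pred_row(c(0.3, 0.7), "p3", "case1", "A", classes))
  v <- vote_case(recs, 0.5, classes)
  expect_equal(v$predicted_class, "A")
  expect_equal(v$vote_fraction, 2 / 3)
  expect_equal(v$n_surviving, 3L)
  # strictly below the threshold abstains
  v2 <- vote_case(recs, 0.7, classes)
  expect_equal(v2$predicted_class, "UNCLASSIFIED")
  # modal tie broken by summed probability
  tie <- rbind(
    pred_row(c(0.55, 0.45), "p1", "case2", "A", classes),
    pred_row(c(0.50, 0.50), "p2", "case2", "A", classes))  # argmax A (first)
  tie2 <- rbind(
    pred_row(c(0.60, 0.40), "p1", "case3", "A", classes),
    pred_row(c(0.45, 0.55), "p2", "case3", "A", classes))
  v3 <- vote_case(tie2, 0.5, classes)   # votes 1:1, sums A 1.05 vs B 0.95
  expect_equal(v3$predicted_class, "A")
  expect_error(vote_case(rbind(recs, pred_row(c(1, 0), "px", "other", "A",
                                              classes)), 0.5, classes),
               "multiple cases")
})

test_that("balanced accuracy is the mean per-class recall over classified items", {
  # perfect predictions
  cb <- confusion_and_bacc(rep(c("A", "B", "C"), c(5, 2, 9)),
                           rep(c("A", "B", "C"), c(5, 2, 9)),
                           c("A", "B", "C"))
  expect_equal(cb$bacc, 1.0)
  # constructed recalls 1.0, 0.8, 0.9
  true <- c(rep("A", 10), rep("B", 10), rep("C", 10))
  pred <- c(rep("A", 10), rep("B", 8), "A", "A", rep("C", 9), "B")
  cb2 <- confusion_and_bacc(true, pred, c("A", "B", "C"))
  expect_equal(unname(cb2$recalls), c(1.0, 0.8, 0.9))
  expect_equal(cb2$bacc, 0.9)
  # constant classifier on a balanced 3-class problem
  cb3 <- confusion_and_bacc(rep(c("A", "B", "C"), 10), rep("A", 30),
                            c("A", "B", "C"))
  expect_equal(cb3$bacc, 1 / 3)
  # UNCLASSIFIED rows are excluded; absent classes are dropped with warning
  expect_warning(
    cb4 <- confusion_and_bacc(c("A", "A", "B"),
                              c("A", "UNCLASSIFIED", "UNCLASSIFIED"),
                              c("A", "B")),
    "dropped")
  expect_equal(cb4$bacc, 1.0)
  expect_equal(cb4$n_classified, 1L)
  # nothing classified: flagged empty result, not an error
  cb5 <- confusion_and_bacc("A", "UNCLASSIFIED", c("A", "B"))
  expect_true(is.na(cb5$bacc))
  expect_equal(cb5$n_classified, 0L)
})

test_that("BACC on fixture-driven decisions matches a per-class tally oracle", {
  fx <- generate_prediction_fixture(
    fixture_manifest(60), c(10, 30),
    prediction_fixture_config(patch_accuracy = 0.75, seed = 11))
  agg <- aggregate_probs(fx)
  classes <- attr(agg, "classes")
  votes <- do.call(rbind, lapply(split(agg, agg$case_id), vote_case,
                                 cqc_threshold = 0.5, classes = classes))
  cb <- confusion_and_bacc(votes$true_class, votes$predicted_class, classes)
  # oracle: group by true class, tally
  keep <- votes$predicted_class != "UNCLASSIFIED"
  recs <- c()
  for (cl in classes) {
    idx <- keep & votes$true_class == cl
    if (any(idx)) recs <- c(recs, mean(votes$predicted_class[idx] == cl))
  }
  expect_equal(cb$bacc, mean(recs))
})

test_that("qc_grid composes its parts and matches the nested-loop oracle", {
  classes <- c("A", "B")
  idmap <- c(A = "A", B = "B")
  recs <- rbind(
    pred_row(c(0.9, 0.1), "p1", "case1", "A", classes),
    pred_row(c(0.8, 0.2), "p2", "case1", "A", classes),
    pred_row(c(0.3, 0.7), "p3", "case1", "A", classes))
  g <- qc_grid(recs, 0, 0.5, map = idmap)
  expect_equal(g$bacc_pct, 100)
  expect_equal(g$pqc_not_met_pct, 0)
  expect_equal(g$cqc_not_met_pct, 0)
  # full-grid oracle equivalence on a random fixture
  fx <- generate_prediction_fixture(
    fixture_manifest(40), c(10, 40),
    prediction_fixture_config(patch_accuracy = 0.8,
                              confidence_correct_boost = 2, seed = 11))
  map <- default_class_map()
  got <- suppressWarnings(qc_grid(fx, map = map))
  want <- oracle_qc_grid(fx, seq(0.5, 0.9, 0.1), seq(0.5, 0.9, 0.1), map)
  expect_equal(got$bacc_pct, want$bacc_pct)
  expect_equal(got$pqc_not_met_pct, want$pqc_not_met_pct)
  expect_equal(got$cqc_not_met_pct, want$cqc_not_met_pct)
})

test_that("rejection percentages are monotone in their thresholds", {
  fx <- generate_prediction_fixture(
    fixture_manifest(50), c(10, 30),
    prediction_fixture_config(patch_accuracy = 0.7, seed = 23))
  g <- suppressWarnings(
    qc_grid(fx, seq(0, 0.9, 0.15), seq(0, 0.9, 0.15)))
  for (q in unique(g$cqc)) {
    sub <- g[g$cqc == q, ]
    expect_true(all(diff(sub[order(sub$pqc), "pqc_not_met_pct"]) >= 0))
  }
  for (p in unique(g$pqc)) {
    sub <- g[g$pqc == p, ]
    expect_true(all(diff(sub[order(sub$cqc), "cqc_not_met_pct"]) >= 0))
  }
})

test_that("with both thresholds zero the grid is plain majority voting", {
  fx <- generate_prediction_fixture(
    fixture_manifest(30), c(5, 15),
    prediction_fixture_config(patch_accuracy = 0.8, seed = 31))
  g <- qc_grid(fx, 0, 0)
  expect_equal(g$pqc_not_met_pct, 0)
  expect_equal(g$cqc_not_met_pct, 0)
  agg <- aggregate_probs(fx)
  classes <- attr(agg, "classes")
  votes <- do.call(rbind, lapply(split(agg, agg$case_id), vote_case,
                                 cqc_threshold = 0, classes = classes))
  cb <- confusion_and_bacc(votes$true_class, votes$predicted_class, classes)
  expect_equal(g$bacc_pct, 100 * cb$bacc)
})

test_that("raising CQC improves BACC on confidence-correlated fixtures", {
  # qualitative trend: stricter case QC trades coverage for accuracy
  violations <- 0L
  for (s in 1:5) {
    fx <- generate_prediction_fixture(
      fixture_manifest(100), c(10, 40),
      prediction_fixture_config(patch_accuracy = 0.72,
                                confidence_correct_boost = 2, seed = s))
    g <- suppressWarnings(qc_grid(fx, 0.5, c(0.5, 0.9)))
    b_lo <- g$bacc_pct[g$cqc == 0.5]
    b_hi <- g$bacc_pct[g$cqc == 0.9]
    if (!(b_hi >= b_lo)) violations <- violations + 1L
    expect_gte(g$cqc_not_met_pct[g$cqc == 0.9],
               g$cqc_not_met_pct[g$cqc == 0.5])
  }
  expect_lte(violations, 1L)
})

test_that("case-level voting beats patch-level accuracy on informative fixtures", {
  violations <- 0L
  for (s in 1:5) {
    fx <- generate_prediction_fixture(
      fixture_manifest(60), c(20, 40),
      prediction_fixture_config(patch_accuracy = 0.8, seed = 100 + s))
    agg <- aggregate_probs(fx)
    classes <- attr(agg, "classes")
    pm <- as.matrix(agg[, paste0("p_", classes)])
    patch_pred <- classes[max.col(pm, ties.method = "first")]
    patch_b <- confusion_and_bacc(agg$true_class, patch_pred, classes)$bacc
    votes <- do.call(rbind, lapply(split(agg, agg$case_id), vote_case,
                                   cqc_threshold = 0, classes = classes))
    case_b <- confusion_and_bacc(votes$true_class, votes$predicted_class,
                                 classes)$bacc
    if (!(case_b >= patch_b)) violations <- violations + 1L
  }
  expect_lte(violations, 1L)
})
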