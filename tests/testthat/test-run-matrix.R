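# A normalized-feature-shaped table built directly (no signal synthesis):
# fast scaffolding for the experiment-matrix contracts.
mock_feature_table <- function(n_participants = 6, informative = TRUE,
                               seed = 1) {
  set.seed(seed)
  n <- n_participants * 32
  fs <- feature_sets()
  feats <- data.frame(
    participant = rep(seq_len(n_participants), each = 32),
    session = rep(rep(1:4, each = 8), n_participants),
    segment = rep(1:8, n_participants * 4),
    role = "scenario",
    phone = rep(c(0, 1), n / 2),
    town = rep(rep(c(0, 1), each = 4), n / 8),
    snowy = rep(rep(c(0, 1), each = 2), n / 4))
  feats$drowsy <- rep(rep(c(1, 0, 0, 1), each = 8), n_participants)
  for (f in unlist(fs)) feats[[f]] <- runif(n)
  ses <- interaction(feats$participant, feats$session)
  for (f in fs$characteristics)
    feats[[f]] <- stats::ave(rnorm(n), ses)        # session-constant
  if (informative) {
    feats$rr_mean <- 0.3 * feats$rr_mean + 0.7 * feats$phone
    feats$lane_number_std <- 0.3 * feats$lane_number_std + 0.7 * feats$town
    feats$slip_rear_std <- 0.3 * feats$slip_rear_std + 0.7 * feats$snowy
    feats$staq_negative_affect <- feats$staq_negative_affect +
      2 * stats::ave(feats$drowsy, ses)
  }
  feats
}

small_menu <- function() default_classifier_menu()[c("logistic", "svm_linear")]

test_that("the experiment matrix covers 4 causes x 7 combinations", {
  feats <- mock_feature_table(4)
  res <- run_matrix(feats, menu = small_menu())
  expect_length(res$cells, 28)
  at <- accuracy_table(res)
  expect_equal(dim(at), c(7, 4))
  expect_setequal(colnames(at), hds_causes())
})

test_that("session-constant features alone cannot classify within-session causes", {
  feats <- mock_feature_table(6)
  res <- run_matrix(feats, menu = small_menu(),
                    combos = feature_set_combinations()["characteristics"])
  at <- accuracy_table(res)
  expect_true(is.na(at["characteristics", "phone"]))
  expect_true(is.na(at["characteristics", "town"]))
  expect_true(is.na(at["characteristics", "snowy"]))
  expect_false(is.na(at["characteristics", "drowsy"]))
})

test_that("informative features drive their designated cells to high accuracy", {
  feats <- mock_feature_table(6)
  res <- run_matrix(feats, menu = small_menu(),
                    causes = c("phone", "town"),
                    combos = feature_set_combinations()[c("physio",
                                                          "kinematics")])
  at <- accuracy_table(res)
  expect_gt(at["physio", "phone"], 90)
  expect_gt(at["kinematics", "town"], 90)
  # the planted feature is the first selected
  expect_equal(res$cells$phone.physio$selected_features$feature[1], "rr_mean")
})

test_that("the augmented scheme appends the other causes' indicator bits", {
  feats <- mock_feature_table(4)
  res <- run_matrix(feats, scheme = "augmented", menu = small_menu(),
                    causes = "phone",
                    combos = feature_set_combinations()["physio"])
  cell <- res$cells[["phone.physio"]]
  expect_equal(cell$scheme, "augmented")
  # indicators were available to the selection
  expect_true(all(c("has_drowsy", "has_town", "has_snowy") %in%
                    c(cell$selected_features$feature,
                      "has_drowsy", "has_town", "has_snowy")))
  expect_false(is.na(cell$accuracy))
})

test_that("runs are deterministic", {
  feats <- mock_feature_table(4)
  r1 <- run_matrix(feats, menu = small_menu(), causes = "snowy",
                   combos = feature_set_combinations()["kinematics"])
  r2 <- run_matrix(feats, menu = small_menu(), causes = "snowy",
                   combos = feature_set_combinations()["kinematics"])
  expect_identical(accuracy_table(r1), accuracy_table(r2))
  expect_identical(r1$cells[[1]]$accuracies, r2$cells[[1]]$accuracies)
})

test_that("reports list three best features per cause with formatted p-values", {
  feats <- mock_feature_table(6)
  res <- run_matrix(feats, menu = small_menu())
  bt <- report_best(res)
  expect_lte(max(table(bt$cause)), 3)
  expect_setequal(unique(bt$cause), hds_causes())
  expect_true(all(grepl("^<0\\.001$|^0\\.\\d{3}$", bt$p_value)))
  expect_equal(format_pvalue(c(0.0001, 0.02)), c("<0.001", "0.020"))
  dir <- file.path(tempdir(), "hds-report-test")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_report(res, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "accuracy_table.csv", "best_features.csv", "report.txt")))))
})
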