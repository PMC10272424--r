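test_that("the SAP grading rule maps involvement bands correctly", {
  expect_identical(as.character(grade_sap(c(0, 0.5, 1, 25, 26, 30, 50, 51,
                                            100))),
                   c("none", "none", "mild", "mild", "moderate", "moderate",
                     "moderate", "severe", "severe"))
  # monotone in its argument
  pct <- sort(runif(50, 0, 100))
  g <- as.integer(grade_sap(pct))
  expect_true(all(diff(g) >= 0))
  expect_error(grade_sap(-1), class = "hemomap_bad_percentage")
  expect_error(grade_sap(101), class = "hemomap_bad_percentage")
})

test_that("task labels implement both binary tasks", {
  cats <- c("none", "mild", "moderate", "severe")
  expect_identical(make_task_labels(cats, "sap_any"), c(0L, 1L, 1L, 1L))
  expect_identical(make_task_labels(cats, "sap_moderate_plus"),
                   c(0L, 0L, 1L, 1L))
  expect_error(make_task_labels(cats, "nope"),
               class = "hemomap_unknown_task")
  expect_error(make_task_labels(c("none", "bad"), "sap_any"),
               class = "hemomap_bad_category")
})

test_that("standardization uses training statistics only", {
  x <- matrix(c(1, 2, 3), ncol = 1)
  s <- standardize(x)
  expect_equal(as.numeric(s), c(-1, 0, 1), tolerance = 1e-3)

  const <- matrix(5, 4, 2)
  expect_true(all(standardize(const) == 0))

  expect_error(standardize(matrix(1, 1, 3)), class = "hemomap_too_few_rows")

  # leakage guard: shifting test rows must not change how they are scaled
  set.seed(2)
  train <- matrix(rnorm(50), 10, 5)
  test1 <- matrix(rnorm(25), 5, 5)
  s1 <- standardize(train, test1)
  s2 <- standardize(train, test1 + 100)
  expect_equal(attr(s1, "center"), attr(s2, "center"))
  expect_equal(attr(s1, "scale"), attr(s2, "scale"))
  expect_equal(s2 - s1,
               sweep(matrix(100, 5, 5), 2, attr(s1, "scale"), "/"),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("cross-validation partitions subjects and averages per-fold", {
  cats <- rep(c("none", "mild"), each = 30)
  tab <- synthetic_feature_table(60, cats, seed = 3)
  cv <- crossval(tab, "sap_any", "logistic", seed = 7, lambda_l2 = 0.1)
  expect_equal(cv$nfolds, 10)
  expect_equal(nrow(cv$per_fold), 10)
  expect_equal(cv$auc, mean(cv$per_fold$auc), tolerance = 1e-12)
  expect_equal(cv$accuracy, mean(cv$per_fold$accuracy), tolerance = 1e-12)
  # fold assignment is a partition
  y <- make_task_labels(tab$sap_category, "sap_any")
  fold <- hemomap:::stratified_folds(y, 10, 7)
  expect_equal(sort(unlist(lapply(1:10, function(f) which(fold == f)))),
               1:60)
})

test_that("a perfectly separable feature yields perfect CV metrics", {
  cats <- rep(c("none", "severe"), each = 25)
  tab <- synthetic_feature_table(50, cats, seed = 4)
  # one informative feature; all other columns constant (standardize to 0)
  for (cl in hemomap:::feature_colnames()) tab[[cl]] <- 0
  tab$ratio_hem_brain <- ifelse(cats == "severe", 10 + rnorm(50, sd = 0.1),
                                0.1)
  for (m in c("logistic", "random_forest")) {
    cv <- crossval(tab, "sap_any", m, seed = 2, lambda_l2 = 0.01)
    expect_equal(cv$auc, 1)
    expect_equal(cv$accuracy, 1)
  }
})

test_that("label-independent features give chance-level AUC", {
  set.seed(8)
  cats <- sample(rep(c("none", "mild"), each = 100))
  tab <- synthetic_feature_table(200, cats, seed = 8)
  cv <- crossval(tab, "sap_any", "logistic", seed = 3, lambda_l2 = 0.05)
  expect_gte(cv$auc, 0.35)
  expect_lte(cv$auc, 0.65)
})

test_that("degenerate classes and small classes are handled", {
  tab <- synthetic_feature_table(20, rep("none", 20), seed = 5)
  expect_error(crossval(tab, "sap_any", "logistic"),
               class = "hemomap_single_class")
  # 4 positives < 10 folds: folds reduced with a warning, still stratified
  cats <- c(rep("none", 16), rep("severe", 4))
  tab2 <- synthetic_feature_table(20, cats, seed = 6)
  expect_warning(
    suppressWarnings(cv <- crossval(tab2, "sap_any", "logistic",
                                    lambda_l2 = 0.1),
                     classes = "simpleWarning"),
    class = "hemomap_reduced_folds")
  expect_equal(cv$nfolds, 4)
})

test_that("AUC is invariant under monotone transforms of the scores", {
  set.seed(9)
  y <- rep(c(0, 1), each = 40)
  p <- plogis(rnorm(80) + y)
  a1 <- as.numeric(pROC::auc(pROC::roc(y, p, levels = c(0, 1),
                                       direction = "<", quiet = TRUE)))
  a2 <- as.numeric(pROC::auc(pROC::roc(y, qlogis(p), levels = c(0, 1),
                                       direction = "<", quiet = TRUE)))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("L1 weights are sparse, planted signals rank on top", {
  set.seed(10)
  n <- 200
  cats <- sample(c("none", "mild"), n, replace = TRUE)
  tab <- synthetic_feature_table(n, cats, seed = 10)
  y <- make_task_labels(cats, "sap_any")
  for (f in c("bd_14_Left-Hippocampus", "bd_19_Left-Choroid-Plexus",
              "bd_35_Right-Choroid-Plexus"))
    tab[[f]] <- 0.5 * y + rnorm(n, sd = 0.3)
  fw <- feature_weights(tab, "sap_any", penalty = 0.02)
  expect_s3_class(fw, "sap_feature_weights")
  expect_equal(nrow(fw), 43)
  top10 <- fw$feature[1:10]
  expect_true(all(c("bd_14_Left-Hippocampus", "bd_19_Left-Choroid-Plexus",
                    "bd_35_Right-Choroid-Plexus") %in% top10))
  # some exact zeros at this penalty
  expect_gt(sum(fw$weight == 0), 0)

  # penalty -> infinity: all weights vanish
  fw_inf <- feature_weights(tab, "sap_any", penalty = 1e6)
  expect_true(all(fw_inf$weight == 0))
})

test_that("L1 keeps at most one of a duplicated column pair", {
  set.seed(11)
  n <- 150
  cats <- sample(c("none", "severe"), n, replace = TRUE)
  tab <- synthetic_feature_table(n, cats, seed = 11)
  y <- make_task_labels(cats, "sap_any")
  sig <- y + rnorm(n, sd = 0.5)
  tab$csf_vol <- sig
  tab$parenchyma_vol <- sig  # exact duplicate
  fw <- feature_weights(tab, "sap_any", penalty = 0.1)
  w <- fw$weight[fw$feature %in% c("csf_vol", "parenchyma_vol")]
  expect_lte(sum(abs(w) > 1e-8), 1)
})
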