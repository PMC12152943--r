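test_that("confusion tallies the 2x2 table with positives = cholestasis", {
  c1 <- confusion(c(1, 0), c(1, 0))
  expect_equal(unlist(c1[c("TP", "TN", "FP", "FN")]), c(TP = 1, TN = 1, FP = 0, FN = 0))
  c2 <- confusion(c(1, 1, 0), c(0, 1, 1))
  expect_equal(unlist(c2[c("TP", "FN", "FP", "TN")]), c(TP = 1, FN = 1, FP = 1, TN = 0))
  expect_error(confusion(c(1, 0), c(1)), class = "cholecon_schema_error")
  set.seed(21)
  for (i in 1:10) {
    y <- rbinom(50, 1, 0.4); p <- rbinom(50, 1, 0.5)
    cc <- confusion(y, p)
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 50)
    expect_equal(cc$TP, sum(y & p))   # brute-force tally
    expect_equal(cc$TN, sum(!y & !p))
  }
})

test_that("compute_metrics reproduces the published filtered US_GB rows", {
  m_test <- compute_metrics(confusion_counts(TP = 28, FP = 38, TN = 57, FN = 4))
  expect_equal(round(m_test$mcc, 2), 0.41)
  expect_equal(round(m_test$sensitivity, 2), 0.88)
  expect_equal(round(m_test$specificity, 2), 0.60)
  expect_equal(round(m_test$accuracy, 2), 0.67)
  expect_equal(round(m_test$precision, 2), 0.42)
  expect_equal(round(m_test$balanced_accuracy, 2), 0.74)
  m_cv <- compute_metrics(confusion_counts(TP = 105, FP = 170, TN = 224, FN = 28))
  expect_equal(round(m_cv$mcc, 2), 0.31)
  expect_equal(round(m_cv$sensitivity, 2), 0.79)
})

test_that("metric identities and undefined markers hold", {
  perf <- compute_metrics(confusion_counts(TP = 10, FP = 0, TN = 20, FN = 0))
  expect_equal(perf$mcc, 1)
  expect_equal(perf$balanced_accuracy, 1)
  set.seed(31)
  for (i in 1:10) {
    cc <- confusion_counts(TP = rpois(1, 20) + 1, FP = rpois(1, 15) + 1,
                           TN = rpois(1, 30) + 1, FN = rpois(1, 10) + 1)
    m <- compute_metrics(cc)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
    expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
    # label swap flips the MCC sign
    sw <- compute_metrics(confusion_counts(TP = cc$FN, FP = cc$TN,
                                           TN = cc$FP, FN = cc$TP))
    expect_equal(sw$mcc, -m$mcc)
  }
  # zero denominators surface as NA, never 0
  degen <- compute_metrics(confusion_counts(TP = 0, FP = 0, TN = 10, FN = 5))
  expect_true(is.na(degen$precision))
  expect_true(is.na(degen$mcc))
  expect_false(is.na(degen$sensitivity))
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)),
               class = "cholecon_schema_error")
})

test_that("band tabulation uses [0,low), [low,high], (high,1] semantics", {
  t <- band_table(c(0.2, 0.5, 0.9), c(0, 0, 1))
  expect_equal(unname(unclass(t)["negative", ]), c(1, 1, 0))
  expect_equal(unname(unclass(t)["positive", ]), c(0, 0, 1))
  tb <- band_table(c(0.35, 0.65), c(0, 1))
  expect_equal(unname(unclass(tb)[, 2]), c(1, 1))  # both boundaries mid-band
  set.seed(7)
  p <- runif(200); y <- rbinom(200, 1, 0.3)
  tt <- band_table(p, y)
  expect_equal(sum(unclass(tt)["positive", ]), sum(y))
  expect_equal(sum(unclass(tt)["negative", ]), sum(1 - y))
  expect_error(band_table(c(0.2, 1.4), c(0, 1)), class = "cholecon_schema_error")
})

test_that("band metrics equal direct metrics on the retained subset", {
  set.seed(13)
  for (i in 1:10) {
    p <- runif(150); y <- rbinom(150, 1, 0.35)
    t <- band_table(p, y)
    keep <- p < 0.35 | p > 0.65
    direct <- compute_metrics(confusion(y[keep], as.integer(p[keep] > 0.65)))
    via_bands <- metrics_from_bands(t)
    expect_equal(via_bands$mcc, direct$mcc)
    expect_equal(via_bands$sensitivity, direct$sensitivity)
    expect_equal(via_bands$specificity, direct$specificity)
    expect_equal(via_bands$accuracy, direct$accuracy)
  }
  # all-zero middle band: filtering changes nothing
  t0 <- as_band_table(negative = c(30, 0, 10), positive = c(5, 0, 20))
  full <- compute_metrics(confusion(c(rep(0, 40), rep(1, 25)),
                                    c(rep(0, 30), rep(1, 10), rep(0, 5), rep(1, 20))))
  expect_equal(metrics_from_bands(t0)$mcc, full$mcc)
})

test_that("excluded_summary reports middle-band bookkeeping", {
  t <- as_band_table(negative = c(57, 43, 38), positive = c(4, 10, 28))
  s <- excluded_summary(t)
  expect_equal(s$count, 53)
  expect_equal(s$neg, 43)
  expect_equal(s$pos, 10)
  expect_equal(round(s$ratio, 2), 4.30)
  empty <- excluded_summary(as_band_table(c(10, 0, 5), c(2, 0, 3)))
  expect_equal(empty$count, 0)
  expect_true(is.na(empty$ratio))
})

test_that("class balance matches the published dataset compositions", {
  expect_equal(round(class_balance(c(rep(0, 688), rep(1, 211))), 2), 3.26)
  expect_equal(round(class_balance(c(rep(0, 1342), rep(1, 313))), 2), 4.29)
  expect_equal(class_balance(c(0, 1, 0, 1)), 1)
  expect_equal(format_ratio(3.2607), "3.26:1")
  expect_warning(nb <- class_balance(c(0, 0)), "undefined")
  expect_true(is.na(nb))
})

test_that("pooled cross-validation predicts every compound exactly once", {
  d <- tiny_dataset(80, 30, n_features = 12, seed = 3)
  cv <- cross_validate(d, fast_gb(1), k = 5, seed = 4)
  expect_equal(nrow(cv$predictions), 110)
  expect_setequal(cv$predictions$compound_id, rownames(d$x))
  expect_length(cv$per_fold, 5)
  expect_equal(sum(unclass(cv$band)), 110)
  cv2 <- cross_validate(d, fast_gb(1), k = 5, seed = 4)
  expect_identical(cv$predictions, cv2$predictions)
  expect_error(cross_validate(tiny_dataset(30, 4, 5), fast_gb(), k = 5, seed = 1),
               class = "cholecon_config_error")
})

test_that("unbalanced deterministic CV is stable across fold seeds", {
  d <- tiny_dataset(210, 90, n_features = 10, seed = 6)
  # moderate planted signal so the MCC is away from both 0 and 1
  d$x[, 1] <- rbinom(300, 1, ifelse(d$y == 1, 0.65, 0.35))
  mccs <- sapply(c(11, 22, 33), function(s)
    cross_validate(d, fast_gb(1), balancing = "none", k = 5, seed = s)$pooled$mcc)
  expect_lt(max(mccs) - min(mccs), 0.1)
})

test_that("select_best uses 3-decimal balanced accuracy with stated tie-breaks", {
  mr <- function(ba, sens = 0.5, mcc = 0.2) {
    structure(list(accuracy = 0.5, mcc = mcc, sensitivity = sens,
                   specificity = 0.5, precision = 0.4,
                   balanced_accuracy = ba), class = "metrics_report")
  }
  res <- list(a = mr(0.664), pubchem_pathway_transporter = mr(0.67, sens = 0.79),
              b = mr(0.669))
  expect_equal(select_best(res), "pubchem_pathway_transporter")
  expect_equal(select_best(list(only = mr(0.1))), "only")
  # 3-decimal tie broken by sensitivity, then mcc, then name
  expect_equal(select_best(list(x = mr(0.6704, sens = 0.7), y = mr(0.6701, sens = 0.8))), "y")
  expect_equal(select_best(list(x = mr(0.67, 0.7, mcc = 0.3), y = mr(0.67, 0.7, mcc = 0.2))), "x")
  expect_equal(select_best(list(b = mr(0.67, 0.7, 0.2), a = mr(0.67, 0.7, 0.2))), "a")
  # permutation invariance
  res2 <- res[c(3, 1, 2)]
  expect_equal(select_best(res2), select_best(res))
})

test_that("mean-scaled importance scales per submodel and ranks descending", {
  raw <- list(c(f1 = 2, f2 = 1), c(f1 = 4, f2 = 2),
              c(f1 = 2, f2 = 1), c(f1 = 4, f2 = 2))
  r <- mean_scaled_importance(raw)
  expect_equal(r$feature_id, c("f1", "f2"))
  expect_equal(r$mean_scaled_influence, c(1.0, 0.5))
  expect_equal(r$rank, c(1, 2))
  # all-zero submodel contributes zeros with a warning
  raw0 <- c(raw[1:3], list(c(f1 = 0, f2 = 0)))
  expect_warning(r0 <- mean_scaled_importance(raw0), "all-zero")
  expect_equal(r0$mean_scaled_influence, c(0.75, 0.375))
  # monotone non-increasing on a real ensemble
  d <- tiny_dataset(60, 25, n_features = 10, seed = 2)
  ens <- fit_us_ensemble(undersample_subsets(d, 4, seed = 1), fast_rf(1))
  ri <- mean_scaled_importance(ens)
  expect_true(all(diff(ri$mean_scaled_influence) <= 0))
  expect_true(all(ri$mean_scaled_influence >= 0 & ri$mean_scaled_influence <= 1))
})

test_that("a single dominant informative feature ranks first across seeds", {
  wins <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 120
    x <- matrix(rbinom(n * 15, 1, 0.3), n, 15,
                dimnames = list(sprintf("c%03d", 1:n), sprintf("f%02d", 1:15)))
    y <- c(rep(0, 90), rep(1, 30))
    x[, 5] <- rbinom(n, 1, ifelse(y == 1, 0.85, 0.15))
    ens <- fit_us_ensemble(undersample_subsets(labeled_dataset(x, y), 4, seed = s),
                           fast_gb(s))
    if (mean_scaled_importance(ens)$feature_id[1] == "f05") wins <- wins + 1
  }
  expect_gte(wins, 9)
})
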