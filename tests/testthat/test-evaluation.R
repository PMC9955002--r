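fake_table <- function(counts, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(names(counts), function(lab) {
    n <- counts[[lab]]
    data.frame(channel_id = paste0(lab, seq_len(n)), label = lab,
               f1 = rnorm(n), f2 = rnorm(n), stringsAsFactors = FALSE)
  }))
}

test_that("random undersampling balances every class to the minority size", {
  tab <- fake_table(c(TCSZ = 83, CPSZ = 114, EGSZ = 282))
  bal <- random_undersample(tab, seed = 7)
  expect_equal(as.vector(table(bal$label)[c("TCSZ", "CPSZ", "EGSZ")]),
               c(83, 83, 83))
  # deterministic
  expect_identical(bal, random_undersample(tab, seed = 7))
  expect_false(identical(bal$channel_id,
                         random_undersample(tab, seed = 8)$channel_id))
  # already balanced -> identical membership
  tab2 <- fake_table(c(TCSZ = 10, CPSZ = 10, EGSZ = 10))
  expect_setequal(random_undersample(tab2, seed = 1)$channel_id,
                  tab2$channel_id)
  expect_error(random_undersample(tab[tab$label == "TCSZ", ], 1),
               class = "seizr_error_invalid_argument")
})

test_that("stratified folds are disjoint, exhaustive and balanced", {
  tab <- fake_table(c(TCSZ = 83, CPSZ = 83, EGSZ = 83))
  plan <- stratified_kfold(tab, k = 10, seed = 3)
  idx <- unlist(plan$folds)
  expect_equal(sort(idx), seq_len(249))
  sizes <- lengths(plan$folds)
  expect_true(all(sizes %in% c(24, 25)))
  for (f in plan$folds) {
    cc <- table(factor(tab$label[f], c("TCSZ", "CPSZ", "EGSZ")))
    expect_true(all(cc %in% c(8, 9)))
  }
  expect_error(stratified_kfold(tab, k = 1),
               class = "seizr_error_invalid_argument")
  small <- fake_table(c(TCSZ = 5, CPSZ = 20, EGSZ = 20))
  expect_error(stratified_kfold(small, k = 10), "TCSZ")
})

test_that("confusion counts are consistent with the K x K matrix", {
  tru <- rep(c("a", "b", "c"), each = 10)
  cm <- confusion(tru, tru)
  expect_equal(sum(diag(cm$matrix)), 30)
  expect_true(all(cm$per_class$FP == 0) && all(cm$per_class$FN == 0))
  # constructed binary case
  tru2 <- c(rep("pos", 50), rep("neg", 50))
  prd2 <- c(rep("pos", 50), rep("pos", 10), rep("neg", 40))
  cm2 <- confusion(tru2, prd2)
  pos <- cm2$per_class[cm2$per_class$class == "pos", ]
  expect_equal(unlist(pos[c("TP", "TN", "FP", "FN")], use.names = FALSE),
               c(50, 40, 10, 0))
  # every class: TP+TN+FP+FN = n
  expect_true(all(rowSums(cm2$per_class[, c("TP", "TN", "FP", "FN")]) ==
                  cm2$n))
  # single-class truth with mixed predictions stays consistent
  cm3 <- confusion(rep("a", 10), c(rep("a", 6), rep("b", 4)))
  a <- cm3$per_class[cm3$per_class$class == "a", ]
  expect_equal(a$TP + a$FN, 10)
  expect_error(confusion(c("a", "b"), "a"),
               class = "seizr_error_invalid_argument")
})

test_that("metrics reproduce hand-worked values and edge cases", {
  tru <- c(rep("pos", 50), rep("neg", 50))
  prd <- c(rep("pos", 50), rep("pos", 10), rep("neg", 40))
  rep_ <- metrics(confusion(tru, prd))
  pos <- rep_$per_class[rep_$per_class$class == "pos", ]
  expect_equal(pos$sensitivity, 1.0)
  expect_equal(pos$specificity, 0.8)
  expect_equal(round(pos$precision, 4), 0.8333)
  expect_equal(round(pos$f1, 4), 0.9091)
  expect_equal(round(pos$mcc, 4), 0.8165)
  # perfect 3-class
  tru3 <- rep(c("a", "b", "c"), 10)
  perf <- metrics(confusion(tru3, tru3))
  expect_true(all(perf$macro == 1))
  expect_equal(perf$overall_accuracy, 1)
  # all-wrong binary
  aw <- metrics(confusion(c("a", "b"), c("b", "a")))
  expect_equal(aw$per_class$mcc, c(-1, -1))
})

test_that("binary label swap flips the MCC sign", {
  set.seed(17)
  tru <- sample(c("x", "y"), 60, replace = TRUE)
  prd <- ifelse(runif(60) < 0.75, tru, ifelse(tru == "x", "y", "x"))
  m1 <- metrics(confusion(tru, prd))$per_class
  swap <- function(v) ifelse(v == "x", "y", "x")
  m2 <- metrics(confusion(swap(tru), prd))$per_class
  expect_equal(m1$mcc[m1$class == "x"], -m2$mcc[m2$class == "x"])
})

test_that("metric suite matches a brute-force oracle on random matrices", {
  set.seed(23)
  for (i in 1:100) {
    K <- sample(2:4, 1)
    labs <- letters[1:K]
    tru <- sample(labs, 60, replace = TRUE)
    prd <- sample(labs, 60, replace = TRUE)
    rp <- metrics(confusion(tru, prd, levels = labs))
    for (j in seq_len(K)) {
      pc <- rp$per_class[j, ]
      o <- oracle_binary_metrics(pc$TP, pc$TN, pc$FP, pc$FN)
      expect_equal(unlist(pc[c("sensitivity", "specificity", "precision",
                               "accuracy", "f1", "mcc")],
                          use.names = FALSE),
                   unname(o), tolerance = 1e-12)
    }
  }
})

test_that("binary one-vs-rest accuracy equals trace over n", {
  set.seed(29)
  tru <- sample(c("a", "b"), 80, replace = TRUE)
  prd <- sample(c("a", "b"), 80, replace = TRUE)
  cm <- confusion(tru, prd)
  rp <- metrics(cm)
  expect_equal(rp$per_class$accuracy[1], sum(diag(cm$matrix)) / cm$n)
})

test_that("gorodkin multiclass MCC agrees with macro on symmetric cases", {
  tru <- rep(c("a", "b", "c"), 10)
  perf <- metrics(confusion(tru, tru), mcc_method = "gorodkin")
  expect_equal(unname(perf$macro["mcc"]), 1)
  rnd <- metrics(confusion(tru, rev(tru)), mcc_method = "gorodkin")
  expect_true(abs(rnd$macro[["mcc"]]) <= 1)
})

test_that("cross-validated reports are seed-deterministic", {
  tab <- fake_table(c(TCSZ = 20, CPSZ = 20, EGSZ = 20), seed = 5)
  tab$f1 <- tab$f1 + c(TCSZ = 0, CPSZ = 3, EGSZ = 6)[tab$label]
  r1 <- cross_validated_report(tab, svm_config(), k = 5, seed = 9)
  r2 <- cross_validated_report(tab, svm_config(), k = 5, seed = 9)
  expect_identical(r1$metrics$per_class, r2$metrics$per_class)
  expect_gte(r1$metrics$overall_accuracy, 0.9)
})

test_that("anova_oneway matches the hand-computed F and flags degeneracy", {
  a <- anova_oneway(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                    rep(c("g1", "g2", "g3"), each = 3))
  expect_equal(a$statistic, 3.0)
  expect_false(a$degenerate)
  d <- anova_oneway(rep(5, 9), rep(c("g1", "g2", "g3"), each = 3))
  expect_true(d$degenerate)
  expect_true(is.na(d$statistic))
  expect_error(anova_oneway(1:5, c("a", "a", "a", "a", "b")),
               class = "seizr_error_invalid_argument")
  expect_error(anova_oneway(1:4, rep("a", 4)),
               class = "seizr_error_invalid_argument")
})

test_that("anova type-I error is near nominal under the null", {
  set.seed(61)
  rej <- mean(replicate(1000, {
    anova_oneway(rnorm(30), rep(c("a", "b"), each = 15))$p_value < 0.05
  }))
  expect_equal(rej, 0.05, tolerance = 0.02 / 0.05)
})

test_that("anova_screen returns one row per feature", {
  segs <- simulate_dataset(dataset_spec(c(TCSZ = 8, CPSZ = 8, EGSZ = 8),
                                        seed = 30))
  ft <- extract_feature_table(segs, window_config(0.5, 50))
  sc <- anova_screen(ft)
  expect_equal(nrow(sc), 18)
  expect_true(all(is.finite(sc$F)))
})
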