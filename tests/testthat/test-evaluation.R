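# Evaluation layer: 2x2 metrics, LOOCV/k-fold/bootstrap, Fisher exact test.

test_that("diagnostic metrics handle the perfect and degenerate tables", {
  dm <- diagnostic_metrics(contingency_table(10, 0, 0, 10))
  est <- setNames(dm$estimate, dm$metric)
  expect_equal(unname(est[c("sensitivity", "specificity", "ppv", "npv",
                            "accuracy")]), rep(1, 5))
  expect_identical(unname(est["lr_pos"]), Inf)
  expect_equal(unname(est["lr_neg"]), 0)
  expect_error(diagnostic_metrics(contingency_table(0, 0, 3, 7)), "class")
  expect_error(contingency_table(-1, 0, 0, 1), "non-negative")
})

test_that("likelihood-ratio identities hold to 1e-12", {
  set.seed(31)
  for (i in 1:20) {
    tab <- contingency_table(sample(1:30, 1), sample(1:30, 1),
                             sample(1:30, 1), sample(1:30, 1))
    dm <- diagnostic_metrics(tab)
    est <- setNames(dm$estimate, dm$metric)
    expect_equal(est[["lr_pos"]] * (1 - est[["specificity"]]),
                 est[["sensitivity"]], tolerance = 1e-12)
    expect_equal(est[["lr_neg"]] * est[["specificity"]],
                 1 - est[["sensitivity"]], tolerance = 1e-12)
  }
})

test_that("Wilson interval reproduces a frozen reference value", {
  # 8 successes of 10, 95%: canonical Wilson interval (0.4901, 0.9433)
  ci <- ibsacoustics:::wilson_ci(8, 10)
  expect_equal(ci, c(0.4901, 0.9433), tolerance = 5e-4)
})

test_that("monotone consistency: a correct IBS case never lowers sensitivity", {
  set.seed(32)
  for (i in 1:10) {
    tab <- contingency_table(sample(0:20, 1), sample(0:20, 1),
                             sample(1:20, 1), sample(1:20, 1))
    if (tab$TP + tab$FN == 0) next
    s1 <- tab$TP / (tab$TP + tab$FN)
    tab2 <- contingency_table(tab$TP + 1, tab$FN, tab$FP, tab$TN)
    s2 <- tab2$TP / (tab2$TP + tab2$FN)
    expect_gte(s2, s1)
  }
})

test_that("LOOCV is perfect on a separable cohort and equals k = n folds", {
  coh <- gaussian_cohort(10, 12, delta = 6, p_noise = 2, seed = 33)
  r <- loocv(coh$x, coh$y)
  expect_equal(r$accuracy, 1)
  n <- nrow(coh$x)
  expect_equal(r$table$TP + r$table$FN + r$table$FP + r$table$TN, n)
  rk <- kfold_cv(coh$x, coh$y, k = n)
  expect_equal(r$predictions$index, rk$predictions$index, tolerance = 1e-12)
  expect_error(loocv(coh$x[1:2, ], coh$y[1:2]), "at least 3")
})

test_that("LOOCV under label permutation is at chance (null oracle)", {
  coh <- gaussian_cohort(10, 10, delta = 3, p_noise = 1, seed = 34)
  set.seed(35)
  accs <- replicate(60, loocv(coh$x, sample(coh$y))$accuracy)
  expect_lt(abs(mean(accs) - 0.5), 3 * sd(accs))
})

test_that("k-fold partitions are balanced and stratified folds keep ratios", {
  coh <- gaussian_cohort(31, 37, delta = 2, p_noise = 1, seed = 36)
  r <- kfold_cv(coh$x, coh$y, k = 5, stratified = TRUE, seed = 9)
  sizes <- table(r$folds)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(sizes), 68)
  expect_true(all(table(r$folds) == tabulate(r$folds)))  # exactly one fold each
  for (f in 1:5) {
    n_ibs_f <- sum(coh$y[r$folds == f] == "IBS")
    expect_lte(abs(n_ibs_f - 31 / 68 * sizes[[f]]), 1)
  }
  expect_error(kfold_cv(coh$x, coh$y, k = 1), "k must be")
  bat <- cv_battery(coh$x, coh$y, seed = 2)
  expect_equal(nrow(bat), 7)   # the documented battery of 7 schemes
})

test_that("bootstrap defaults to 300 reps, is seeded, and tracks LOOCV", {
  expect_equal(eval(formals(bootstrap_eval)$B), 300L)
  coh <- gaussian_cohort(15, 15, delta = 5, p_noise = 2, seed = 37)
  b1 <- bootstrap_eval(coh$x, coh$y, B = 40, seed = 5)
  b2 <- bootstrap_eval(coh$x, coh$y, B = 40, seed = 5)
  expect_identical(b1$replicates, b2$replicates)
  total <- b1$table$TP + b1$table$FN + b1$table$FP + b1$table$TN
  expect_gt(total, 0)
  # strongly separated cohort: bootstrap accuracy inside the LOOCV 95% CI
  lo <- loocv(coh$x, coh$y)
  ci <- diagnostic_metrics(lo$table)
  acc_ci <- unlist(ci[ci$metric == "accuracy", c("ci_low", "ci_high")])
  expect_gte(b1$accuracy, acc_ci[[1]])
  expect_lte(b1$accuracy, acc_ci[[2]])
})

test_that("Fisher exact test equals exhaustive hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2)), 1.0)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5),
               tolerance = 1e-12)
  set.seed(38)
  for (i in 1:15) {
    m <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact(m), fisher.test(m)$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})
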