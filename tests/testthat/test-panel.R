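test_that("bootstrap penalty selection is reproducible and bookkeeps draws", {
  set.seed(2)
  beta <- c(0.6, 0.6, 0.4, 0, 0.4, 0.5, 0.7, 0.4, 0.5)
  coh <- generate_model_cohort(120, beta, seed = 5)
  x <- as.matrix(coh[, marker_reference()$marker])
  s1 <- select_penalty_bootstrap(x, coh$label, n_bootstrap = 40, seed = 9)
  s2 <- select_penalty_bootstrap(x, coh$label, n_bootstrap = 40, seed = 9)
  expect_identical(s1$chosen_lambda, s2$chosen_lambda)
  expect_identical(s1$mean_oob_auc, s2$mean_oob_auc)
  expect_equal(s1$n_used + s1$n_skipped, 40L)
  # chosen lambda attains the maximum of the mean OOB AUC
  expect_equal(
    max(s1$mean_oob_auc),
    s1$mean_oob_auc[match(s1$chosen_lambda, s1$lambda_grid)]
  )
  s3 <- select_penalty_bootstrap(x, coh$label, n_bootstrap = 40, seed = 10)
  expect_false(identical(s1$mean_oob_auc, s3$mean_oob_auc))
})

test_that("an intercept-only grid scores out-of-bag subjects at chance", {
  set.seed(3)
  coh <- generate_model_cohort(150, rep(0.5, 9), seed = 7)
  x <- as.matrix(coh[, marker_reference()$marker])
  s <- select_penalty_bootstrap(x, coh$label,
    lambda_grid = 1e6,
    n_bootstrap = 60, seed = 2
  )
  expect_equal(s$mean_oob_auc, 0.5, tolerance = 1e-9)
})

test_that("the out-of-bag fraction matches its closed-form expectation", {
  n <- 283
  coh <- generate_model_cohort(n, rep(0.5, 9), seed = 13)
  x <- as.matrix(coh[, marker_reference()$marker])
  s <- select_penalty_bootstrap(x, coh$label,
    lambda_grid = 1e6,
    n_bootstrap = 400, seed = 3
  )
  # distinct in-bag fraction 1-(1-1/n)^n, out-of-bag its complement
  expect_equal(s$oob_fraction_mean, (1 - 1 / n)^n, tolerance = 0.01)
  expect_equal(1 - s$oob_fraction_mean, 1 - (1 - 1 / n)^n, tolerance = 0.01)
})

test_that("ties in the mean OOB AUC resolve to the larger penalty", {
  set.seed(4)
  coh <- generate_model_cohort(100, rep(0.4, 9), seed = 3)
  x <- as.matrix(coh[, marker_reference()$marker])
  # two absurdly large lambdas give identical intercept-only scores
  s <- select_penalty_bootstrap(x, coh$label,
    lambda_grid = c(1e6, 1e7),
    n_bootstrap = 20, seed = 1
  )
  expect_equal(s$chosen_lambda, 1e7)
})

test_that("finalization keeps nonzero markers and rejects empty panels", {
  set.seed(6)
  n <- 120
  # fully separable on marker "a"
  x <- cbind(a = c(seq(0, 1, length.out = n / 2), seq(3, 4, length.out = n / 2)),
    b = rnorm(n)
  )
  y <- rep(c(0, 1), each = n / 2)
  pan <- finalize_panel(x, y, selection = 0.01, alpha = 0.5)
  expect_true("a" %in% pan$markers)
  expect_equal(
    roc_auc(predict(pan, as.data.frame(x)), y)$auc, 1.0
  )
  expect_error(
    finalize_panel(x, y, selection = 1e6),
    "degenerate"
  )
})

test_that("duplicating a marker leaves panel scores nearly unchanged", {
  set.seed(8)
  coh <- generate_model_cohort(200, c(0.8, 0.6, rep(0, 7)), seed = 4)
  x1 <- as.matrix(coh[, c("CEA", "MDK")])
  x2 <- cbind(x1, CEA2 = x1[, "CEA"]) # exact copy: grouping behavior
  p1 <- finalize_panel(x1, coh$label, selection = 0.02, alpha = 0.5)
  p2 <- finalize_panel(x2, coh$label, selection = 0.02, alpha = 0.5)
  s1 <- predict(p1, as.data.frame(x2))
  s2 <- predict(p2, as.data.frame(x2))
  expect_gt(cor(s1, s2), 0.999)
})

test_that("panel evaluation reports overall, subgroup and threshold metrics", {
  set.seed(10)
  beta <- c(0.6, 0.6, 0.4, 0, 0.4, 0.5, 0.7, 0.4, 0.5)
  coh <- generate_model_cohort(250, beta, seed = 6)
  x <- as.matrix(coh[, marker_reference()$marker])
  pan <- finalize_panel(x, coh$label, selection = 0.02)
  ev <- evaluate_panel(pan, coh)
  expect_equal(ev$auc, roc_auc(predict(pan, coh), coh$label)$auc)
  # subgroup covering all controls reproduces the overall AUC
  ev2 <- evaluate_panel(pan, coh, subgroups = list(all = rep(TRUE, nrow(coh))))
  expect_equal(unname(ev2$subgroup_auc["all"]), ev2$auc)
  expect_warning(
    evaluate_panel(pan, coh, subgroups = list(none = rep(FALSE, nrow(coh)))),
    "no controls"
  )
})

test_that("evaluation AUC tracks the binormal prediction on synthetic scores", {
  # log-scale group shift d on one marker: binormal AUC = pnorm(d / sqrt(2))
  set.seed(11)
  n <- 4000
  d <- 1.2
  scores <- c(rnorm(n), rnorm(n, d))
  labels <- rep(c(FALSE, TRUE), each = n)
  expect_equal(
    roc_auc(scores, labels)$auc, pnorm(d / sqrt(2)),
    tolerance = 0.02
  )
})

test_that("panel training recovers informative coefficient signs", {
  beta <- c(0.6, 0.6, 0.4, 0, 0.4, 0.5, 0.7, 0.4, 0.5)
  hits <- vapply(1:5, function(s) {
    coh <- generate_model_cohort(283, beta, seed = 40 + s)
    x <- as.matrix(coh[, marker_reference()$marker])
    pan <- finalize_panel(x, coh$label, selection = 0.01)
    coefs <- setNames(rep(0, 9), marker_reference()$marker)
    coefs[pan$markers] <- pan$coefficients
    all(coefs[names(coefs) != "SLPI"] > 0)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
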