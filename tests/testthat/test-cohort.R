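test_that("log-normal calibration solves the median/IQR system", {
  # worked example: control-group CEA
  p <- lognormal_params(1.65, 0.85, 2.92)
  expect_equal(p$meanlog, log(1.65), tolerance = 1e-12)
  expect_equal(p$sdlog, (log(2.92) - log(0.85)) / (2 * qnorm(0.75)),
    tolerance = 1e-12
  )
  # round trip: analytic median exact, geometric IQR ratio exact
  mk <- marker_reference()
  for (grp in c("control", "case")) {
    for (i in seq_len(nrow(mk))) {
      med <- mk[[paste0(grp, "_median")]][i]
      q1 <- mk[[paste0(grp, "_q1")]][i]
      q3 <- mk[[paste0(grp, "_q3")]][i]
      par <- lognormal_params(med, q1, q3)
      expect_equal(exp(par$meanlog), med, tolerance = 1e-12)
      if (q1 > 0) {
        ratio <- exp(qnorm(0.75) * par$sdlog)^2 # Q3/Q1 of the fitted law
        expect_equal(ratio, q3 / q1, tolerance = 1e-12)
      }
    }
  }
})

test_that("zero scale collapses every draw onto the median", {
  mk <- marker_reference()[1, ]
  mk$control_q1 <- mk$control_median
  mk$control_q3 <- mk$control_median
  cfg <- cohort_sim_config(
    markers = mk, n_cases = 5, n_controls = 20,
    correlation = matrix(1, 1, 1), seed = 1
  )
  coh <- generate_serum_cohort(cfg)
  ctl <- coh$CEA[coh$label == "control"]
  expect_equal(ctl, rep(1.65, 20), tolerance = 1e-12)
})

test_that("large cohorts converge on the calibrated medians", {
  cfg <- cohort_sim_config(n_cases = 200, n_controls = 20000, seed = 7)
  coh <- generate_serum_cohort(cfg)
  ctl <- coh[coh$label == "control", ]
  mk <- marker_reference()
  for (i in seq_len(nrow(mk))) {
    expect_equal(
      median(ctl[[mk$marker[i]]]), mk$control_median[i],
      tolerance = 0.02, label = mk$marker[i]
    )
  }
})

test_that("a non-positive-semi-definite correlation matrix is rejected", {
  bad <- diag(9)
  bad[1, 2] <- bad[2, 1] <- 0.9
  bad[1, 3] <- bad[3, 1] <- 0.9
  bad[2, 3] <- bad[3, 2] <- -0.9
  expect_error(cohort_sim_config(correlation = bad), "positive semi-definite")
  asym <- diag(9)
  asym[1, 2] <- 0.5
  expect_error(cohort_sim_config(correlation = asym), "symmetric")
})

test_that("cohort simulation is reproducible and covariates are complete", {
  cfg <- cohort_sim_config(n_cases = 40, n_controls = 60, seed = 12)
  a <- generate_serum_cohort(cfg)
  b <- generate_serum_cohort(cfg)
  expect_identical(a, b)
  expect_equal(sum(a$label == "case"), 40)
  expect_true(all(!is.na(a$age)))
  expect_true(all(a$stage[a$label == "case"] == "I"))
  expect_true(all(!is.na(a$nodule_size_cm[a$label == "case"])))
  expect_true(all(as.matrix(a[, marker_reference()$marker]) > 0))
  d <- generate_serum_cohort(cohort_sim_config(
    n_cases = 40, n_controls = 60,
    seed = 13
  ))
  expect_false(identical(a$CEA, d$CEA))
})

test_that("correlated markers show the requested log-scale correlation", {
  R <- diag(9)
  R[1, 2] <- R[2, 1] <- 0.7
  cfg <- cohort_sim_config(
    n_cases = 10, n_controls = 4000, correlation = R,
    seed = 5
  )
  coh <- generate_serum_cohort(cfg)
  ctl <- coh[coh$label == "control", ]
  r <- cor(log(ctl$CEA), log(ctl$MDK))
  expect_equal(r, 0.7, tolerance = 0.05)
  expect_lt(abs(cor(log(ctl$CEA), log(ctl$MMP2))), 0.06)
})

test_that("paired serum/plasma values are perfectly concordant at zero sd", {
  tbl <- generate_paired_serum_plasma(20, concordance_sd = 0, seed = 2)
  conc <- serum_plasma_concordance(tbl)
  expect_equal(conc$r, rep(1, 9), tolerance = 1e-12)
  expect_error(generate_paired_serum_plasma(2), "at least 3")
  # reproducible
  expect_identical(
    generate_paired_serum_plasma(5, seed = 4),
    generate_paired_serum_plasma(5, seed = 4)
  )
})

test_that("the model cohort carries its generating coefficients", {
  beta <- c(0.5, 0.5, 0.3, 0, 0.3, 0.4, 0.6, 0.3, 0.4)
  coh <- generate_model_cohort(500, beta, seed = 3)
  expect_equal(unname(attr(coh, "beta")), beta)
  expect_true(all(coh$label %in% c("case", "control")))
  expect_gt(sum(coh$label == "case"), 50)
  # a strong positive marker separates groups in the expected direction
  expect_gt(
    median(coh$CYFRA21_1[coh$label == "case"]),
    median(coh$CYFRA21_1[coh$label == "control"])
  )
})
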