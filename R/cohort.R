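# Serum cohort simulation calibrated to published marker summary statistics.
#
# Marker concentrations are drawn from (optionally correlated) log-normal
# distributions whose parameters are solved from a group's printed median and
# interquartile range: location = ln(median), scale = (ln Q3 - ln Q1) /
# (2 * qnorm(0.75)). The median and the geometric IQR ratio Q3/Q1 of the
# configured distribution then match the targets exactly.

#' Published serum marker summary statistics
#'
#' Median (ng/mL) and interquartile range of each of the nine panel markers
#' in the verification cohort (94 stage I NSCLC cases, 189 healthy smoker
#' controls), with the published single-marker AUC. These are the default
#' calibration targets of [generate_serum_cohort()].
#'
#' @return Tibble: `marker`, `control_median`, `control_q1`, `control_q3`,
#'   `case_median`, `case_q1`, `case_q3`, `auc`.
#' @export
marker_reference <- function() {
  tibble::tribble(
    ~marker, ~control_median, ~control_q1, ~control_q3,
    ~case_median, ~case_q1, ~case_q3, ~auc,
    "CEA", 1.65, 0.85, 2.92, 2.68, 1.85, 4.90, 0.706,
    "MDK", 0.15, 0.04, 0.35, 0.43, 0.20, 0.66, 0.714,
    "MMP2", 207, 184, 234, 207, 171, 254, 0.492,
    "SLPI", 39.6, 34.8, 46.2, 43.3, 35.5, 54.5, 0.595,
    "TFPI", 39.7, 25.6, 55.1, 54.1, 29.1, 70.3, 0.617,
    "TIMP1", 302, 269, 346, 361, 306, 440, 0.692,
    "CYFRA21_1", 0.58, 0.00, 1.05, 1.60, 0.91, 3.00, 0.816,
    "OPN", 19.3, 10.0, 31.0, 31.4, 16.7, 52.4, 0.666,
    "SCC", 0.58, 0.34, 0.93, 1.21, 0.55, 1.70, 0.696
  )
}

#' Log-normal parameters from a median and interquartile range
#'
#' `meanlog = ln(median)`; `sdlog = (ln Q3 - ln Q1) / (2 * qnorm(0.75))`.
#' When Q1 is at or below zero (a quartile pinned at the assay floor, as for
#' CYFRA 21-1 controls) the scale is taken from the upper half-width only:
#' `sdlog = (ln Q3 - ln median) / qnorm(0.75)`.
#'
#' @param median,q1,q3 Group median and quartiles (same units, > 0 except
#'   that q1 may be 0).
#' @return List with `meanlog` and `sdlog`.
#' @export
lognormal_params <- function(median, q1, q3) {
  stopifnot(median > 0, q3 >= median, q1 <= median)
  z75 <- qnorm(0.75)
  sdlog <- if (q1 > 0) {
    (log(q3) - log(q1)) / (2 * z75)
  } else {
    (log(q3) - log(median)) / z75
  }
  list(meanlog = log(median), sdlog = sdlog)
}

#' Cohort simulation settings
#'
#' @param markers Calibration table in the layout of [marker_reference()].
#' @param n_cases,n_controls Group sizes; defaults match the verification
#'   cohort (94 cases / 189 controls).
#' @param correlation Marker-marker correlation matrix on the log scale
#'   (default: identity, i.e. independent markers). Must be symmetric
#'   positive semi-definite with unit diagonal.
#' @param control_nodule_rate Fraction of controls carrying a benign nodule.
#' @param nodule_risk_slope Slope linking a case's latent marker burden
#'   (mean standardized log concentration) to log lesion size, so panel
#'   scores correlate with lesion size as observed clinically.
#' @param seed Integer seed.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(markers = marker_reference(),
                              n_cases = 94, n_controls = 189,
                              correlation = NULL,
                              control_nodule_rate = 0.12,
                              nodule_risk_slope = 0.35,
                              seed = 1L) {
  p <- nrow(markers)
  if (is.null(correlation)) correlation <- diag(p)
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
    !isTRUE(all.equal(diag(correlation), rep(1, p)))) {
    stop_invalid("`correlation` must be symmetric with unit diagonal")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_invalid("`correlation` must be positive semi-definite")
  }
  structure(
    list(
      markers = markers, n_cases = as.integer(n_cases),
      n_controls = as.integer(n_controls), correlation = correlation,
      control_nodule_rate = control_nodule_rate,
      nodule_risk_slope = nodule_risk_slope, seed = as.integer(seed)
    ),
    class = "cohort_sim_config"
  )
}

# draw n x p correlated standard normals
draw_correlated_normals <- function(n, correlation) {
  p <- nrow(correlation)
  z <- matrix(rnorm(n * p), n, p)
  ev <- eigen(correlation, symmetric = TRUE)
  root <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p) %*% t(ev$vectors)
  z %*% root
}

#' Simulate a case/control serum cohort
#'
#' Concentrations are drawn from correlated log-normal distributions
#' calibrated per group to the configured medians and interquartile ranges.
#' Demographics follow the verification cohort: control age ~ N(62.1, 11.8),
#' case age ~ N(66.6, 9.6); pack-years N(37.6, 21.7) / N(43.9, 20.6); cases
#' are stage I with the training histology mix; case lesion sizes are
#' log-normal around 2.8 cm and coupled to the latent marker burden; a
#' fraction of controls carries a small benign nodule (median 0.5 cm).
#'
#' @param config A [cohort_sim_config()].
#' @return Tibble of subject records: `subject_id`, `label`
#'   (`"control"`/`"case"`), covariates, `nodule_size_cm` (NA when no
#'   nodule), then one concentration column per marker (ng/mL).
#' @export
generate_serum_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  mk <- config$markers
  with_seed(config$seed, {
    draw_group <- function(n, group) {
      z <- draw_correlated_normals(n, config$correlation)
      x <- sapply(seq_len(nrow(mk)), function(j) {
        par <- if (group == "control") {
          lognormal_params(mk$control_median[j], mk$control_q1[j], mk$control_q3[j])
        } else {
          lognormal_params(mk$case_median[j], mk$case_q1[j], mk$case_q3[j])
        }
        exp(par$meanlog + par$sdlog * z[, j])
      })
      x <- matrix(x, nrow = n)
      colnames(x) <- mk$marker
      list(x = x, z = z)
    }
    ctl <- draw_group(config$n_controls, "control")
    cas <- draw_group(config$n_cases, "case")

    histologies <- c(
      "adenocarcinoma", "BAC", "large_cell", "NSCLC_NOS", "neuroendocrine",
      "squamous_cell"
    )
    hist_prob <- c(63, 4, 6, 4, 2, 15) / 94

    n_ctl <- config$n_controls
    n_cas <- config$n_cases
    ctl_nodule <- runif(n_ctl) < config$control_nodule_rate
    ctl_size <- ifelse(
      ctl_nodule,
      pmin(pmax(exp(log(0.5) + 0.4 * rnorm(n_ctl)), 0.2), 1.2),
      NA_real_
    )
    # latent marker burden: mean standardized log concentration
    burden <- rowMeans(scale(log(cas$x)))
    cas_size <- pmin(pmax(
      exp(log(2.8) + config$nodule_risk_slope * burden + 0.25 * rnorm(n_cas)),
      0.8
    ), 12)

    controls <- tibble(
      subject_id = sprintf("CTL%04d", seq_len(n_ctl)),
      label = "control",
      age = round(rnorm(n_ctl, 62.1, 11.8), 1),
      sex = sample(c("M", "F"), n_ctl, replace = TRUE, prob = c(109, 80)),
      pack_years = round(pmax(rnorm(n_ctl, 37.6, 21.7), 0), 1),
      nodule_size_cm = round(ctl_size, 2),
      stage = NA_character_,
      histology = NA_character_
    )
    cases <- tibble(
      subject_id = sprintf("CSE%04d", seq_len(n_cas)),
      label = "case",
      age = round(rnorm(n_cas, 66.6, 9.6), 1),
      sex = sample(c("M", "F"), n_cas, replace = TRUE, prob = c(33, 61)),
      pack_years = round(pmax(rnorm(n_cas, 43.9, 20.6), 0), 1),
      nodule_size_cm = round(cas_size, 2),
      stage = "I",
      histology = sample(histologies, n_cas, replace = TRUE, prob = hist_prob)
    )
    bind_rows(
      dplyr::bind_cols(controls, as_tibble(ctl$x)),
      dplyr::bind_cols(cases, as_tibble(cas$x))
    )
  })
}

#' Simulate a cohort with a known linear log-odds signal
#'
#' Marker concentrations for all subjects are drawn from the control-group
#' calibrated log-normals; disease status is then sampled from a logistic
#' model on the standardized log concentrations with user-supplied
#' coefficients. Markers with a zero coefficient are pure noise -- the
#' ground truth for panel-selection recovery studies.
#'
#' @param n Number of subjects.
#' @param beta Named numeric vector of log-odds coefficients on the
#'   standardized log scale, one per marker of `markers`.
#' @param intercept Log-odds intercept (controls prevalence).
#' @param markers Calibration table in the layout of [marker_reference()].
#' @param correlation Optional marker-marker correlation matrix on the log
#'   scale (default: independent markers).
#' @param seed Integer seed.
#' @return Tibble: `subject_id`, `label`, marker columns; attribute
#'   `"beta"` carries the generating coefficients.
#' @export
generate_model_cohort <- function(n, beta, intercept = -0.7,
                                  markers = marker_reference(),
                                  correlation = NULL, seed = 1L) {
  stopifnot(length(beta) == nrow(markers))
  if (is.null(correlation)) correlation <- diag(nrow(markers))
  with_seed(seed, {
    z <- draw_correlated_normals(n, correlation)
    x <- sapply(seq_len(nrow(markers)), function(j) {
      par <- lognormal_params(
        markers$control_median[j], markers$control_q1[j], markers$control_q3[j]
      )
      exp(par$meanlog + par$sdlog * z[, j])
    })
    colnames(x) <- markers$marker
    eta <- intercept + scale(log(x)) %*% beta
    y <- rbinom(n, 1, plogis(eta))
    out <- dplyr::bind_cols(
      tibble(
        subject_id = sprintf("SIM%05d", seq_len(n)),
        label = ifelse(y == 1, "case", "control")
      ),
      as_tibble(x)
    )
    attr(out, "beta") <- setNames(beta, markers$marker)
    out
  })
}

#' Simulate paired serum/plasma measurements
#'
#' Serum values are drawn from the control-group calibration; the paired
#' plasma value multiplies each serum value by a log-normal matrix effect of
#' standard deviation `concordance_sd` (natural-log scale). At
#' `concordance_sd = 0` the two matrices agree exactly.
#'
#' @param n_subjects Number of paired subjects (>= 3).
#' @param concordance_sd Log-scale SD of the serum-to-plasma matrix effect.
#' @param seed Integer seed.
#' @param markers Calibration table in the layout of [marker_reference()].
#' @return Long tibble: `subject_id`, `marker`, `serum`, `plasma` (ng/mL).
#' @export
generate_paired_serum_plasma <- function(n_subjects, concordance_sd = 0.1,
                                         seed = 1L,
                                         markers = marker_reference()) {
  if (n_subjects < 3) stop_invalid("`n_subjects` must be at least 3")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(markers)), function(j) {
      par <- lognormal_params(
        markers$control_median[j], markers$control_q1[j], markers$control_q3[j]
      )
      serum <- rlnorm(n_subjects, par$meanlog, par$sdlog)
      eff <- if (concordance_sd > 0) {
        exp(rnorm(n_subjects, 0, concordance_sd))
      } else {
        1
      }
      tibble(
        subject_id = sprintf("PRD%03d", seq_len(n_subjects)),
        marker = markers$marker[j],
        serum = serum,
        plasma = serum * eff
      )
    })
    bind_rows(rows)
  })
}
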