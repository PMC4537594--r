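# Marker-level verification statistics: median/IQR summaries, two-sample
# Kolmogorov-Smirnov tests, and ROC curves with the rank (Mann-Whitney) AUC.

#' ROC curve and AUC
#'
#' The AUC uses the rank (Mann-Whitney) formulation with mid-rank tie
#' correction: the probability that a random case scores above a random
#' control, ties counting one half. Operating points are computed at every
#' distinct threshold with the rule "positive iff score >= threshold".
#'
#' @param scores Numeric risk scores, higher = more case-like.
#' @param labels Case/control labels: logical (TRUE = case), 0/1, or a
#'   vector containing `"case"`/`"control"`.
#' @return Object of class `roc_curve`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `n_cases`, `n_controls`.
#' @export
roc_auc <- function(scores, labels) {
  is_case <- as_case_indicator(labels)
  if (length(scores) != length(is_case)) {
    stop_invalid("`scores` and `labels` lengths differ")
  }
  ok <- !is.na(scores) & !is.na(is_case)
  scores <- scores[ok]
  is_case <- is_case[ok]
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) {
    stop_invalid("both classes must be present to compute a ROC curve")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(is_case & scores >= t) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(!is_case & scores < t) / n0, numeric(1))
  structure(
    list(
      thresholds = thr, sensitivity = sens, specificity = spec,
      auc = auc, n_cases = n1, n_controls = n0
    ),
    class = "roc_curve"
  )
}

as_case_indicator <- function(labels) {
  if (is.logical(labels)) {
    return(labels)
  }
  if (is.numeric(labels)) {
    return(labels == 1)
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("case", "control"))) {
    stop_invalid("character labels must be \"case\"/\"control\"")
  }
  labels == "case"
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "<roc_curve> AUC = %.3f (%d cases, %d controls)\n",
    x$auc, x$n_cases, x$n_controls
  ))
  invisible(x)
}

#' Sensitivity at a minimum specificity
#'
#' The highest sensitivity among achievable operating points with
#' specificity at or above the target; no interpolation between points, so
#' the reported pair is attainable with an actual threshold.
#'
#' @param roc A `roc_curve` from [roc_auc()].
#' @param target_specificity Target in (0, 1).
#' @return Sensitivity at the chosen operating point.
#' @export
sensitivity_at_specificity <- function(roc, target_specificity = 0.9) {
  stopifnot(inherits(roc, "roc_curve"))
  if (target_specificity <= 0 || target_specificity >= 1) {
    stop_invalid("`target_specificity` must be in (0, 1)")
  }
  ok <- roc$specificity >= target_specificity
  max(roc$sensitivity[ok])
}

#' Marker-level case/control summary
#'
#' Group medians and interquartile ranges (linear-interpolation quantiles),
#' the two-sample Kolmogorov-Smirnov statistic with asymptotic p-value, and
#' the single-marker AUC (higher value = more case-like).
#'
#' @param values_case,values_control Concentrations per group (ng/mL).
#' @param marker Optional marker name carried into the output.
#' @return One-row tibble: `marker`, `n_case`, `n_control`, medians and
#'   quartiles per group, `ks_d`, `ks_p`, `auc`.
#' @export
summarize_marker <- function(values_case, values_control, marker = NA_character_) {
  if (length(values_case) == 0 || length(values_control) == 0) {
    stop_invalid("both groups must be non-empty")
  }
  q_case <- quantile(values_case, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  q_ctl <- quantile(values_control, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  ks <- suppressWarnings(
    ks.test(values_case, values_control, exact = FALSE)
  )
  roc <- roc_auc(
    c(values_case, values_control),
    c(rep(TRUE, length(values_case)), rep(FALSE, length(values_control)))
  )
  tibble(
    marker = marker,
    n_case = length(values_case), n_control = length(values_control),
    control_median = q_ctl[2], control_q1 = q_ctl[1], control_q3 = q_ctl[3],
    case_median = q_case[2], case_q1 = q_case[1], case_q3 = q_case[3],
    ks_d = unname(ks$statistic), ks_p = ks$p.value,
    auc = roc$auc
  )
}

#' Verification summary for every marker of a cohort
#'
#' @param cohort Cohort tibble with a `label` column and one column per
#'   marker.
#' @param markers Character vector of marker column names.
#' @return Tibble with one [summarize_marker()] row per marker.
#' @export
verify_markers <- function(cohort, markers) {
  is_case <- as_case_indicator(cohort$label)
  bind_rows(lapply(markers, function(m) {
    summarize_marker(cohort[[m]][is_case], cohort[[m]][!is_case], marker = m)
  }))
}

#' Pearson correlation of a panel score with a covariate
#'
#' @param scores Numeric panel scores.
#' @param covariate Paired covariate (e.g. lesion size in cm); pairs with
#'   missing values are dropped.
#' @return List: `r`, `p`, `n`.
#' @export
correlate_score_covariate <- function(scores, covariate) {
  ok <- !is.na(scores) & !is.na(covariate)
  if (sum(ok) < 3) stop_invalid("need >= 3 complete pairs")
  if (sd(covariate[ok]) == 0 || sd(scores[ok]) == 0) {
    stop_invalid("correlation undefined for a constant input")
  }
  ct <- cor.test(scores[ok], covariate[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Per-marker serum/plasma concordance
#'
#' @param paired_table Long tibble with `marker`, `serum`, `plasma` columns
#'   (see [generate_paired_serum_plasma()]).
#' @return Tibble: `marker`, `r`, `p`, `n`.
#' @export
serum_plasma_concordance <- function(paired_table) {
  bind_rows(lapply(split(paired_table, paired_table$marker), function(d) {
    res <- correlate_score_covariate(d$serum, d$plasma)
    tibble(marker = d$marker[1], r = res$r, p = res$p, n = res$n)
  }))
}
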