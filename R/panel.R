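# Multi-marker panel development: bootstrap out-of-bag AUC penalty
# selection, final refit, evaluation with control subgroups.

#' Select the penalty weight by bootstrap out-of-bag AUC
#'
#' For each bootstrap draw, subjects are resampled with replacement; the
#' elastic-net path over the lambda grid is fit on the in-bag sample and the
#' out-of-bag subjects are scored; the out-of-bag AUC is recorded per
#' lambda. The chosen lambda maximizes the mean out-of-bag AUC over draws,
#' ties broken toward the larger (more parsimonious) lambda. Draws whose
#' out-of-bag set contains a single class are skipped and counted.
#'
#' @param x Predictor matrix or data frame (subjects x markers).
#' @param y Binary outcome (logical, 0/1, or `"case"`/`"control"`).
#' @param lambda_grid Penalty grid; defaults to [default_lambda_grid()].
#' @param alpha Elastic-net mixing parameter.
#' @param n_bootstrap Number of bootstrap draws (the reference procedure
#'   uses 10,000; reduce for quick runs).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return Object of class `penalty_selection`: `lambda_grid`,
#'   `mean_oob_auc`, `sd_oob_auc`, `chosen_lambda`, `n_bootstrap`,
#'   `n_skipped`, `oob_fraction_mean`, `alpha`, `seed`.
#' @export
select_penalty_bootstrap <- function(x, y, lambda_grid = NULL, alpha = 0.5,
                                     n_bootstrap = 10000, seed = 1L) {
  if (n_bootstrap < 1) stop_invalid("`n_bootstrap` must be >= 1")
  x <- as.matrix(x)
  y <- as.numeric(as_case_indicator(y))
  n <- nrow(x)
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(x, y, alpha)
  if (length(lambda_grid) == 0) stop_invalid("`lambda_grid` is empty")
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)
  nl <- length(lambda_grid)

  with_seed(seed, {
    auc_sum <- numeric(nl)
    auc_sq <- numeric(nl)
    n_used <- 0L
    n_skipped <- 0L
    oob_frac <- numeric(n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      oob_frac[b] <- length(oob) / n
      if (length(unique(y[oob])) < 2 || length(unique(y[idx])) < 2) {
        n_skipped <- n_skipped + 1L
        next
      }
      xb <- x[idx, , drop = FALSE]
      centers <- colMeans(xb)
      scales <- sqrt(colMeans(sweep(xb, 2, centers)^2))
      keep <- scales > 0
      xs <- sweep(sweep(xb[, keep, drop = FALSE], 2, centers[keep]), 2,
        scales[keep],
        FUN = "/"
      )
      path <- fit_enet_path(xs, y[idx], lambda_grid, alpha)
      xo <- sweep(sweep(x[oob, keep, drop = FALSE], 2, centers[keep]), 2,
        scales[keep],
        FUN = "/"
      )
      eta <- sweep(xo %*% path$beta, 2, path$b0, FUN = "+")
      is_case <- y[oob] == 1
      n1 <- sum(is_case)
      n0 <- sum(!is_case)
      aucs <- apply(eta, 2, function(s) {
        r <- rank(s, ties.method = "average")
        (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
      })
      auc_sum <- auc_sum + aucs
      auc_sq <- auc_sq + aucs^2
      n_used <- n_used + 1L
    }
    if (n_used == 0L) stop_invalid("every bootstrap draw was degenerate")
    mean_auc <- auc_sum / n_used
    sd_auc <- sqrt(pmax(auc_sq / n_used - mean_auc^2, 0))
    best <- which(mean_auc >= max(mean_auc) - 1e-12)
    chosen <- lambda_grid[min(best)] # grid is decreasing: first = largest
    structure(
      list(
        lambda_grid = lambda_grid, mean_oob_auc = mean_auc,
        sd_oob_auc = sd_auc, chosen_lambda = chosen,
        n_bootstrap = n_bootstrap, n_used = n_used, n_skipped = n_skipped,
        oob_fraction_mean = mean(oob_frac), alpha = alpha, seed = seed
      ),
      class = "penalty_selection"
    )
  })
}

#' @export
print.penalty_selection <- function(x, ...) {
  cat(sprintf(
    "<penalty_selection> chosen lambda = %.4g (mean OOB AUC %.3f over %d draws, %d skipped)\n",
    x$chosen_lambda, max(x$mean_oob_auc), x$n_used, x$n_skipped
  ))
  invisible(x)
}

#' Finalize the multi-marker panel
#'
#' Refits the elastic-net logistic model on the full training set at the
#' selected penalty; markers whose coefficient is exactly zero are excluded
#' from the panel.
#'
#' @param x,y Full training data.
#' @param selection A `penalty_selection` (or a single numeric lambda).
#' @param alpha Elastic-net mixing parameter.
#' @return Object of class `panel_model`: `markers` (retained), `all_markers`,
#'   `coefficients` (original ng/mL scale, retained markers), `intercept`,
#'   `lambda`, `alpha`, `selection`.
#' @export
finalize_panel <- function(x, y, selection, alpha = 0.5) {
  lambda <- if (inherits(selection, "penalty_selection")) {
    selection$chosen_lambda
  } else {
    as.numeric(selection)
  }
  fit <- fit_penalized_logistic(x, y, lambda, alpha)
  nonzero <- names(fit$beta_std)[fit$beta_std != 0]
  if (length(nonzero) == 0) {
    stop_invalid("degenerate model: all marker coefficients are zero")
  }
  structure(
    list(
      markers = nonzero,
      all_markers = names(fit$coefficients),
      coefficients = fit$coefficients[nonzero],
      intercept = fit$intercept,
      lambda = lambda, alpha = alpha,
      selection = if (inherits(selection, "penalty_selection")) selection else NULL
    ),
    class = "panel_model"
  )
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf(
    "<panel_model> %d/%d markers retained (lambda = %.4g, alpha = %.2f)\n",
    length(x$markers), length(x$all_markers), x$lambda, x$alpha
  ))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Score subjects with a panel model
#'
#' @param object A `panel_model`.
#' @param newdata Cohort tibble (or matrix) containing the panel's marker
#'   columns in ng/mL.
#' @param type `"link"` (log-odds score) or `"response"` (probability).
#' @param ... Unused.
#' @return Numeric score vector.
#' @export
predict.panel_model <- function(object, newdata,
                                type = c("link", "response"), ...) {
  type <- match.arg(type)
  x <- as.matrix(as.data.frame(newdata)[, object$markers, drop = FALSE])
  if (isTRUE(object$log_transform)) x <- log(x)
  eta <- drop(object$intercept + x %*% object$coefficients)
  if (type == "link") eta else plogis(eta)
}

#' Evaluate a panel on a cohort
#'
#' Overall AUC, sensitivity at a target specificity, and AUCs of cases
#' against each named control subgroup (e.g. controls with vs without
#' pulmonary nodules). Empty subgroups are skipped with a warning.
#'
#' @param model A `panel_model`.
#' @param cohort Cohort tibble with `label` and the panel's marker columns.
#' @param subgroups Named list of logical vectors over the cohort rows;
#'   each selects a control subgroup (cases are always all cases).
#' @param target_specificity Specificity for the reported sensitivity.
#' @return List of class `panel_evaluation`: `auc`, `sens_at_spec`,
#'   `target_specificity`, `subgroup_auc` (named), `n_cases`, `n_controls`.
#' @export
evaluate_panel <- function(model, cohort, subgroups = NULL,
                           target_specificity = 0.9) {
  scores <- predict(model, cohort)
  is_case <- as_case_indicator(cohort$label)
  roc <- roc_auc(scores, is_case)
  sub_auc <- c()
  for (nm in names(subgroups)) {
    sel <- is_case | (!is_case & subgroups[[nm]])
    if (sum(!is_case & subgroups[[nm]]) == 0) {
      warning("subgroup \"", nm, "\" has no controls; skipped")
      next
    }
    sub_auc[nm] <- roc_auc(scores[sel], is_case[sel])$auc
  }
  structure(
    list(
      auc = roc$auc,
      sens_at_spec = sensitivity_at_specificity(roc, target_specificity),
      target_specificity = target_specificity,
      subgroup_auc = sub_auc,
      n_cases = roc$n_cases, n_controls = roc$n_controls,
      roc = roc
    ),
    class = "panel_evaluation"
  )
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat(sprintf(
    "<panel_evaluation> AUC = %.3f; sensitivity %.1f%% at %.0f%% specificity\n",
    x$auc, 100 * x$sens_at_spec, 100 * x$target_specificity
  ))
  for (nm in names(x$subgroup_auc)) {
    cat(sprintf("  vs %s controls: AUC = %.3f\n", nm, x$subgroup_auc[nm]))
  }
  invisible(x)
}

#' Train a panel from a cohort table
#'
#' Convenience wrapper: extracts the marker matrix, runs the bootstrap
#' penalty selection and finalizes the panel.
#'
#' @param cohort Cohort tibble with `label` and marker columns.
#' @param markers Marker column names (default: the nine reference markers
#'   present in the cohort).
#' @param alpha Elastic-net mixing parameter.
#' @param n_bootstrap Bootstrap draws for penalty selection.
#' @param log_transform Fit on natural-log concentrations instead of the
#'   raw ng/mL scale (the default mirrors the reference regression on
#'   concentrations; the log scale suits markers with strongly skewed
#'   distributions).
#' @param seed Integer seed.
#' @return A `panel_model`.
#' @export
train_panel <- function(cohort, markers = NULL, alpha = 0.5,
                        n_bootstrap = 500, log_transform = FALSE,
                        seed = 1L) {
  if (is.null(markers)) {
    markers <- intersect(marker_reference()$marker, names(cohort))
  }
  x <- as.matrix(as.data.frame(cohort)[, markers])
  if (log_transform) x <- log(x)
  y <- as_case_indicator(cohort$label)
  sel <- select_penalty_bootstrap(x, y,
    alpha = alpha,
    n_bootstrap = n_bootstrap, seed = seed
  )
  model <- finalize_panel(x, y, sel, alpha)
  model$log_transform <- log_transform
  model
}
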