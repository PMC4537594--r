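# Differential-expression screening and candidate prioritization.
#
# Peptide-ion tumor/control ratios are computed per sample pair from the
# normalized feature matrix; ions whose ratio strictly exceeds the fold
# threshold are flagged; flagged peptides are aggregated per protein and the
# published prioritization criteria applied: multiple differential peptides,
# multiple malignant samples, median ratio > 4, secreted or cell-membrane
# localization.

#' Discovery filter settings
#'
#' @param ratio_threshold Tumor/control fold-change gate (strict `>`).
#' @param min_peptides Minimum distinct differential peptides per protein
#'   ("multiple" read as >= 2).
#' @param min_samples Minimum distinct malignant samples per protein.
#' @param allowed_localizations Subcellular compartments retained.
#' @param detection_floor Linear intensity floor used for censored ratios.
#' @return A list of class `discovery_config`.
#' @export
discovery_config <- function(ratio_threshold = 4.0, min_peptides = 2,
                             min_samples = 2,
                             allowed_localizations = c("secreted", "cell_membrane"),
                             detection_floor = 500) {
  if (ratio_threshold <= 0) stop_invalid("`ratio_threshold` must be positive")
  if (min_peptides < 1 || min_samples < 1) {
    stop_invalid("minimum counts must be >= 1")
  }
  structure(
    list(
      ratio_threshold = ratio_threshold,
      min_peptides = as.integer(min_peptides),
      min_samples = as.integer(min_samples),
      allowed_localizations = allowed_localizations,
      detection_floor = detection_floor
    ),
    class = "discovery_config"
  )
}

#' Tumor/control peptide-ion ratios per sample pair
#'
#' For each tumor/control map pair and each identified feature observed in
#' the tumor map: `ratio = 2^(tumor log2 - control log2)`. When the control
#' value is missing the ratio is the censored lower bound
#' `2^tumor / detection_floor`; when the tumor value is missing no record is
#' emitted. Internal standards and unidentified features are skipped.
#'
#' @param feature_matrix A `feature_matrix` from [build_feature_matrix()].
#' @param pairs Tibble with `pair_id`, `tumor_map_id`, `control_map_id` and
#'   optionally `platform`.
#' @param detection_floor Linear intensity floor for censored ratios.
#' @return Tibble: `peptide`, `protein`, `pair_id`, `platform`, `group_id`,
#'   `ratio`, `censored`.
#' @export
compute_peptide_ratios <- function(feature_matrix, pairs,
                                   detection_floor = 500) {
  missing_maps <- setdiff(
    c(pairs$tumor_map_id, pairs$control_map_id), names(feature_matrix)
  )
  if (length(missing_maps) > 0) {
    stop_invalid(
      "pair refers to maps absent from the feature matrix: ",
      paste(missing_maps, collapse = ", ")
    )
  }
  keep <- !feature_matrix$is_internal_standard &
    !is.na(feature_matrix$peptide) & !is.na(feature_matrix$protein)
  fm <- feature_matrix[keep, ]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    t_log2 <- fm[[pairs$tumor_map_id[i]]]
    c_log2 <- fm[[pairs$control_map_id[i]]]
    obs_t <- !is.na(t_log2)
    censored <- obs_t & is.na(c_log2)
    ratio <- ifelse(
      censored,
      2^t_log2 / detection_floor,
      2^(t_log2 - c_log2)
    )
    tibble(
      peptide = fm$peptide[obs_t],
      protein = fm$protein[obs_t],
      pair_id = pairs$pair_id[i],
      platform = if ("platform" %in% names(pairs)) pairs$platform[i] else NA_character_,
      group_id = fm$group_id[obs_t],
      ratio = ratio[obs_t],
      censored = censored[obs_t]
    )
  })
  bind_rows(rows)
}

#' Flag differentially expressed peptides
#'
#' Retains records whose tumor/control ratio strictly exceeds the threshold.
#' Censored records (control below the detection floor) are retained iff
#' their lower bound exceeds the threshold. Down-regulated peptides never
#' pass: the screen targets elevated expression.
#'
#' @param ratios Output of [compute_peptide_ratios()].
#' @param config A [discovery_config()].
#' @return The subset of `ratios` passing the fold gate.
#' @export
flag_differential_peptides <- function(ratios, config = discovery_config()) {
  ratios[ratios$ratio > config$ratio_threshold, ]
}

#' Aggregate differential peptides to candidate proteins
#'
#' Per protein: distinct differential peptides, distinct malignant samples,
#' the median of all differential peptide ratios (censored values enter at
#' their lower bound), and the set of platforms where at least one
#' differential peptide was observed. Localization is joined from the
#' annotation table; unannotated accessions become `"other"` with a warning.
#'
#' @param peptides Flagged peptides from [flag_differential_peptides()].
#' @param annotations Tibble with `accession` and `localization`.
#' @param method `"pooled"` (default): one median over all peptide ratios;
#'   `"per_sample"`: median of per-sample medians.
#' @return Tibble of candidate proteins.
#' @export
aggregate_to_protein <- function(peptides, annotations,
                                 method = c("pooled", "per_sample")) {
  method <- match.arg(method)
  med <- if (method == "pooled") {
    function(d) median(d$ratio)
  } else {
    function(d) {
      median(tapply(d$ratio, d$pair_id, median))
    }
  }
  out <- peptides %>%
    group_by(accession = .data$protein) %>%
    summarise(
      n_peptides = n_distinct(.data$peptide),
      peptides = list(sort(unique(.data$peptide))),
      n_samples = n_distinct(.data$pair_id),
      median_ratio = med(dplyr::pick(dplyr::everything())),
      platforms = list(sort(unique(.data$platform[!is.na(.data$platform)]))),
      .groups = "drop"
    ) %>%
    left_join(annotations[, c("accession", "localization")], by = "accession")
  if (anyNA(out$localization)) {
    missing <- out$accession[is.na(out$localization)]
    warning(
      "no annotation for ", length(missing),
      " accession(s); localization set to \"other\": ",
      paste(head(missing, 5), collapse = ", ")
    )
    out$localization[is.na(out$localization)] <- "other"
  }
  arrange(out, .data$accession)
}

#' Apply the candidate prioritization filters
#'
#' Retains proteins with (i) more than one distinct differential peptide,
#' (ii) differential peptides in more than one malignant sample,
#' (iii) median cancer:control ratio strictly above the fold threshold, and
#' (iv) secreted or cell-membrane localization. The returned table carries a
#' per-criterion pass/fail audit trail; the four criteria commute, so their
#' order never changes the retained set.
#'
#' @param candidates Output of [aggregate_to_protein()].
#' @param config A [discovery_config()].
#' @return `candidates` with logical columns `pass_peptides`,
#'   `pass_samples`, `pass_ratio`, `pass_localization` and `retained`.
#' @export
apply_prioritization_filters <- function(candidates,
                                         config = discovery_config()) {
  candidates %>%
    mutate(
      pass_peptides = .data$n_peptides >= config$min_peptides,
      pass_samples = .data$n_samples >= config$min_samples,
      pass_ratio = .data$median_ratio > config$ratio_threshold,
      pass_localization = .data$localization %in% config$allowed_localizations,
      retained = .data$pass_peptides & .data$pass_samples &
        .data$pass_ratio & .data$pass_localization
    )
}

#' Run the discovery screen for one platform
#'
#' @param feature_matrix A `feature_matrix`.
#' @param pairs Pair assignment table (see [compute_peptide_ratios()]).
#' @param annotations Annotation table with `accession`, `localization`.
#' @param config A [discovery_config()].
#' @return Candidate table with audit columns (see
#'   [apply_prioritization_filters()]).
#' @export
discover_candidates <- function(feature_matrix, pairs, annotations,
                                config = discovery_config()) {
  ratios <- compute_peptide_ratios(feature_matrix, pairs, config$detection_floor)
  flagged <- flag_differential_peptides(ratios, config)
  if (nrow(flagged) == 0) {
    return(tibble(
      accession = character(0), n_peptides = integer(0),
      peptides = list(), n_samples = integer(0), median_ratio = numeric(0),
      platforms = list(), localization = character(0),
      pass_peptides = logical(0), pass_samples = logical(0),
      pass_ratio = logical(0), pass_localization = logical(0),
      retained = logical(0)
    ))
  }
  candidates <- aggregate_to_protein(flagged, annotations)
  apply_prioritization_filters(candidates, config)
}
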