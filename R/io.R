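# File formats: ion maps and feature matrices as TSV, cohorts as CSV,
# models and evaluations as JSON, configs as YAML. Writers emit '#'-prefixed
# provenance comments (tool version, seed, config hash) that all readers
# skip.

ION_MAP_COLUMNS <- c(
  "map_id", "sample_id", "condition", "platform", "paired_map_id",
  "ion_id", "mz", "rt", "z", "intensity", "peptide", "protein",
  "is_internal_standard"
)

provenance_header <- function(seed = NULL, config_hash = NULL) {
  c(
    paste0(
      "# lcmspanel ",
      as.character(utils::packageVersion("lcmspanel"))
    ),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (!is.null(config_hash)) paste0("# config_hash: ", config_hash)
  )
}

write_with_header <- function(tbl, path, delim, seed = NULL,
                              config_hash = NULL) {
  writeLines(provenance_header(seed, config_hash), path)
  readr::write_delim(tbl, path, delim = delim, na = "", append = TRUE,
    col_names = TRUE)
  invisible(path)
}

#' Write ion maps to TSV
#'
#' One file holds any number of maps; map-level metadata is repeated per
#' row. A '#'-prefixed provenance header is prepended.
#'
#' @param maps List of `ion_map` objects (or a single one).
#' @param path Output file path.
#' @param seed,config_hash Optional provenance fields.
#' @return The path, invisibly.
#' @export
write_ion_maps <- function(maps, path, seed = NULL, config_hash = NULL) {
  if (inherits(maps, "ion_map")) maps <- list(maps)
  tbl <- bind_rows(lapply(maps, function(m) {
    dplyr::bind_cols(
      tibble(
        map_id = m$map_id, sample_id = m$sample_id, condition = m$condition,
        platform = m$platform,
        paired_map_id = m$paired_map_id %||% NA_character_
      ),
      m$ions
    )[, ION_MAP_COLUMNS]
  }))
  write_with_header(tbl, path, "\t", seed, config_hash)
}

#' Read ion maps from TSV
#'
#' Skips '#'-prefixed provenance comments. A missing required column is a
#' schema error; rows violating the ion invariants (`mz > 0`, `z >= 1`,
#' `intensity >= 0`) are dropped with a warning naming their 1-based data
#' line numbers.
#'
#' @param path TSV file written by [write_ion_maps()].
#' @return Named list of `ion_map` objects.
#' @export
read_ion_maps <- function(path) {
  header <- readr::read_tsv(
    path,
    comment = "#", n_max = 0, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = "c")
  )
  missing_cols <- setdiff(ION_MAP_COLUMNS, names(header))
  if (length(missing_cols) > 0) {
    stop_invalid(
      "schema error: missing column(s) ", paste(missing_cols, collapse = ", ")
    )
  }
  tbl <- readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      mz = "d", rt = "d", z = "i", intensity = "d",
      is_internal_standard = "l", .default = "c"
    )
  )
  if (nrow(tbl) == 0) {
    return(list())
  }
  bad <- which(
    !(tbl$mz > 0) | !(tbl$z >= 1) | !(tbl$intensity >= 0) |
      is.na(tbl$mz) | is.na(tbl$z) | is.na(tbl$intensity)
  )
  if (length(bad) > 0) {
    warning(
      "rejected ", length(bad), " malformed row(s) at data line(s): ",
      paste(bad, collapse = ", ")
    )
    tbl <- tbl[-bad, ]
  }
  maps <- lapply(split(tbl, tbl$map_id), function(d) {
    new_ion_map(
      map_id = d$map_id[1], sample_id = d$sample_id[1],
      condition = d$condition[1], platform = d$platform[1],
      paired_map_id = if (is.na(d$paired_map_id[1])) NULL else d$paired_map_id[1],
      ions = tibble(
        ion_id = d$ion_id, mz = d$mz, rt = d$rt, z = d$z,
        intensity = d$intensity, peptide = d$peptide, protein = d$protein,
        is_internal_standard = d$is_internal_standard
      )
    )
  })
  maps[order(names(maps))]
}

#' Write / read a feature matrix as TSV
#'
#' @param feature_matrix A `feature_matrix`.
#' @param path File path.
#' @param seed,config_hash Optional provenance fields.
#' @return The path ([write_feature_matrix()]) or a tibble
#'   ([read_feature_matrix()]).
#' @export
write_feature_matrix <- function(feature_matrix, path, seed = NULL,
                                 config_hash = NULL) {
  write_with_header(feature_matrix, path, "\t", seed, config_hash)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Write / read a subject cohort as CSV
#'
#' @param cohort Cohort tibble (see [generate_serum_cohort()]).
#' @param path File path.
#' @param seed,config_hash Optional provenance fields.
#' @return The path ([write_cohort()]) or a tibble ([read_cohort()]).
#' @export
write_cohort <- function(cohort, path, seed = NULL, config_hash = NULL) {
  write_with_header(cohort, path, ",", seed, config_hash)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Serialize / restore a panel model as JSON
#'
#' The round trip reproduces scores bit-exactly: coefficients are written
#' at full precision.
#'
#' @param model A `panel_model`.
#' @param path JSON file path.
#' @return The path ([write_panel_model()]) or a `panel_model`
#'   ([read_panel_model()]).
#' @export
write_panel_model <- function(model, path) {
  payload <- list(
    markers = model$markers,
    all_markers = model$all_markers,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    lambda = model$lambda,
    alpha = model$alpha,
    log_transform = isTRUE(model$log_transform),
    seed = model$selection$seed,
    n_bootstrap = model$selection$n_bootstrap
  )
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_panel_model
#' @export
read_panel_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      markers = p$markers,
      all_markers = p$all_markers,
      coefficients = unlist(p$coefficients),
      intercept = p$intercept,
      lambda = p$lambda, alpha = p$alpha,
      log_transform = isTRUE(p$log_transform),
      selection = NULL
    ),
    class = "panel_model"
  )
}

#' Write an evaluation report as JSON
#'
#' @param evaluation A `panel_evaluation`.
#' @param path JSON file path.
#' @return The path, invisibly.
#' @export
write_evaluation <- function(evaluation, path) {
  payload <- list(
    auc = evaluation$auc,
    sens_at_spec = evaluation$sens_at_spec,
    target_specificity = evaluation$target_specificity,
    subgroup_auc = as.list(evaluation$subgroup_auc),
    n_cases = evaluation$n_cases,
    n_controls = evaluation$n_controls
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize / restore RT warps as JSON
#'
#' @param warps Named list of `rt_warp` objects.
#' @param path JSON file path.
#' @return The path ([write_rt_warps()]) or a named list
#'   ([read_rt_warps()]).
#' @export
write_rt_warps <- function(warps, path) {
  payload <- lapply(warps, function(w) {
    out <- unclass(w)
    out$anchors <- NULL
    out
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rt_warps
#' @export
read_rt_warps <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(p, function(w) {
    do.call(new_rt_warp, c(list(map_id = w$map_id, kind = w$kind),
      w[setdiff(names(w), c("map_id", "kind"))]))
  })
}
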