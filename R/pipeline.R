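# One-call demo pipeline: simulate -> align -> discover -> integrate ->
# verify -> train -> evaluate, with deterministic seeding and provenance.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations with a global seed. Stage seeds are
#' derived deterministically from the global seed, so a rerun with the same
#' configuration is bit-identical.
#'
#' @param seed Global integer seed.
#' @param n_proteins Proteins per simulated platform proteome.
#' @param frac_differential Fraction of spiked differential proteins.
#' @param map_config A [map_sim_config()] (its seed is overridden by the
#'   derived stage seed).
#' @param alignment A [alignment_config()].
#' @param discovery A [discovery_config()].
#' @param cohort A [cohort_sim_config()] (seed overridden likewise).
#' @param alpha Elastic-net mixing parameter for the panel.
#' @param n_bootstrap Bootstrap draws for penalty selection (demo scale).
#' @param out_dir Optional output directory for artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_proteins = 60,
                            frac_differential = 0.15,
                            map_config = map_sim_config(n_pairs = 3),
                            alignment = alignment_config(),
                            discovery = discovery_config(),
                            cohort = cohort_sim_config(),
                            alpha = 0.5,
                            n_bootstrap = 100,
                            out_dir = NULL) {
  structure(
    list(
      seed = as.integer(seed), n_proteins = n_proteins,
      frac_differential = frac_differential, map_config = map_config,
      alignment = alignment, discovery = discovery, cohort = cohort,
      alpha = alpha, n_bootstrap = n_bootstrap, out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [pipeline_config()] and of the nested stage configs can
#' be overridden from a YAML file; unspecified fields keep their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(defaults, overrides) {
    for (nm in intersect(names(overrides), names(defaults))) {
      defaults[[nm]] <- overrides[[nm]]
    }
    defaults
  }
  map_cfg <- do.call(map_sim_config, take(
    formals_defaults(map_sim_config), y$map_config %||% list()
  ))
  args <- y[intersect(names(y), c(
    "seed", "n_proteins", "frac_differential", "alpha", "n_bootstrap",
    "out_dir"
  ))]
  do.call(pipeline_config, c(args, list(map_config = map_cfg)))
}

formals_defaults <- function(f) {
  d <- formals(f)
  d <- d[!vapply(d, is.symbol, logical(1))]
  lapply(d, eval, envir = environment(f))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage \"", name, "\" failed: ", conditionMessage(e),
      call. = FALSE
    )
  })
}

#' Run the full demo pipeline
#'
#' Simulates the three discovery platforms, aligns and normalizes the ion
#' maps, screens and prioritizes candidates, integrates them across
#' platforms, simulates and verifies a serum cohort, trains the penalized
#' panel with bootstrap penalty selection, and evaluates it on an
#' independently simulated test cohort with nodule/no-nodule control
#' subgroups. A stage failure aborts with the failing stage named. All
#' artifacts are returned in one bundle (and written under
#' `config$out_dir` when set, stamped with the config hash and seed).
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_bundle`: per-platform `candidates`,
#'   `membership`, `venn`, `marker_summary`, `panel`, `evaluation`,
#'   `score_size_correlation`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- rlang::hash(unclass(config))
  platforms <- c("tissue", "cell_line", "conditioned_medium")

  # one shared proteome: the same biology assayed by all three platforms
  proteome <- run_stage("simulate_proteome", generate_proteome(
    config$n_proteins, config$frac_differential,
    seed = derive_seed(config$seed, 1)
  ))
  annotations <- tibble(
    accession = proteome$accession,
    localization = proteome$localization
  )

  discovered <- run_stage("discover", {
    lapply(seq_along(platforms), function(i) {
      pf <- platforms[i]
      mc <- config$map_config
      mc$seed <- derive_seed(config$seed, 100 + i)
      sim <- generate_platform_maps(proteome, mc, platform = pf)
      aligned <- align_maps(
        sim$maps,
        internal_standards(mc$n_standards, mc$rt_range),
        config$alignment
      )
      cands <- discover_candidates(
        aligned$feature_matrix, sim$pairs, annotations, config$discovery
      )
      list(
        platform = pf,
        feature_matrix = aligned$feature_matrix, candidates = cands
      )
    })
  })
  names(discovered) <- platforms

  integration <- run_stage("integrate", {
    retained <- lapply(discovered, function(d) {
      d$candidates$accession[d$candidates$retained]
    })
    membership <- integrate_platforms(retained)
    list(membership = membership, venn = venn_partition(membership))
  })

  cohort_cfg <- config$cohort
  cohort_cfg$seed <- derive_seed(config$seed, 200)
  train_cohort <- run_stage("simulate_cohort", generate_serum_cohort(cohort_cfg))
  marker_summary <- run_stage(
    "verify",
    verify_markers(train_cohort, cohort_cfg$markers$marker)
  )

  panel <- run_stage("train", train_panel(
    train_cohort,
    markers = cohort_cfg$markers$marker,
    alpha = config$alpha, n_bootstrap = config$n_bootstrap,
    seed = derive_seed(config$seed, 300)
  ))

  test_cfg <- config$cohort
  test_cfg$n_cases <- 50L
  test_cfg$n_controls <- 50L
  test_cfg$control_nodule_rate <- 0.44
  test_cfg$seed <- derive_seed(config$seed, 400)
  test_cohort <- run_stage("simulate_test_cohort", generate_serum_cohort(test_cfg))
  evaluation <- run_stage("evaluate", {
    has_nodule <- !is.na(test_cohort$nodule_size_cm)
    evaluate_panel(
      panel, test_cohort,
      subgroups = list(nodule = has_nodule, no_nodule = !has_nodule)
    )
  })
  scores <- predict(panel, test_cohort)
  is_case <- as_case_indicator(test_cohort$label)
  size_cor <- run_stage("correlate", correlate_score_covariate(
    scores[is_case], test_cohort$nodule_size_cm[is_case]
  ))

  bundle <- structure(
    list(
      proteome = proteome,
      candidates = lapply(discovered, `[[`, "candidates"),
      feature_matrices = lapply(discovered, `[[`, "feature_matrix"),
      membership = integration$membership,
      venn = integration$venn,
      train_cohort = train_cohort,
      marker_summary = marker_summary,
      panel = panel,
      test_cohort = test_cohort,
      evaluation = evaluation,
      score_size_correlation = size_cor,
      config_hash = hash,
      seed = config$seed
    ),
    class = "pipeline_bundle"
  )

  if (!is.null(config$out_dir)) {
    run_stage("write_artifacts", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      for (pf in platforms) {
        write_feature_matrix(
          discovered[[pf]]$feature_matrix,
          file.path(config$out_dir, paste0("features_", pf, ".tsv")),
          seed = config$seed, config_hash = hash
        )
      }
      write_cohort(
        train_cohort, file.path(config$out_dir, "train_cohort.csv"),
        seed = config$seed, config_hash = hash
      )
      write_panel_model(panel, file.path(config$out_dir, "panel_model.json"))
      write_evaluation(evaluation, file.path(config$out_dir, "evaluation.json"))
    })
  }
  bundle
}
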