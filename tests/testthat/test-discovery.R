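# minimal hand-built feature matrix: 2 maps (tumor/control), given log2 values
fm_from_values <- function(tumor_log2, control_log2, peptide = NULL,
                           protein = NULL) {
  n <- length(tumor_log2)
  fm <- tibble::tibble(
    group_id = sprintf("G%03d", seq_len(n)),
    mz = 500 + seq_len(n), rt = seq_len(n), z = 2L,
    peptide = peptide %||% sprintf("PEP%03d", seq_len(n)),
    protein = protein %||% sprintf("PRO%03d", seq_len(n)),
    is_internal_standard = FALSE, n_maps = 2L,
    T1 = tumor_log2, C1 = control_log2
  )
  class(fm) <- c("feature_matrix", class(fm))
  fm
}

one_pair <- tibble::tibble(
  pair_id = "P1", tumor_map_id = "T1", control_map_id = "C1",
  platform = "tissue"
)

test_that("peptide ratios follow the log2 difference and censoring rules", {
  fm <- fm_from_values(
    tumor_log2 = c(5, 4, log2(80), NA),
    control_log2 = c(3, 4, NA, 2)
  )
  r <- compute_peptide_ratios(fm, one_pair, detection_floor = 10)
  expect_equal(nrow(r), 3) # tumor-missing row emits nothing
  expect_equal(r$ratio[1], 4.0) # 2^(5-3)
  expect_false(r$censored[1])
  expect_equal(r$ratio[2], 1.0)
  expect_equal(r$ratio[3], 8.0) # 80 / floor 10, censored
  expect_true(r$censored[3])
  expect_error(
    compute_peptide_ratios(fm, tibble::tibble(
      pair_id = "PX", tumor_map_id = "T9", control_map_id = "C1"
    )),
    "absent"
  )
})

test_that("the fold gate is strict and one-sided", {
  r <- tibble::tibble(
    peptide = letters[1:4], protein = letters[1:4], pair_id = "P1",
    platform = "tissue", group_id = letters[1:4],
    ratio = c(4.01, 4.00, 0.1, 8), censored = c(FALSE, FALSE, FALSE, TRUE)
  )
  kept <- flag_differential_peptides(r, discovery_config())
  expect_setequal(kept$peptide, c("a", "d")) # 4.00 and the down-regulated drop
})

test_that("protein aggregation pools peptides, samples and the median", {
  peps <- tibble::tibble(
    peptide = c("p1", "p2", "p3", "p1"),
    protein = c("TIMP1like", "TIMP1like", "TIMP1like", "SOLO"),
    pair_id = c("P1", "P2", "P1", "P1"),
    platform = c("tissue", "tissue", "cell_line", "tissue"),
    group_id = paste0("G", 1:4),
    ratio = c(2, 8, 32, 50),
    censored = FALSE
  )
  ann <- tibble::tibble(
    accession = "TIMP1like", localization = "secreted"
  )
  expect_warning(
    cands <- aggregate_to_protein(peps, ann),
    "localization"
  )
  t1 <- cands[cands$accession == "TIMP1like", ]
  expect_equal(t1$n_peptides, 3L)
  expect_equal(t1$n_samples, 2L)
  expect_equal(t1$median_ratio, 8) # median of {2, 8, 32}
  expect_equal(t1$platforms[[1]], c("cell_line", "tissue"))
  solo <- cands[cands$accession == "SOLO", ]
  expect_equal(solo$n_peptides, 1L)
  expect_equal(solo$n_samples, 1L)
  expect_equal(solo$localization, "other") # unannotated
})

test_that("a protein whose peptide ratios have median 34.6 reports 34.6", {
  peps <- tibble::tibble(
    peptide = paste0("p", 1:3), protein = "TIMP1", pair_id = "P1",
    platform = "tissue", group_id = paste0("G", 1:3),
    ratio = c(20.0, 34.6, 80.0), censored = FALSE
  )
  cands <- aggregate_to_protein(
    peps, tibble::tibble(accession = "TIMP1", localization = "secreted")
  )
  expect_equal(cands$median_ratio, 34.6)
})

test_that("prioritization filters encode the four published criteria", {
  cands <- tibble::tibble(
    accession = c("MDKlike", "ONEPEP", "WRONGLOC", "LOWRATIO"),
    n_peptides = c(2L, 1L, 3L, 3L),
    peptides = list("x", "x", "x", "x"),
    n_samples = c(2L, 5L, 3L, 3L),
    median_ratio = c(4.9, 50, 20, 4.0),
    platforms = list("tissue", "tissue", "tissue", "tissue"),
    localization = c("secreted", "secreted", "other", "secreted")
  )
  out <- apply_prioritization_filters(cands, discovery_config())
  expect_equal(out$retained, c(TRUE, FALSE, FALSE, FALSE))
  expect_false(out$pass_peptides[2])
  expect_false(out$pass_localization[3])
  expect_false(out$pass_ratio[4]) # boundary 4.0 excluded (strict >)
})

test_that("raising the fold threshold only shrinks the retained set", {
  set.seed(61)
  cands <- tibble::tibble(
    accession = sprintf("P%03d", 1:60),
    n_peptides = sample(1:5, 60, TRUE),
    peptides = replicate(60, "x", simplify = FALSE),
    n_samples = sample(1:5, 60, TRUE),
    median_ratio = exp(rnorm(60, log(5), 1)),
    platforms = replicate(60, "tissue", simplify = FALSE),
    localization = sample(c("secreted", "cell_membrane", "other"), 60, TRUE)
  )
  prev <- NULL
  for (thr in c(2, 4, 8, 16)) {
    cfg <- discovery_config(ratio_threshold = thr)
    kept <- apply_prioritization_filters(cands, cfg)
    kept <- kept$accession[kept$retained]
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("filter criteria commute", {
  set.seed(62)
  cands <- tibble::tibble(
    accession = sprintf("P%03d", 1:40),
    n_peptides = sample(1:4, 40, TRUE),
    peptides = replicate(40, "x", simplify = FALSE),
    n_samples = sample(1:4, 40, TRUE),
    median_ratio = exp(rnorm(40, log(5), 1)),
    platforms = replicate(40, "tissue", simplify = FALSE),
    localization = sample(c("secreted", "other"), 40, TRUE)
  )
  cfg <- discovery_config()
  full <- apply_prioritization_filters(cands, cfg)
  # apply single criteria as independent subsets in shuffled orders
  crits <- list(
    function(d) d[d$n_peptides >= cfg$min_peptides, ],
    function(d) d[d$n_samples >= cfg$min_samples, ],
    function(d) d[d$median_ratio > cfg$ratio_threshold, ],
    function(d) d[d$localization %in% cfg$allowed_localizations, ]
  )
  for (ord in list(1:4, 4:1, c(2, 4, 1, 3))) {
    d <- cands
    for (k in ord) d <- crits[[k]](d)
    expect_setequal(d$accession, full$accession[full$retained])
  }
})

test_that("noise-only screens flag what an independent recount flags", {
  set.seed(63)
  n <- 2000
  noise_sd <- 0.3
  t_log2 <- rnorm(n, 10, 1)
  c_log2 <- t_log2 - rnorm(n, 0, noise_sd) # true fold 1 plus noise
  fm <- fm_from_values(t_log2, c_log2)
  r <- compute_peptide_ratios(fm, one_pair, detection_floor = 1)
  flagged <- flag_differential_peptides(r, discovery_config())
  # independent recount straight from the generated values
  expect_equal(nrow(flagged), sum(2^(t_log2 - c_log2) > 4))
})

test_that("spiked proteins are recovered and nulls rejected end to end", {
  # one platform, censoring-driven missingness (the regime the censored
  # lower-bound rule is designed for)
  pro <- generate_proteome(60, frac_differential = 0.2, fold_change = 8, seed = 21)
  cfg <- map_sim_config(n_pairs = 3, noise_sd = 0.25, dropout_rate = 0, seed = 22)
  sim <- generate_platform_maps(pro, cfg, "tissue")
  al <- align_maps(sim$maps, internal_standards(), refine = FALSE)
  ann <- tibble::tibble(
    accession = pro$accession, localization = pro$localization
  )
  cands <- discover_candidates(al$feature_matrix, sim$pairs, ann)
  truth_diff <- pro$accession[pro$true_fold_change > 1]
  retained <- cands$accession[cands$retained]
  expect_gte(mean(truth_diff %in% retained), 0.9)
  nulls <- setdiff(pro$accession, truth_diff)
  expect_lte(mean(nulls %in% retained), 0.05)
})
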