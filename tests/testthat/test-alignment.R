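test_that("the primary warp recovers identity and pure shifts", {
  std <- internal_standards()
  m_id <- make_standard_map("A", std$reference_rt)
  w <- fit_primary_rt_warp(m_id, std)
  expect_equal(w$slope, 1, tolerance = 1e-10)
  expect_equal(w$intercept, 0, tolerance = 1e-9)

  m_shift <- make_standard_map("B", std$reference_rt + 2)
  w2 <- fit_primary_rt_warp(m_shift, std)
  expect_equal(w2$slope, 1, tolerance = 1e-10)
  expect_equal(w2$intercept, -2, tolerance = 1e-9)
  expect_equal(
    apply_rt_warp(w2, std$reference_rt + 2), std$reference_rt,
    tolerance = 1e-9
  )
})

test_that("the primary warp equals the closed-form least-squares solution", {
  std <- tibble::tibble(
    peptide = c("S1", "S2", "S3"), reference_rt = c(1.1, 5.3, 9.9)
  )
  m <- make_map("A",
    mz = c(400, 500, 600), rt = c(1, 5, 9),
    peptide = std$peptide, is_standard = TRUE
  )
  w <- fit_primary_rt_warp(m, std)
  # independent simple-regression arithmetic (reference ~ observed)
  x <- c(1, 5, 9)
  y <- c(1.1, 5.3, 9.9)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(w$slope, slope, tolerance = 1e-12)
  expect_equal(w$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
})

test_that("too few anchors is an error", {
  std <- internal_standards()
  m <- make_standard_map("A", std$reference_rt[1])
  expect_error(fit_primary_rt_warp(m, std), "insufficient anchors")
})

test_that("co-located ions across maps form one group; charge separates", {
  maps <- list(
    A = make_map("A", mz = 500.0, rt = 10),
    B = make_map("B", mz = 500.000001, rt = 10.1),
    C = make_map("C", mz = 500.000002, rt = 9.95)
  )
  g <- match_ions(maps)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_maps, 3L)

  maps_z <- list(
    A = make_map("A", mz = 500.0, rt = 10, z = 2L),
    B = make_map("B", mz = 500.0, rt = 10, z = 3L)
  )
  g2 <- match_ions(maps_z)
  expect_equal(nrow(g2), 2) # identical coordinates, different charge
})

test_that("grouping equals exhaustive minimum-distance matching", {
  cfg <- alignment_config(mz_tol_ppm = 10, rt_tol_min = 1.0)
  set.seed(55)
  for (rep in 1:12) {
    # a few well-separated features plus one ambiguous close competitor
    base_mz <- 400 + cumsum(runif(4, 1, 3))
    a_mz <- c(base_mz, base_mz[2] + base_mz[2] * 3e-6)
    a_rt <- c(10, 12, 14, 16, 12.3)
    b_mz <- base_mz + base_mz * runif(4, -2e-6, 2e-6)
    b_rt <- c(10, 12, 14, 16) + runif(4, -0.3, 0.3)
    a <- tibble::tibble(mz = a_mz, rt = a_rt, z = 2L)
    b <- tibble::tibble(mz = b_mz, rt = b_rt, z = 2L)
    got <- match_ions(
      list(
        A = make_map("A", mz = a$mz, rt = a$rt),
        B = make_map("B", mz = b$mz, rt = b$rt)
      ),
      cfg
    )
    members <- attr(got, "members")
    matched <- members |>
      dplyr::group_by(group_id) |>
      dplyr::filter(dplyr::n() == 2) |>
      dplyr::summarise(
        a = ion_id[map_id == "A"], b = ion_id[map_id == "B"]
      )
    oracle <- oracle_two_map_matching(a, b, cfg$mz_tol_ppm, cfg$rt_tol_min)
    oracle_pairs <- sort(vapply(
      oracle,
      function(p) paste(sprintf("A_%03d", p[1]), sprintf("B_%03d", p[2])),
      character(1)
    ))
    expect_identical(sort(paste(matched$a, matched$b)), oracle_pairs)
  }
})

test_that("matching is input-order independent", {
  set.seed(9)
  mz <- 500 + cumsum(runif(6, 0.5, 2))
  maps1 <- list(
    A = make_map("A", mz = mz, rt = 1:6),
    B = make_map("B", mz = mz, rt = 1:6 + 0.1)
  )
  maps2 <- maps1
  maps2$A$ions <- maps2$A$ions[sample(6), ]
  g1 <- match_ions(maps1)
  g2 <- match_ions(maps2)
  m1 <- attr(g1, "members")
  m2 <- attr(g2, "members")
  key <- function(m) {
    s <- split(paste(m$map_id, m$ion_id), m$group_id)
    sort(vapply(s, function(v) paste(sort(v), collapse = "|"), character(1)))
  }
  expect_identical(unname(key(m1)), unname(key(m2)))
})

test_that("secondary refinement corrects an injected quadratic drift", {
  std <- internal_standards()
  set.seed(17)
  mz <- 420 + cumsum(runif(40, 0.5, 1.5))
  rt_ref <- seq(6, 58, length.out = 40)
  build <- function(id, warp_fun) {
    m <- make_map(id, mz = c(mz, std$mz), rt = warp_fun(c(rt_ref, std$reference_rt)),
      z = 2L,
      peptide = c(sprintf("PEP%03d", 1:40), std$peptide),
      is_standard = c(rep(FALSE, 40), rep(TRUE, nrow(std)))
    )
    m
  }
  maps <- list(
    A = build("A", identity),
    B = build("B", function(rt) rt + 0.02 * (rt - 30)^2 / 30 + 0.5),
    C = build("C", function(rt) 0.98 * rt - 0.4)
  )
  cfg <- alignment_config()
  warps <- lapply(maps, fit_primary_rt_warp, std)
  refined <- refine_rt_secondary(maps, warps, cfg, max_iter = 4)
  warped <- lcmspanel:::apply_warps_to_maps(maps, refined)
  # non-standard features should land within the RT tolerance of consensus
  g <- match_ions(warped, cfg)
  members <- attr(g, "members")
  members <- members[!members$is_internal_standard & members$n_maps_in_group >= 2, ]
  resid <- abs(members$rt - members$consensus_rt)
  expect_lt(median(resid), 0.1)
  expect_lt(max(resid), cfg$rt_tol_min)
  # monotonicity: warped RT order preserved within each map
  for (m in warped) {
    ord_raw <- order(m$ions$rt_raw)
    expect_true(all(diff(m$ions$rt[ord_raw]) > 0))
  }
})

test_that("refinement without a partner or common features is a no-op", {
  std <- internal_standards()
  m <- make_standard_map("A", std$reference_rt)
  w <- list(A = fit_primary_rt_warp(m, std))
  expect_identical(refine_rt_secondary(list(A = m), w), w)
})

test_that("normalization recovers pure per-map scale factors", {
  mz <- 500 + (1:5)
  a <- make_map("A", mz = mz, rt = 1:5, intensity = c(10, 20, 40, 80, 160))
  b <- make_map("B", mz = mz, rt = 1:5, intensity = 4 * c(10, 20, 40, 80, 160))
  g <- match_ions(list(A = a, B = b))
  norm <- normalize_intensities(g, list(A = a, B = b))
  expect_equal(sum(norm$offsets), 0, tolerance = 1e-12)
  expect_equal(unname(diff(norm$offsets)), -2, tolerance = 1e-9) # log2(4)
  ratios <- norm$matrix[, "B"] - norm$matrix[, "A"]
  expect_equal(unname(ratios), rep(0, 5), tolerance = 1e-9)

  # two identical maps: zero offsets, matrix unchanged
  a2 <- make_map("A2", mz = mz, rt = 1:5, intensity = c(10, 20, 40, 80, 160))
  g2 <- match_ions(list(A = a, A2 = a2))
  norm2 <- normalize_intensities(g2, list(A = a, A2 = a2))
  expect_equal(unname(norm2$offsets), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(norm2$matrix[, "A"]), log2(c(10, 20, 40, 80, 160)),
    tolerance = 1e-12
  )
})

test_that("offsets match a numerical brute-force minimizer", {
  set.seed(44)
  for (rep in 1:5) {
    x <- matrix(rnorm(12, 10, 2), 3, 4,
      dimnames = list(NULL, c("A", "B", "C", "D"))
    )
    x[sample(12, 2)] <- NA # some missingness
    if (!any(rowSums(!is.na(x)) >= 2)) next
    # wrap the fixed matrix in ion maps via a synthetic member table
    maps <- lapply(colnames(x), function(id) {
      obs <- !is.na(x[, id])
      make_map(id, mz = (500 + (1:3))[obs], rt = (1:3)[obs],
        intensity = 2^x[obs, id]
      )
    })
    names(maps) <- colnames(x)
    g <- match_ions(maps)
    norm <- normalize_intensities(g, maps)
    oracle <- oracle_normalization_offsets(
      lcmspanel:::build_log2_matrix(g, maps)
    )
    expect_equal(unname(norm$offsets), oracle, tolerance = 1e-6)
    # optimality: objective no worse than at zero offsets
    obj0 <- {
      xm <- lcmspanel:::build_log2_matrix(g, maps)
      m <- rowMeans(xm, na.rm = TRUE)
      sum((xm - m)^2, na.rm = TRUE)
    }
    expect_lte(norm$objective, obj0 + 1e-12)
  }
})

test_that("post-normalization ratios are invariant to per-map rescaling", {
  set.seed(70)
  mz <- 500 + (1:6)
  base <- runif(6, 1e4, 1e6)
  factors <- c(1, 7.3, 0.2)
  maps <- lapply(1:3, function(k) {
    make_map(LETTERS[k],
      mz = mz, rt = 1:6,
      intensity = base * factors[k] * exp(rnorm(6, 0, 0.1) * 0)
    )
  })
  names(maps) <- LETTERS[1:3]
  g <- match_ions(maps)
  norm <- normalize_intensities(g, maps)
  # all maps identical up to scale: normalized columns coincide
  expect_equal(unname(norm$matrix[, 2] - norm$matrix[, 1]), rep(0, 6),
    tolerance = 1e-8
  )
  expect_equal(unname(norm$matrix[, 3] - norm$matrix[, 1]), rep(0, 6),
    tolerance = 1e-8
  )
})

test_that("degenerate normalization inputs are rejected", {
  a <- make_map("A", mz = 500, rt = 1)
  expect_error(normalize_intensities(NULL, list(A = a)), "at least 2 maps")
  b <- make_map("B", mz = 900, rt = 9)
  g <- match_ions(list(A = a, B = b)) # disjoint: no shared group
  expect_error(normalize_intensities(g, list(A = a, B = b)), "unidentifiable")
})

test_that("the feature matrix carries groups, maps and missingness", {
  g0 <- lcmspanel:::empty_groups()
  fm0 <- build_feature_matrix(g0, list(A = make_map("A", 500, 1)))
  expect_equal(nrow(fm0), 0)
  expect_true(all(c("group_id", "mz", "rt", "z", "A") %in% names(fm0)))

  pro <- generate_proteome(10, frac_differential = 0.2, seed = 3)
  cfg <- map_sim_config(
    rt_drift_intercept = c(0, 0), rt_drift_slope = c(1, 1),
    rt_drift_quad = c(0, 0), intensity_log_offset = c(0, 0),
    noise_sd = 0, dropout_rate = 0.25, detection_floor = 1e-6, seed = 8
  )
  pair <- generate_ion_map_pair(pro, cfg, 1)
  truth <- attr(pair, "truth")
  maps <- list(pair$tumor, pair$control)
  names(maps) <- vapply(maps, function(m) m$map_id, character(1))
  g <- match_ions(maps)
  fm <- build_feature_matrix(g, maps)
  idrows <- !fm$is_internal_standard
  # masked cells equal the injected dropouts among ions the partner map
  # still observed (ions dropped from both maps leave no feature row)
  expect_equal(
    sum(is.na(fm[idrows, pair$tumor$map_id])),
    sum(truth$missing_tumor & !truth$missing_control)
  )
  expect_equal(
    sum(is.na(fm[idrows, pair$control$map_id])),
    sum(truth$missing_control & !truth$missing_tumor)
  )
  info <- attr(fm, "map_info")
  expect_equal(info$map_id, names(maps))
  expect_equal(info$condition, c("tumor", "control"))
})
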