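# Cross-map alignment of peptide-ion maps.
#
# Retention-time normalization is done in two steps: a primary affine warp
# anchored on the spiked internal standards, then a secondary fine-tuning
# that iteratively matches common features across maps and fits a monotone
# piecewise-linear correction per map toward the cross-map consensus.
# Matching groups ions on (m/z, RT, z); intensity normalization solves for
# per-map additive offsets on the log2 scale by least squares against the
# per-ion cross-map mean.

#' Alignment settings
#'
#' @param mz_tol_ppm m/z matching tolerance in parts per million.
#' @param rt_tol_min RT matching tolerance in minutes (after warping).
#' @param min_maps_for_secondary Minimum number of maps a feature must be
#'   seen in to anchor the secondary RT refinement.
#' @param normalization One of `"L2_log"` (least squares on log2
#'   intensities, default) or `"L1_log"` (median-based).
#' @param detection_floor Linear-intensity detection floor carried through
#'   to downstream ratio computation.
#' @return A list of class `alignment_config`.
#' @export
alignment_config <- function(mz_tol_ppm = 10, rt_tol_min = 1.0,
                             min_maps_for_secondary = 2,
                             normalization = c("L2_log", "L1_log"),
                             detection_floor = 500) {
  if (mz_tol_ppm <= 0 || rt_tol_min <= 0) {
    stop_invalid("tolerances must be positive")
  }
  structure(
    list(
      mz_tol_ppm = mz_tol_ppm, rt_tol_min = rt_tol_min,
      min_maps_for_secondary = as.integer(min_maps_for_secondary),
      normalization = match.arg(normalization),
      detection_floor = detection_floor
    ),
    class = "alignment_config"
  )
}

new_rt_warp <- function(map_id, kind, ...) {
  structure(list(map_id = map_id, kind = kind, ...), class = "rt_warp")
}

#' Apply a retention-time warp
#'
#' @param warp An `rt_warp` from [fit_primary_rt_warp()] or
#'   [refine_rt_secondary()].
#' @param rt Numeric vector of observed retention times (minutes).
#' @return Warped retention times on the reference scale.
#' @export
apply_rt_warp <- function(warp, rt) {
  stopifnot(inherits(warp, "rt_warp"))
  if (warp$kind == "affine") {
    warp$intercept + warp$slope * rt
  } else {
    kx <- warp$knots_x
    ky <- warp$knots_y
    y <- approx(kx, ky, xout = rt, rule = 1)$y
    # linear extrapolation with the edge slopes keeps the warp monotone
    nk <- length(kx)
    slope_lo <- (ky[2] - ky[1]) / (kx[2] - kx[1])
    slope_hi <- (ky[nk] - ky[nk - 1]) / (kx[nk] - kx[nk - 1])
    lo <- rt < kx[1]
    hi <- rt > kx[nk]
    y[lo] <- ky[1] + slope_lo * (rt[lo] - kx[1])
    y[hi] <- ky[nk] + slope_hi * (rt[hi] - kx[nk])
    y
  }
}

#' Primary RT alignment on internal standards
#'
#' Fits the affine warp `reference = intercept + slope * observed` that
#' minimizes squared anchor residuals over the map's internal-standard ions
#' matched (by standard id) to their reference retention times.
#'
#' @param map An `ion_map`.
#' @param reference_standards Tibble with `peptide` and `reference_rt`
#'   columns, e.g. [internal_standards()].
#' @return An `rt_warp` of kind `"affine"` with the matched anchor pairs.
#' @export
fit_primary_rt_warp <- function(map, reference_standards) {
  std <- map$ions[map$ions$is_internal_standard, ]
  anchors <- dplyr::inner_join(
    std[, c("peptide", "rt")],
    reference_standards[, c("peptide", "reference_rt")],
    by = "peptide"
  )
  if (nrow(anchors) < 2) {
    stop_invalid(
      "insufficient anchors: need >= 2 matched internal standards, got ",
      nrow(anchors)
    )
  }
  fit <- lm(reference_rt ~ rt, data = anchors)
  new_rt_warp(
    map$map_id, "affine",
    intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
    anchors = anchors
  )
}

# replace each map's rt by its warped value (keeps rt_raw)
apply_warps_to_maps <- function(maps, warps) {
  lapply(maps, function(m) {
    w <- warps[[m$map_id]]
    if (!is.null(w)) {
      if (!("rt_raw" %in% names(m$ions))) m$ions$rt_raw <- m$ions$rt
      m$ions$rt <- apply_rt_warp(w, m$ions$rt_raw)
    }
    m
  })
}

# monotone piecewise-linear fit of y on x through binned medians;
# isotonic regression on the bin medians enforces monotonicity
fit_monotone_piecewise <- function(x, y, n_knots = 11) {
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  qs <- unique(quantile(x, seq(0, 1, length.out = n_knots), type = 7))
  bins <- cut(x, breaks = qs, include.lowest = TRUE)
  kx <- as.numeric(tapply(x, bins, median))
  ky <- as.numeric(tapply(y, bins, median))
  ok <- !is.na(kx) & !is.na(ky)
  kx <- kx[ok]
  ky <- ky[ok]
  if (length(kx) < 2) {
    return(NULL)
  }
  iso <- stats::isoreg(kx, ky)
  ky <- iso$yf
  # strictness: break exact ties introduced by the isotonic pool
  eps <- 1e-9 * max(diff(range(kx)), 1)
  ky <- ky + seq_along(ky) * eps
  list(knots_x = kx, knots_y = ky)
}

#' Secondary RT refinement on common features
#'
#' Starting from primary warps, iteratively matches ions across maps,
#' computes each matched group's consensus retention time, and refits every
#' map's warp as a monotone piecewise-linear map from raw RT to consensus
#' RT. Iterations stop when the median absolute RT residual stops improving
#' or `max_iter` is reached; the best warp set seen is returned.
#'
#' @param maps Named list of `ion_map` objects (raw retention times).
#' @param warps Named list of primary `rt_warp` objects, one per map.
#' @param config An [alignment_config()].
#' @param max_iter Maximum refinement iterations.
#' @param tol Stop when the median absolute residual improves by less than
#'   this (minutes).
#' @return Named list of `rt_warp` objects (piecewise where refined).
#' @export
refine_rt_secondary <- function(maps, warps, config = alignment_config(),
                                max_iter = 3, tol = 0.005) {
  if (length(maps) < 2) {
    return(warps)
  }
  best_warps <- warps
  best_resid <- Inf
  current <- warps
  for (iter in seq_len(max_iter)) {
    warped <- apply_warps_to_maps(maps, current)
    groups <- match_ions(warped, config)
    members <- attr(groups, "members")
    members <- members[members$n_maps_in_group >= config$min_maps_for_secondary, ]
    if (nrow(members) == 0) {
      warning("no common features; returning warps unchanged")
      return(best_warps)
    }
    resid <- median(abs(members$rt - members$consensus_rt))
    if (resid < best_resid - 1e-12) {
      best_resid <- resid
      best_warps <- current
    }
    if (resid <= tol || iter == max_iter) break
    new_warps <- current
    for (m in maps) {
      mm <- members[members$map_id == m$map_id, ]
      if (nrow(mm) < 4) next
      raw <- m$ions$rt[match(mm$ion_id, m$ions$ion_id)]
      pw <- fit_monotone_piecewise(raw, mm$consensus_rt)
      if (is.null(pw)) next
      new_warps[[m$map_id]] <- new_rt_warp(
        m$map_id, "piecewise",
        knots_x = pw$knots_x, knots_y = pw$knots_y
      )
    }
    current <- new_warps
  }
  # final check: did the last refit improve?
  warped <- apply_warps_to_maps(maps, current)
  groups <- match_ions(warped, config)
  members <- attr(groups, "members")
  members <- members[members$n_maps_in_group >= config$min_maps_for_secondary, ]
  if (nrow(members) > 0) {
    resid <- median(abs(members$rt - members$consensus_rt))
    if (resid < best_resid) best_warps <- current
  }
  best_warps
}

#' Match ions across maps into aligned groups
#'
#' Ions are grouped across maps when they share the charge state and lie
#' within `mz_tol_ppm` and `rt_tol_min` of the group consensus (running
#' mean). At most one ion per map joins a group; an ion joins the candidate
#' group at minimal m/z distance (ppm), RT distance breaking ties.
#' Processing order is a deterministic sort on (z, m/z, RT, map id, ion id),
#' so the result does not depend on input order.
#'
#' @param maps Named list of `ion_map` objects with warped retention times.
#' @param config An [alignment_config()].
#' @return Tibble of aligned groups (`group_id`, consensus `mz`, `rt`, `z`,
#'   `peptide`, `protein`, `is_internal_standard`, `n_maps`), with attribute
#'   `"members"`: the per-ion assignment table.
#' @export
match_ions <- function(maps, config = alignment_config()) {
  ions <- bind_rows(lapply(maps, function(m) {
    dplyr::mutate(m$ions, map_id = m$map_id)
  }))
  if (nrow(ions) == 0) {
    return(empty_groups())
  }
  ions <- arrange(ions, .data$z, .data$mz, .data$rt, .data$map_id, .data$ion_id)

  # coarse partition: same charge, then single-link m/z clusters split at
  # consecutive gaps exceeding the ppm tolerance; groups never span clusters
  gap <- c(
    TRUE,
    diff(ions$z) != 0 |
      1e6 * diff(ions$mz) / ions$mz[-nrow(ions)] > config$mz_tol_ppm
  )
  cluster <- cumsum(gap)

  # within a coarse cluster, merge ions into groups by ascending pair
  # distance (ppm first, RT as tie-break); a merge is allowed only when the
  # combined group keeps one ion per map and stays within both tolerances
  # (m/z span in ppm, RT span in minutes). Processing closest pairs first
  # resolves ambiguous competitors by minimal combined distance.
  assign_cluster <- function(idx) {
    k <- length(idx)
    if (k == 1) {
      return(1L)
    }
    mzs <- ions$mz[idx]
    rts <- ions$rt[idx]
    mids <- ions$map_id[idx]
    pairs <- which(
      upper.tri(matrix(0, k, k)),
      arr.ind = TRUE
    )
    i <- pairs[, 1]
    j <- pairs[, 2]
    dppm <- 2e6 * abs(mzs[i] - mzs[j]) / (mzs[i] + mzs[j])
    drt <- abs(rts[i] - rts[j])
    ok <- mids[i] != mids[j] & dppm <= config$mz_tol_ppm &
      drt <= config$rt_tol_min
    ord <- order(dppm[ok], drt[ok], i[ok], j[ok])
    ei <- i[ok][ord]
    ej <- j[ok][ord]
    group <- seq_len(k)
    for (e in seq_along(ei)) {
      gi <- group[ei[e]]
      gj <- group[ej[e]]
      if (gi == gj) next
      members <- which(group == gi | group == gj)
      if (anyDuplicated(mids[members])) next
      mzm <- mzs[members]
      rtm <- rts[members]
      if (2e6 * (max(mzm) - min(mzm)) / (max(mzm) + min(mzm)) >
        config$mz_tol_ppm) {
        next
      }
      if (max(rtm) - min(rtm) > config$rt_tol_min) next
      group[group == gj] <- gi
    }
    match(group, unique(group))
  }

  local_ids <- unlist(lapply(split(seq_len(nrow(ions)), cluster), assign_cluster),
    use.names = FALSE
  )
  ions$group_key <- paste(cluster, local_ids, sep = "_")

  modal <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(NA_character_)
    }
    names(sort(table(x), decreasing = TRUE))[1]
  }
  groups <- ions %>%
    group_by(.data$group_key) %>%
    summarise(
      mz = mean(.data$mz),
      rt = mean(.data$rt),
      z = .data$z[1],
      peptide = modal(.data$peptide),
      protein = modal(.data$protein),
      is_internal_standard = any(.data$is_internal_standard),
      n_maps = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(.data$mz, .data$rt, .data$z)
  groups$group_id <- sprintf("G%06d", seq_len(nrow(groups)))

  members <- ions %>%
    left_join(groups[, c("group_key", "group_id")], by = "group_key") %>%
    left_join(
      groups %>%
        select(group_id, consensus_rt = "rt", n_maps_in_group = "n_maps"),
      by = "group_id"
    ) %>%
    select(
      "group_id", "map_id", "ion_id", "mz", "rt", "z", "intensity",
      "peptide", "protein", "is_internal_standard", "consensus_rt",
      "n_maps_in_group"
    )
  groups <- select(groups, -"group_key")
  attr(groups, "members") <- members
  groups
}

# group-by-map matrix of log2 intensities (NA = unobserved)
build_log2_matrix <- function(groups, maps) {
  members <- attr(groups, "members")
  map_ids <- vapply(maps, function(m) m$map_id, character(1))
  x <- matrix(NA_real_,
    nrow = nrow(groups), ncol = length(map_ids),
    dimnames = list(groups$group_id, map_ids)
  )
  if (nrow(groups) > 0 && nrow(members) > 0) {
    x[cbind(
      match(members$group_id, groups$group_id),
      match(members$map_id, map_ids)
    )] <- log2(members$intensity)
  }
  x
}

empty_groups <- function() {
  g <- tibble(
    mz = numeric(0), rt = numeric(0), z = integer(0),
    peptide = character(0), protein = character(0),
    is_internal_standard = logical(0), n_maps = integer(0),
    group_id = character(0)
  )
  attr(g, "members") <- tibble(
    group_id = character(0), map_id = character(0), ion_id = character(0),
    mz = numeric(0), rt = numeric(0), z = integer(0), intensity = numeric(0),
    peptide = character(0), protein = character(0),
    is_internal_standard = logical(0), consensus_rt = numeric(0),
    n_maps_in_group = integer(0)
  )
  g
}

#' Normalize intensities across maps
#'
#' Finds one additive offset per map on the log2 intensity scale minimizing
#' the sum of squared deviations between each ion's offset intensity and
#' that ion's mean across the maps where it was observed (missing cells are
#' excluded, not imputed). Solved by alternating closed-form updates of the
#' per-ion means and per-map offsets to convergence; offsets are centered to
#' sum to zero. The `"L1_log"` variant replaces means by medians.
#'
#' @param groups Aligned groups from [match_ions()] (their `"members"`
#'   attribute supplies the intensities).
#' @param maps Named list of `ion_map` objects (defines the map set and
#'   column order).
#' @param config An [alignment_config()].
#' @return List: `offsets` (named, sum to zero), `matrix` (group-by-map
#'   normalized log2 intensities, NA where unobserved), `objective`,
#'   `n_iter`.
#' @export
normalize_intensities <- function(groups, maps, config = alignment_config()) {
  if (length(maps) < 2) stop_invalid("need at least 2 maps to normalize")
  x <- build_log2_matrix(groups, maps)
  if (all(is.na(x))) stop_invalid("no observed intensities to normalize")
  if (!any(rowSums(!is.na(x)) >= 2)) {
    stop_invalid("no group observed in >= 2 maps; offsets are unidentifiable")
  }

  map_ids <- colnames(x)
  center_fun <- if (config$normalization == "L2_log") {
    function(v) mean(v, na.rm = TRUE)
  } else {
    function(v) median(v, na.rm = TRUE)
  }
  offsets <- setNames(rep(0, ncol(x)), map_ids)
  objective <- function(c_off) {
    xc <- sweep(x, 2, -c_off)
    m <- rowMeans(xc, na.rm = TRUE)
    sum((xc - m)^2, na.rm = TRUE)
  }
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    xc <- sweep(x, 2, -offsets) # x + c
    m <- apply(xc, 1, center_fun)
    new_off <- vapply(seq_len(ncol(x)), function(j) {
      obs <- !is.na(x[, j])
      center_fun_v <- m[obs] - x[obs, j]
      if (length(center_fun_v) == 0) {
        return(0)
      }
      if (config$normalization == "L2_log") {
        mean(center_fun_v)
      } else {
        median(center_fun_v)
      }
    }, numeric(1))
    new_off <- new_off - mean(new_off)
    delta <- max(abs(new_off - offsets))
    offsets[] <- new_off
    if (delta < 1e-10 || n_iter >= 100) break
  }
  list(
    offsets = offsets,
    matrix = sweep(x, 2, -offsets),
    objective = objective(offsets),
    n_iter = n_iter
  )
}

#' Assemble the feature-by-map intensity matrix
#'
#' @param groups Aligned groups from [match_ions()].
#' @param maps Named list of `ion_map` objects.
#' @param normalized Result of [normalize_intensities()] (optional; raw log2
#'   intensities are used when omitted).
#' @return Tibble of class `feature_matrix`: consensus metadata columns then
#'   one normalized-log2-intensity column per map (NA = not observed).
#'   Attribute `"map_info"` carries map metadata and offsets.
#' @export
build_feature_matrix <- function(groups, maps, normalized = NULL) {
  map_ids <- vapply(maps, function(m) m$map_id, character(1))
  if (is.null(normalized)) {
    members <- attr(groups, "members")
    x <- matrix(NA_real_,
      nrow = nrow(groups), ncol = length(map_ids),
      dimnames = list(groups$group_id, map_ids)
    )
    if (nrow(groups) > 0) {
      x[cbind(
        match(members$group_id, groups$group_id),
        match(members$map_id, map_ids)
      )] <- log2(members$intensity)
    }
    offsets <- setNames(rep(0, length(map_ids)), map_ids)
  } else {
    x <- normalized$matrix
    offsets <- normalized$offsets
  }
  out <- dplyr::bind_cols(
    groups[, c(
      "group_id", "mz", "rt", "z", "peptide", "protein",
      "is_internal_standard", "n_maps"
    )],
    as_tibble(x)
  )
  attr(out, "map_info") <- tibble(
    map_id = unname(map_ids),
    sample_id = unname(vapply(maps, function(m) m$sample_id, character(1))),
    condition = unname(vapply(maps, function(m) m$condition, character(1))),
    platform = unname(vapply(maps, function(m) m$platform, character(1))),
    paired_map_id = unname(vapply(
      maps, function(m) m$paired_map_id %||% NA_character_, character(1)
    )),
    offset = unname(offsets[map_ids])
  )
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Align a set of ion maps end to end
#'
#' Convenience wrapper: primary warps on internal standards, secondary
#' refinement, matching, intensity normalization, feature matrix.
#'
#' @param maps Named list of `ion_map` objects (raw retention times).
#' @param reference_standards Tibble of standard reference RTs.
#' @param config An [alignment_config()].
#' @param refine Logical: run the secondary refinement.
#' @return List: `feature_matrix`, `groups`, `warps`, `normalization`.
#' @export
align_maps <- function(maps, reference_standards = internal_standards(),
                       config = alignment_config(), refine = TRUE) {
  warps <- lapply(maps, fit_primary_rt_warp, reference_standards)
  names(warps) <- names(maps)
  if (refine && length(maps) >= 2) {
    warps <- refine_rt_secondary(maps, warps, config)
  }
  warped <- apply_warps_to_maps(maps, warps)
  groups <- match_ions(warped, config)
  normalized <- normalize_intensities(groups, warped, config)
  fm <- build_feature_matrix(groups, warped, normalized)
  list(
    feature_matrix = fm, groups = groups, warps = warps,
    normalization = normalized
  )
}
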