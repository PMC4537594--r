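# Simulation of paired tumor/control peptide-ion maps.
#
# Feature-level (peak list) simulation only: each eligible peptide produces
# ions at charge 2 and 3 with theoretical m/z, a reference retention time
# warped by a per-map monotone drift, and an intensity subject to a per-map
# log2 scale offset, multiplicative log-normal noise, a detection floor and
# random dropout. Spiked internal-standard ions anchor the primary RT
# alignment.

#' Simulation settings for paired ion maps
#'
#' @param n_pairs Number of tumor/control map pairs per platform.
#' @param rt_drift_intercept,rt_drift_slope,rt_drift_quad Ranges (length-2)
#'   from which each map's monotone RT warp
#'   `rt_obs = a + b * rt + c * rt^2` is drawn. The defaults keep the warp
#'   strictly increasing over `rt_range`.
#' @param intensity_log_offset Range of the per-map log2 intensity offset.
#' @param noise_sd Log2-scale standard deviation of multiplicative intensity
#'   noise.
#' @param dropout_rate Probability an ion is missing from a map, in \[0, 1\].
#' @param detection_floor Intensities below this value are censored (dropped).
#' @param rt_range Gradient window in minutes.
#' @param base_intensity_meanlog,base_intensity_sdlog Natural-log parameters
#'   of the per-ion base intensity.
#' @param n_standards Number of internal-standard anchor ions.
#' @param seed Integer seed; each map pair derives its own sub-seed.
#' @return A list of class `map_sim_config`.
#' @export
map_sim_config <- function(n_pairs = 3,
                           rt_drift_intercept = c(-1, 1),
                           rt_drift_slope = c(0.97, 1.03),
                           rt_drift_quad = c(0, 4e-4),
                           intensity_log_offset = c(-0.5, 0.5),
                           noise_sd = 0.25,
                           dropout_rate = 0.05,
                           detection_floor = 500,
                           rt_range = c(5, 60),
                           base_intensity_meanlog = log(1e5),
                           base_intensity_sdlog = 1,
                           n_standards = 12,
                           seed = 1L) {
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop_invalid("`dropout_rate` must be in [0, 1]")
  }
  if (detection_floor <= 0) stop_invalid("`detection_floor` must be positive")
  # strictly increasing warp on the whole gradient: b + 2 c rt > 0
  if (min(rt_drift_slope) + 2 * min(rt_drift_quad) * max(rt_range) <= 0) {
    stop_invalid("RT drift ranges allow a non-monotone warp")
  }
  structure(
    list(
      n_pairs = as.integer(n_pairs),
      rt_drift_intercept = rt_drift_intercept,
      rt_drift_slope = rt_drift_slope,
      rt_drift_quad = rt_drift_quad,
      intensity_log_offset = intensity_log_offset,
      noise_sd = noise_sd,
      dropout_rate = dropout_rate,
      detection_floor = detection_floor,
      rt_range = rt_range,
      base_intensity_meanlog = base_intensity_meanlog,
      base_intensity_sdlog = base_intensity_sdlog,
      n_standards = as.integer(n_standards),
      seed = as.integer(seed)
    ),
    class = "map_sim_config"
  )
}

#' Internal-standard anchor ions
#'
#' Synthetic spiked peptides with known reference retention times evenly
#' covering the gradient; present in every map, exempt from dropout and
#' censoring.
#'
#' @param n Number of standards.
#' @param rt_range Gradient window in minutes.
#' @return Tibble with `peptide`, `mz`, `z`, `reference_rt`, `intensity`.
#' @export
internal_standards <- function(n = 12, rt_range = c(5, 60)) {
  tibble(
    peptide = sprintf("STD%02d", seq_len(n)),
    mz = 400 + 37.3 * seq_len(n),
    z = 2L,
    reference_rt = seq(rt_range[1] - 1, rt_range[2] + 1, length.out = n),
    intensity = 1e6
  )
}

new_ion_map <- function(map_id, sample_id, condition, platform,
                        paired_map_id, ions) {
  structure(
    list(
      map_id = map_id, sample_id = sample_id, condition = condition,
      platform = platform, paired_map_id = paired_map_id,
      ions = ions
    ),
    class = "ion_map"
  )
}

#' @export
print.ion_map <- function(x, ...) {
  cat(sprintf(
    "<ion_map %s: %s/%s, %d ions>\n",
    x$map_id, x$platform, x$condition, nrow(x$ions)
  ))
  invisible(x)
}

# evaluate one map's monotone drift warp: observed rt from reference rt
apply_drift <- function(rt, drift) {
  drift["a"] + drift["b"] * rt + drift["c"] * rt^2
}

#' Simulate one paired tumor/control ion map
#'
#' Every eligible peptide of the proteome yields ions at charge 2 and 3.
#' The tumor map multiplies each spiked protein's ion intensities by its
#' true fold change; both maps apply their own RT drift, log2 scale offset,
#' log-normal noise, dropout and detection floor. Internal standards are
#' added to both maps unperturbed by dropout/censoring (their RT is still
#' drift-warped). Ground truth (per-ion fold changes and dropout flags) is
#' attached as attribute `"truth"`.
#'
#' @param proteome A `proteome` from [generate_proteome()].
#' @param config A [map_sim_config()].
#' @param pair_index Integer pair index (drives the derived seed).
#' @param platform Discovery platform label.
#' @return List of class `ion_map_pair` with elements `tumor` and `control`
#'   ([new_ion_map] objects) and attribute `truth`.
#' @export
generate_ion_map_pair <- function(proteome, config, pair_index = 1,
                                  platform = "tissue") {
  stopifnot(inherits(config, "map_sim_config"))
  if (nrow(proteome) == 0) stop_invalid("`proteome` must be non-empty")
  with_seed(derive_seed(config$seed, pair_index), {
    pep <- tidyr::unnest(
      proteome[, c("accession", "true_fold_change", "peptides", "eligible")],
      cols = c("peptides", "eligible")
    )
    pep <- pep[pep$eligible, ]
    pep <- pep[!duplicated(pep$peptides), ]
    ions <- tidyr::crossing(pep, z = c(2L, 3L))
    ions$mz <- peptide_mz(ions$peptides, ions$z)
    ions$reference_rt <- reference_rt(ions$peptides, config$rt_range)
    ions$base_intensity <- rlnorm(
      nrow(ions), config$base_intensity_meanlog, config$base_intensity_sdlog
    )

    std <- internal_standards(config$n_standards, config$rt_range)

    make_map <- function(condition) {
      drift <- c(
        a = runif(1, config$rt_drift_intercept[1], config$rt_drift_intercept[2]),
        b = runif(1, config$rt_drift_slope[1], config$rt_drift_slope[2]),
        c = runif(1, config$rt_drift_quad[1], config$rt_drift_quad[2])
      )
      offset <- runif(
        1, config$intensity_log_offset[1], config$intensity_log_offset[2]
      )
      fold <- if (condition == "tumor") ions$true_fold_change else 1.0
      noise <- if (config$noise_sd > 0) {
        rnorm(nrow(ions), 0, config$noise_sd)
      } else {
        0
      }
      intensity <- ions$base_intensity * fold * 2^(offset + noise)
      dropped <- runif(nrow(ions)) < config$dropout_rate
      censored <- intensity < config$detection_floor
      keep <- !dropped & !censored
      map_id <- sprintf("%s_P%02d_%s", platform, pair_index, condition)
      obs <- tibble(
        ion_id = sprintf("%s_I%05d", map_id, which(keep)),
        mz = ions$mz[keep],
        rt = unname(apply_drift(ions$reference_rt[keep], drift)),
        z = ions$z[keep],
        intensity = intensity[keep],
        peptide = ions$peptides[keep],
        protein = ions$accession[keep],
        is_internal_standard = FALSE
      )
      std_rows <- tibble(
        ion_id = sprintf("%s_S%02d", map_id, seq_len(nrow(std))),
        mz = std$mz,
        rt = unname(apply_drift(std$reference_rt, drift)),
        z = std$z,
        intensity = std$intensity,
        peptide = std$peptide,
        protein = NA_character_,
        is_internal_standard = TRUE
      )
      list(
        map = new_ion_map(
          map_id = map_id,
          sample_id = sprintf("%s_S%02d", platform, pair_index),
          condition = condition,
          platform = platform,
          paired_map_id = sprintf(
            "%s_P%02d_%s", platform, pair_index,
            if (condition == "tumor") "control" else "tumor"
          ),
          ions = bind_rows(obs, std_rows)
        ),
        drift = drift, offset = offset, dropped = dropped, censored = censored
      )
    }

    tum <- make_map("tumor")
    ctl <- make_map("control")
    truth <- tibble(
      protein = ions$accession,
      peptide = ions$peptides,
      z = ions$z,
      true_fold_change = ions$true_fold_change,
      base_intensity = ions$base_intensity,
      reference_rt = ions$reference_rt,
      missing_tumor = tum$dropped | tum$censored,
      missing_control = ctl$dropped | ctl$censored
    )
    structure(
      list(tumor = tum$map, control = ctl$map),
      truth = truth,
      drift = list(tumor = tum$drift, control = ctl$drift),
      log_offsets = c(tumor = tum$offset, control = ctl$offset),
      class = "ion_map_pair"
    )
  })
}

#' Simulate all map pairs for one platform
#'
#' @inheritParams generate_ion_map_pair
#' @return List with `maps` (flat list of `ion_map`), `pairs` (tibble of
#'   tumor/control map ids), and `truth` (per-pair ground-truth tibbles).
#' @export
generate_platform_maps <- function(proteome, config, platform = "tissue") {
  pairs <- lapply(seq_len(config$n_pairs), function(i) {
    generate_ion_map_pair(proteome, config, i, platform)
  })
  maps <- unlist(lapply(pairs, function(p) list(p$tumor, p$control)),
    recursive = FALSE
  )
  names(maps) <- vapply(maps, function(m) m$map_id, character(1))
  pair_tbl <- tibble(
    pair_id = sprintf("%s_P%02d", platform, seq_len(config$n_pairs)),
    tumor_map_id = vapply(pairs, function(p) p$tumor$map_id, character(1)),
    control_map_id = vapply(pairs, function(p) p$control$map_id, character(1)),
    platform = platform
  )
  list(
    maps = maps, pairs = pair_tbl,
    truth = lapply(pairs, attr, "truth")
  )
}
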