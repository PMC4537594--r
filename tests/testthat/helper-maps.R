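# Hand-built ion maps for alignment tests.

make_map <- function(map_id, mz, rt, z = 2L, intensity = 1e5,
                     peptide = NULL, is_standard = FALSE,
                     condition = "tumor", platform = "tissue",
                     paired_map_id = NULL) {
  n <- length(mz)
  lcmspanel:::new_ion_map(
    map_id = map_id, sample_id = map_id, condition = condition,
    platform = platform, paired_map_id = paired_map_id,
    ions = tibble::tibble(
      ion_id = sprintf("%s_%03d", map_id, seq_len(n)),
      mz = mz,
      rt = rep_len(rt, n),
      z = rep_len(z, n),
      intensity = rep_len(intensity, n),
      peptide = if (is.null(peptide)) sprintf("PEP%03d", seq_len(n)) else rep_len(peptide, n),
      protein = sprintf("PRO%03d", seq_len(n)),
      is_internal_standard = rep_len(is_standard, n)
    )
  )
}

# a map whose internal standards sit at given observed RTs
make_standard_map <- function(map_id, observed_rt, std = internal_standards()) {
  make_map(
    map_id,
    mz = std$mz[seq_along(observed_rt)],
    rt = observed_rt,
    z = std$z[seq_along(observed_rt)],
    peptide = std$peptide[seq_along(observed_rt)],
    is_standard = TRUE
  )
}
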