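# In-silico proteomes and tryptic digestion.
#
# The discovery chemistry enriches for short tryptic peptides carrying either
# a cysteine (isotope-tag capture) or an N-linked glycosylation sequon
# (hydrazide capture); only such "eligible" peptides are observable as ions.

PROTON_MASS <- 1.007276466
WATER_MASS <- 18.010565

# monoisotopic residue masses (Da)
AA_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Kyte-Doolittle hydropathy, used for a deterministic reference retention time
AA_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# approximate vertebrate amino-acid usage for random protein sequences
AA_FREQ <- c(
  A = 0.083, R = 0.055, N = 0.041, D = 0.055, C = 0.020, Q = 0.039,
  E = 0.067, G = 0.071, H = 0.023, I = 0.059, L = 0.096, K = 0.058,
  M = 0.024, F = 0.039, P = 0.047, S = 0.066, T = 0.054, W = 0.011,
  Y = 0.029, V = 0.069
)

#' Tryptic digestion of a protein sequence
#'
#' Cleaves C-terminal to lysine (K) or arginine (R) except when the residue
#' immediately following is proline (P).
#'
#' @param sequence Single protein sequence (uppercase one-letter amino acids).
#' @return Character vector of peptides in N- to C-terminal order.
#' @examples
#' digest_tryptic("MKRAPK")
#' @export
digest_tryptic <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) {
    return(character(0))
  }
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P" |
    cut_after == n]
  bounds <- c(0L, cut_after[cut_after < n], n)
  substring(sequence, head(bounds, -1L) + 1L, tail(bounds, -1L))
}

#' Peptide eligibility for the enrichment chemistry
#'
#' A peptide is observable iff it contains at least one cysteine or an
#' N-linked glycosylation sequon N-X-S/T with X != P.
#'
#' @param peptide Character vector of peptide sequences.
#' @return Logical vector.
#' @examples
#' peptide_eligible(c("ESCNLFVLK", "AAAAA", "LVNKSR"))
#' @export
peptide_eligible <- function(peptide) {
  grepl("C", peptide, fixed = TRUE) | grepl("N[^P][ST]", peptide)
}

#' Monoisotopic peptide mass and m/z
#'
#' @param peptide Character vector of peptide sequences.
#' @return Monoisotopic neutral mass in Da.
#' @export
peptide_mass <- function(peptide) {
  vapply(strsplit(peptide, "", fixed = TRUE), function(chars) {
    m <- AA_MONO_MASS[chars]
    if (anyNA(m)) stop_invalid("unknown amino acid in peptide")
    sum(m) + WATER_MASS
  }, numeric(1))
}

#' @param z Integer charge state (>= 1).
#' @rdname peptide_mass
#' @export
peptide_mz <- function(peptide, z) {
  stopifnot(all(z >= 1))
  (peptide_mass(peptide) + z * PROTON_MASS) / z
}

#' Deterministic reference retention time for a peptide
#'
#' Maps mean Kyte-Doolittle hydropathy onto the chromatographic gradient
#' (more hydrophobic elutes later) plus a small sequence-hash jitter so
#' distinct peptides rarely co-elute exactly. Deterministic: every simulated
#' map shares the same reference coordinate for a peptide without shared
#' RNG state.
#'
#' @param peptide Character vector of peptide sequences.
#' @param rt_range Gradient window in minutes.
#' @return Reference retention time in minutes.
#' @export
reference_rt <- function(peptide, rt_range = c(5, 60)) {
  vapply(peptide, function(p) {
    chars <- strsplit(p, "", fixed = TRUE)[[1]]
    h <- mean(AA_HYDROPATHY[chars])
    frac <- (h + 4.5) / 9
    frac <- min(max(frac, 0), 1)
    jitter <- (sum(utf8ToInt(p) * seq_along(chars)) %% 997) / 997 - 0.5
    rt_range[1] + frac * diff(rt_range) + jitter * 1.5
  }, numeric(1), USE.NAMES = FALSE)
}

random_protein_sequence <- function(length) {
  paste(sample(names(AA_FREQ), length, replace = TRUE, prob = AA_FREQ),
    collapse = ""
  )
}

#' Generate a synthetic proteome with known differential ground truth
#'
#' Each protein is a random sequence, digested in silico with trypsin;
#' peptides of length 5-25 are retained and flagged eligible when they carry
#' a cysteine or an N-glycosylation sequon. A fraction of proteins is spiked
#' as truly differential (tumor/control fold change > 1); the rest are null
#' (fold 1). Spiked proteins are assigned secreted or cell-membrane
#' localization (the compartments the screen targets); null proteins get a
#' mixed localization profile.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param frac_differential Fraction spiked as differential, in \[0, 1\].
#' @param fold_change Fold change for spiked proteins; a scalar, or a range
#'   `c(lo, hi)` sampled uniformly on the log2 scale.
#' @param mean_length Mean protein length in residues.
#' @param min_eligible Minimum eligible in-range peptides per protein
#'   (sequences are re-drawn until satisfied).
#' @param seed Optional integer seed (local to this call).
#' @return A tibble of class `proteome`: `accession`, `localization`,
#'   `true_fold_change`, plus list-columns `peptides` and `eligible`.
#' @export
generate_proteome <- function(n_proteins, frac_differential = 0.1,
                              fold_change = 8, mean_length = 350,
                              min_eligible = 3, seed = NULL) {
  if (!is.numeric(n_proteins) || n_proteins < 1) {
    stop_invalid("`n_proteins` must be a positive integer")
  }
  if (frac_differential < 0 || frac_differential > 1) {
    stop_invalid("`frac_differential` must be in [0, 1]")
  }
  with_seed(seed, {
    n_diff <- round(n_proteins * frac_differential)
    is_diff <- seq_len(n_proteins) <= n_diff
    rows <- lapply(seq_len(n_proteins), function(i) {
      for (attempt in 1:100) {
        len <- max(80L, round(rnorm(1, mean_length, mean_length / 4)))
        peps <- digest_tryptic(random_protein_sequence(len))
        peps <- peps[nchar(peps) >= 5 & nchar(peps) <= 25]
        elig <- peptide_eligible(peps)
        if (sum(elig) >= min_eligible) break
      }
      fold <- if (is_diff[i]) {
        if (length(fold_change) == 2) {
          2^runif(1, log2(fold_change[1]), log2(fold_change[2]))
        } else {
          fold_change
        }
      } else {
        1.0
      }
      loc <- if (is_diff[i]) {
        sample(c("secreted", "cell_membrane"), 1)
      } else {
        sample(c("secreted", "cell_membrane", "other"), 1,
          prob = c(0.2, 0.2, 0.6)
        )
      }
      tibble(
        accession = sprintf("SYN%04d", i),
        localization = loc,
        true_fold_change = fold,
        peptides = list(peps),
        eligible = list(elig)
      )
    })
    out <- bind_rows(rows)
    class(out) <- c("proteome", class(out))
    out
  })
}
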