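# Independent oracles used across the suite. Each deliberately re-derives
# its quantity by the most literal route available (exhaustive scans,
# all-pairs enumeration, numerical minimization) so it shares no code with
# the implementation under test.

# tryptic cleavage by an exhaustive per-position rule check
oracle_cleavage_positions <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pos <- integer(0)
  for (i in seq_along(chars)) {
    if (i == length(chars)) next
    if (chars[i] %in% c("K", "R") && chars[i + 1] != "P") pos <- c(pos, i)
  }
  pos
}

oracle_digest <- function(sequence) {
  cuts <- oracle_cleavage_positions(sequence)
  bounds <- c(0, cuts, nchar(sequence))
  out <- character(0)
  for (k in seq_len(length(bounds) - 1)) {
    out <- c(out, substr(sequence, bounds[k] + 1, bounds[k + 1]))
  }
  out
}

# two-sample KS statistic as the sup over every ECDF evaluation point
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# AUC by all-pairs concordance counting
oracle_auc <- function(scores, is_case) {
  cs <- scores[is_case]
  ct <- scores[!is_case]
  tot <- 0
  for (u in cs) {
    for (v in ct) {
      tot <- tot + (u > v) + 0.5 * (u == v)
    }
  }
  tot / (length(cs) * length(ct))
}

# sensitivity at minimum specificity by scanning every candidate threshold
oracle_sens_at_spec <- function(scores, is_case, target) {
  best <- 0
  for (t in c(Inf, sort(unique(scores)))) {
    sens <- mean(scores[is_case] >= t)
    spec <- mean(scores[!is_case] < t)
    if (spec >= target && sens > best) best <- sens
  }
  best
}

# Pearson correlation from raw sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# exhaustive minimum-distance matching between two ion maps:
# enumerate every one-to-one partial assignment of A-ions to compatible
# B-ions; prefer more matches, then smaller total (ppm, rt) distance with
# ppm dominant. Returns a list of index pairs (a, b).
oracle_two_map_matching <- function(a, b, mz_tol_ppm, rt_tol_min) {
  compatible <- function(i, j) {
    a$z[i] == b$z[j] &&
      1e6 * abs(a$mz[i] - b$mz[j]) / b$mz[j] <= mz_tol_ppm &&
      abs(a$rt[i] - b$rt[j]) <= rt_tol_min
  }
  n_a <- nrow(a)
  best <- NULL
  best_key <- c(-Inf, Inf, Inf) # (n matched, total ppm, total rt)
  recurse <- function(i, used_b, pairs) {
    if (i > n_a) {
      if (length(pairs) == 0) {
        key <- c(0, 0, 0)
      } else {
        m <- do.call(rbind, pairs)
        key <- c(
          nrow(m),
          sum(1e6 * abs(a$mz[m[, 1]] - b$mz[m[, 2]]) / b$mz[m[, 2]]),
          sum(abs(a$rt[m[, 1]] - b$rt[m[, 2]]))
        )
      }
      if (key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2] - 1e-12) ||
        (key[1] == best_key[1] && abs(key[2] - best_key[2]) <= 1e-12 &&
          key[3] < best_key[3])) {
        best_key <<- key
        best <<- pairs
      }
      return(invisible())
    }
    recurse(i + 1, used_b, pairs) # leave a-ion i unmatched
    for (j in seq_len(nrow(b))) {
      if (!(j %in% used_b) && compatible(i, j)) {
        recurse(i + 1, c(used_b, j), c(pairs, list(c(i, j))))
      }
    }
  }
  recurse(1, integer(0), list())
  best
}

# brute-force minimizer of the normalization objective over per-map offsets
# (sum-to-zero parameterization, BFGS from zero)
oracle_normalization_offsets <- function(x) {
  n_map <- ncol(x)
  obj <- function(free) {
    c_off <- c(free, -sum(free))
    xc <- sweep(x, 2, -c_off)
    m <- rowMeans(xc, na.rm = TRUE)
    sum((xc - m)^2, na.rm = TRUE)
  }
  fit <- optim(rep(0, n_map - 1), obj,
    method = "BFGS",
    control = list(maxit = 2000, reltol = 1e-15)
  )
  c(fit$par, -sum(fit$par))
}
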