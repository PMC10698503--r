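# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by the most naive route available so they stay
# independent of the implementation they check.

# nearest reference code by an explicit per-bead loop
oracle_nearest_code <- function(bead_mat, ref_mat, code_ids) {
  vapply(seq_len(nrow(bead_mat)), function(i) {
    d <- apply(ref_mat, 1, function(r) sqrt(sum((bead_mat[i, ] - r)^2)))
    code_ids[which.min(d)]
  }, character(1))
}

# arithmetic mean by an explicit loop
oracle_loop_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

# dense grid search for the one-parameter Langmuir K_d fit
oracle_grid_kd <- function(concentration, intensity, y_max,
                           grid = 10^seq(-2, 6, length.out = 20001)) {
  sse <- vapply(grid, function(kd) {
    sum((intensity - y_max * concentration / (concentration + kd))^2)
  }, numeric(1))
  grid[which.min(sse)]
}

# Welch t statistic, degrees of freedom and two-sided p by the textbook
# formulas (Welch-Satterthwaite)
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# exact permutation p-value for a two-group mean difference
oracle_permutation_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- combn(length(pooled), n)
  obs <- abs(mean(x) - mean(y))
  stats <- apply(idx, 2, function(ii) {
    abs(mean(pooled[ii]) - mean(pooled[-ii]))
  })
  mean(stats >= obs - 1e-12)
}

# brute-force RVxF-class scanner: explicit per-position slot checks
oracle_scan_rvxf <- function(sequence, strict = FALSE, no_proline = TRUE) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  set1 <- if (strict) "R" else c("R", "K")
  setV <- if (strict) "V" else c("V", "I")
  setF <- if (strict) "F" else c("F", "W")
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  wild <- if (no_proline) setdiff(aa, "P") else aa
  hits <- list()
  n <- length(chars)
  for (s in seq_len(n)) {
    if (s + 3 <= n &&
        chars[s] %in% set1 && chars[s + 1] %in% setV &&
        chars[s + 2] %in% wild && chars[s + 3] %in% setF) {
      hits[[length(hits) + 1]] <- c(s, s + 3)
    }
    if (s + 4 <= n &&
        chars[s] %in% set1 && chars[s + 1] %in% wild &&
        chars[s + 2] %in% setV && chars[s + 3] %in% wild &&
        chars[s + 4] %in% setF) {
      hits[[length(hits) + 1]] <- c(s, s + 4)
    }
  }
  if (length(hits) == 0) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, hits)
}

# small bead table built by hand for aggregation tests
toy_beads <- function(intensities, code = "code_001", condition = 0,
                      replicate = 1) {
  tibble::tibble(
    bead_id = sprintf("b%02d", seq_along(intensities)),
    l1 = 0, l2 = 0,
    intensity = intensities,
    condition = condition,
    replicate_id = replicate,
    sample_id = "s1",
    code_id = code
  )
}

small_sim_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_codes = 24, beads_per_code = 12, ...)
}
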