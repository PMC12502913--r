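# Independent oracles used by the unit and acceptance tests. These are kept
# deliberately naive (normal equations, full enumeration) so they share no
# code path with the package implementation.

# OLS of y on X via the normal equations; returns coefficient stats for one
# named column.
oracle_ols <- function(X, y, coef_name) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(resid^2) / df
  covb <- s2 * solve(XtX)
  b <- unname(beta[coef_name, 1])
  se <- unname(sqrt(covb[coef_name, coef_name]))
  t <- b / se
  list(beta = b, se = se, t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Design matrix mirroring the family-model contract: intercept, phenotype,
# indicators for species 2..n (species-major stacking, species ordered by
# mean RPM descending then id).
oracle_design_matrix <- function(rpm_mat, g_sample, epsilon = 0.01) {
  ord <- order(-rowMeans(rpm_mat), rownames(rpm_mat))
  rpm_mat <- rpm_mat[ord, , drop = FALSE]
  n <- nrow(rpm_mat)
  m <- ncol(rpm_mat)
  E <- as.vector(t(log10(rpm_mat + epsilon)))
  X <- cbind(intercept = 1, G = rep(g_sample, n))
  if (n > 1) {
    for (k in 2:n) {
      col <- as.numeric(rep(seq_len(n), each = m) == k)
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0("RNA", k)
    }
  }
  list(X = X, E = E)
}

# Exact two-sided signed-rank p by brute-force enumeration of all 2^n sign
# assignments of the ranks (tie-free inputs only).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small deterministic long abundance table used across io/family tests:
# counts chosen so RPM equals count when library sizes are 1e6.
make_toy_abund <- function() {
  tab <- tibble::tibble(
    species_id = c("sp1", "sp2", "sp3", "sp4"),
    sequence = c("ACGT", "ACGG", "ACGC", "ACGA"),
    annotation = c("tRNA-Gly-GCC", "tRNA-Gly-GCC",
                   "tRNA-Gly-GCC;tRNA-Gly-CCC", "tRNA-Gly-CCC"),
    start = NA_real_, end = NA_real_
  )
  tidyr::crossing(tab, sample_id = c("s1", "s2")) |>
    dplyr::mutate(
      count = c(40, 20, 10, 10, 8, 6, 4, 2),
      library_size = 1e6,
      rpm = count
    ) |>
    dplyr::arrange(species_id, sample_id)
}
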