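#' Signed-rank statistics for one family between two paired samples
#'
#' Computes the paired differences `d_i = x_i - y_i` over the member species,
#' drops zero differences (Wilcoxon's zero-exclusion convention), ranks the
#' absolute nonzero differences with average ranks for ties, and sums the
#' ranks of positive (`W_plus`, species more abundant in the first sample)
#' and negative (`W_minus`) differences. `W_plus > W_minus` means the family
#' is up in the first sample relative to the second, and vice versa.
#'
#' @param x,y Aligned RPM vectors (same species order) of length >= 2.
#' @return A `signed_rank` list: `W_plus`, `W_minus`, `n_effective`,
#'   `ranks` (of the nonzero absolute differences), `d`, `has_ties`,
#'   `direction` (`"up"`, `"down"` or `"tie"`).
#' @export
compute_signed_ranks <- function(x, y) {
  if (length(x) != length(y)) abort("paired vectors differ in length")
  if (length(x) < 2) abort("a family needs >= 2 species for the paired test")
  if (anyNA(x) || anyNA(y)) abort("paired vectors contain NA")
  d <- x - y
  nz <- d != 0
  dn <- d[nz]
  r <- rank(abs(dn))
  w_plus <- sum(r[dn > 0])
  w_minus <- sum(r[dn < 0])
  structure(
    list(
      W_plus = w_plus, W_minus = w_minus, n_effective = length(dn),
      ranks = r, d = d, has_ties = anyDuplicated(abs(dn)) > 0,
      direction = if (w_plus > w_minus) "up"
                  else if (w_plus < w_minus) "down" else "tie"
    ),
    class = "signed_rank"
  )
}

# internal: number of subsets of {1..n} with each possible rank sum 0..n(n+1)/2.
# Generating-function recursion; doubles are exact for n <= 25 (2^25 < 2^53).
signrank_counts <- function(n) {
  maxw <- n * (n + 1) / 2
  f <- numeric(maxw + 1)
  f[1] <- 1
  for (k in seq_len(n)) {
    idx <- (k + 1):(maxw + 1)
    f[idx] <- f[idx] + f[idx - k]
  }
  f
}

#' Signed-rank p-value (exact or normal approximation)
#'
#' Two-sided p-value for a [compute_signed_ranks()] comparison. In `"auto"`
#' mode the exact null distribution of `W_plus` (enumeration over all
#' 2^n_effective sign assignments, computed by a count recursion) is used
#' whenever `n_effective <= exact_max_n` and the absolute differences are
#' tie-free; otherwise a normal approximation with tie-corrected variance and
#' continuity correction is applied. `n_effective = 0` returns p = 1.
#'
#' @param comparison A `signed_rank` object.
#' @param mode `"auto"`, `"exact"` or `"approx"`. Requesting `"exact"` with
#'   tied absolute differences falls back to the approximation with a
#'   warning (the exact distribution assumes distinct ranks).
#' @param exact_max_n Largest `n_effective` for the exact path in auto mode.
#' @return List with `p_value` and `method` (`"exact"` or `"approx"`).
#' @export
signed_rank_p <- function(comparison, mode = c("auto", "exact", "approx"),
                          exact_max_n = 25) {
  mode <- match.arg(mode)
  if (!inherits(comparison, "signed_rank")) {
    abort("comparison must come from compute_signed_ranks()")
  }
  ne <- comparison$n_effective
  if (ne == 0) return(list(p_value = 1, method = "exact"))

  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = ne <= exact_max_n && !comparison$has_ties
  )
  if (use_exact && comparison$has_ties) {
    warn("tied |differences|: exact distribution unavailable, using the normal approximation")
    use_exact <- FALSE
  }

  w <- comparison$W_plus
  if (use_exact) {
    f <- signrank_counts(ne)
    tot <- 2^ne
    p_le <- sum(f[seq_len(w + 1)]) / tot
    p_ge <- sum(f[(w + 1):length(f)]) / tot
    list(p_value = min(1, 2 * min(p_le, p_ge)), method = "exact")
  } else {
    mu <- ne * (ne + 1) / 4
    tie_tab <- table(comparison$ranks)
    sigma2 <- ne * (ne + 1) * (2 * ne + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) return(list(p_value = 1, method = "approx"))
    z <- w - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
    list(p_value = min(1, p), method = "approx")
  }
}

#' Paired family-level differential abundance for one sample pair
#'
#' Runs the within-family signed-rank test between two samples for every
#' family in the index: species RPM profiles are compared pairwise, the
#' family direction comes from the rank sums (`up` = more abundant in
#' `sample1`), and p-values are Bonferroni-adjusted over the families tested
#' for this pair.
#'
#' @param abund Long abundance tibble with `rpm`.
#' @param index Constrained family index.
#' @param sample1,sample2 Sample ids to compare (`direction = "up"` means
#'   higher in `sample1`).
#' @param mode,exact_max_n Passed to [signed_rank_p()].
#' @param alpha Significance level on the adjusted p-value.
#' @return Tibble with columns `family_id`, `n_species`, `n_effective`,
#'   `W_plus`, `W_minus`, `p_value`, `p_adjusted`, `direction`, `method`,
#'   `significant`, sorted by `p_value` then `family_id`.
#' @export
run_family_signedrank <- function(abund, index, sample1, sample2,
                                  mode = "auto", exact_max_n = 25,
                                  alpha = 0.05) {
  check_abundance(abund)
  samples <- unique(abund$sample_id)
  unknown <- setdiff(c(sample1, sample2), samples)
  if (length(unknown) > 0) {
    abort(paste0("unknown sample id(s): ", paste(unknown, collapse = ", ")))
  }
  idx <- dplyr::arrange(index, .data$family_id, dplyr::desc(.data$mean_rpm),
                        .data$species_id)
  pair_data <- abund[abund$sample_id %in% c(sample1, sample2), , drop = FALSE]
  big <- rpm_matrix(
    dplyr::distinct(pair_data[c("species_id", "sample_id", "rpm")]),
    unique(idx$species_id), c(sample1, sample2)
  )
  fams <- split(idx$species_id, idx$family_id)

  rows <- purrr::imap(fams, function(members, fam) {
    cmp <- compute_signed_ranks(big[members, sample1], big[members, sample2])
    pv <- signed_rank_p(cmp, mode = mode, exact_max_n = exact_max_n)
    tibble::tibble(
      family_id = fam, n_species = length(members),
      n_effective = cmp$n_effective,
      W_plus = cmp$W_plus, W_minus = cmp$W_minus,
      p_value = pv$p_value, direction = cmp$direction, method = pv$method
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- bonferroni_adjust(out$p_value, m_tests = nrow(out))
  out$significant <- out$p_adjusted < alpha
  out |>
    dplyr::arrange(.data$p_value, .data$family_id) |>
    dplyr::select("family_id", "n_species", "n_effective", "W_plus",
                  "W_minus", "p_value", "p_adjusted", "direction", "method",
                  "significant")
}

#' Paired family-level analysis across a cohort of sample pairs
#'
#' Applies [run_family_signedrank()] independently to every pair defined in
#' the metadata and stacks the results in long format keyed by
#' `(pair_id, family_id)`. Within each pair, the sample whose phenotype
#' equals `sample1_level` plays the role of sample 1 (so `direction = "up"`
#' reads "up in that condition"); by default this is the lexicographically
#' last phenotype level, mirroring the multi-sample module where the
#' lexicographically first label is the reference.
#'
#' @inheritParams run_family_signedrank
#' @param metadata Tibble with `sample_id`, the phenotype column and the pair
#'   column; each pair id must occur exactly twice with distinct phenotype
#'   labels.
#' @param phenotype,pair Column names in `metadata`.
#' @param sample1_level Phenotype label treated as sample 1 in every pair.
#' @return Long tibble: `pair_id` plus the [run_family_signedrank()] columns.
#' @export
run_signedrank_cohort <- function(abund, index, metadata,
                                  phenotype = "phenotype", pair = "pair_id",
                                  sample1_level = NULL, mode = "auto",
                                  exact_max_n = 25, alpha = 0.05) {
  for (col in c("sample_id", phenotype, pair)) {
    if (!col %in% names(metadata)) {
      abort(paste0("metadata lacks column '", col, "'"))
    }
  }
  md <- metadata[!is.na(metadata[[pair]]), ]
  levels <- sort(unique(as.character(md[[phenotype]])))
  s1_level <- sample1_level %||% levels[length(levels)]
  if (!s1_level %in% levels) {
    abort(paste0("sample1_level '", s1_level, "' is not a phenotype level"))
  }
  pairs <- split(seq_len(nrow(md)), md[[pair]])
  res <- purrr::imap(pairs, function(rows, pid) {
    if (length(rows) != 2 ||
        dplyr::n_distinct(md[[phenotype]][rows]) != 2) {
      abort(paste0("pair '", pid, "' must have exactly two samples with ",
                   "distinct phenotype labels"))
    }
    s1 <- md$sample_id[rows][md[[phenotype]][rows] == s1_level]
    s2 <- setdiff(md$sample_id[rows], s1)
    if (length(s1) != 1) {
      abort(paste0("pair '", pid, "' has no sample with phenotype '",
                   s1_level, "'"))
    }
    run_family_signedrank(abund, index, s1, s2, mode = mode,
                          exact_max_n = exact_max_n, alpha = alpha) |>
      dplyr::mutate(pair_id = pid, .before = 1)
  })
  dplyr::bind_rows(res)
}
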