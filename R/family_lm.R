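#' Log10 transform with an abundance offset
#'
#' Family-level linear modelling works on `log10(rpm + epsilon)`. The offset
#' keeps zero-RPM observations finite; the default 0.01 sits one decade below
#' the usual 0.1 mean-RPM inclusion cut, so it only matters for species close
#' to the detection floor.
#'
#' @param rpm Non-negative numeric vector.
#' @param epsilon Positive offset added before the log (default 0.01).
#' @return `log10(rpm + epsilon)`.
#' @export
log10_eps <- function(rpm, epsilon = 0.01) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    abort("epsilon must be a single positive number")
  }
  if (any(rpm < 0, na.rm = TRUE)) abort("rpm values must be non-negative")
  log10(rpm + epsilon)
}

#' Build the design for a family-level linear model
#'
#' Stacks the log10 abundances of all member species species-major
#' (all samples of species 1, then species 2, ...) and pairs them with the
#' phenotype vector `G` repeated per species block plus species-indicator
#' covariates. Binary group labels are coded 0/1 with the reference group
#' defaulting to the lexicographically first label; numeric phenotypes pass
#' through unchanged. The reference species (whose indicator is omitted) is
#' the member with the highest mean RPM.
#'
#' @param data Long tibble for one family: `species_id`, `sample_id`, `rpm`.
#' @param metadata Tibble with `sample_id` and the phenotype column.
#' @param phenotype Name of the phenotype column in `metadata`.
#' @param reference_group For binary phenotypes, the label coded 0.
#' @param epsilon Offset for [log10_eps()].
#' @param allow_single_species Permit n = 1 (no species indicators); used to
#'   reduce the model to a plain two-sample comparison.
#' @return An `ms_design` list with elements `E`, `G`, `species`, `n`, `m`,
#'   `df`, `reference_species`, `samples`.
#' @export
build_family_design <- function(data, metadata, phenotype = "phenotype",
                                reference_group = NULL, epsilon = 0.01,
                                allow_single_species = FALSE) {
  need <- c("species_id", "sample_id", "rpm")
  if (!all(need %in% names(data))) {
    abort("data needs columns species_id, sample_id, rpm")
  }
  samples <- unique(data$sample_id)
  g_sample <- phenotype_coding(metadata, phenotype, samples, reference_group)
  means <- data |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(mean_rpm = mean(.data$rpm), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_rpm), .data$species_id)
  members <- means$species_id
  rpm_mat <- rpm_matrix(data, members, samples)
  new_ms_design(rpm_mat, g_sample, epsilon = epsilon,
                allow_single_species = allow_single_species)
}

# internal: 0/1 (or continuous) phenotype vector aligned to `samples`
phenotype_coding <- function(metadata, phenotype, samples,
                             reference_group = NULL) {
  if (!phenotype %in% names(metadata)) {
    abort(paste0("metadata lacks phenotype column '", phenotype, "'"))
  }
  if (!"sample_id" %in% names(metadata)) abort("metadata lacks 'sample_id'")
  missing <- setdiff(samples, metadata$sample_id)
  if (length(missing) > 0) {
    abort(paste0("metadata missing sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  ph <- metadata[[phenotype]][match(samples, metadata$sample_id)]
  if (dplyr::n_distinct(ph) < 2) {
    abort("phenotype is constant across samples; design is degenerate",
          class = "sncfam_degenerate_design")
  }
  if (is.numeric(ph)) return(as.numeric(ph))
  labels <- sort(unique(as.character(ph)))
  if (length(labels) != 2) {
    abort(paste0("group phenotype must have exactly 2 levels, got ",
                 length(labels), " (use a numeric column for continuous ",
                 "phenotypes)"))
  }
  ref <- reference_group %||% labels[1]
  if (!ref %in% labels) {
    abort(paste0("reference group '", ref, "' is not a phenotype level"))
  }
  as.numeric(ph != ref)
}

# internal: species x sample RPM matrix in the given orders
rpm_matrix <- function(data, members, samples) {
  mat <- matrix(NA_real_, nrow = length(members), ncol = length(samples),
                dimnames = list(members, samples))
  mat[cbind(match(data$species_id, members),
            match(data$sample_id, samples))] <- data$rpm
  if (any(is.na(mat))) {
    abort("every species needs an RPM value in every sample")
  }
  mat
}

# internal: design constructor shared by build_family_design and run_family_lm.
# rpm_mat rows are ordered by mean RPM descending (row 1 = reference species).
new_ms_design <- function(rpm_mat, g_sample, epsilon = 0.01,
                          allow_single_species = FALSE) {
  n <- nrow(rpm_mat)
  m <- ncol(rpm_mat)
  if (n < 2 && !allow_single_species) {
    abort("a family needs >= 2 species (set allow_single_species to bypass)")
  }
  df <- n * m - (n + 1)
  if (df < 1) {
    abort(paste0("insufficient degrees of freedom: n*m - (n+1) = ", df),
          class = "sncfam_insufficient_df")
  }
  members <- rownames(rpm_mat)
  structure(
    list(
      E = as.vector(t(log10_eps(rpm_mat, epsilon))),
      G = rep(g_sample, times = n),
      species = factor(rep(members, each = m), levels = members),
      n = n, m = m, df = df,
      reference_species = members[1],
      samples = colnames(rpm_mat)
    ),
    class = "ms_design"
  )
}

#' Fit the family-level linear model
#'
#' Ordinary least squares of the stacked log10 abundances on the phenotype
#' plus species indicators:
#' `E = b0 + b1 G + b2 RNA_2 + ... + bn RNA_n`.
#' The family-level differential abundance call is carried entirely by the
#' phenotype coefficient: its t-statistic on `n*m - (n+1)` residual degrees
#' of freedom and the two-sided Student-t p-value.
#'
#' @param design An `ms_design` from [build_family_design()].
#' @return A `family_lm` object (use [tidy()] / [glance()] to extract
#'   tibbles) with elements `beta1`, `se`, `t_stat`, `df`, `p_value`,
#'   `direction`, `n_species`, `m_samples`.
#' @export
fit_family_model <- function(design) {
  if (!inherits(design, "ms_design")) abort("design must be an ms_design")
  dat <- data.frame(E = design$E, G = design$G)
  if (design$n > 1) {
    dat$species <- design$species
    fit <- lm(E ~ G + species, data = dat)
  } else {
    fit <- lm(E ~ G, data = dat)
  }
  if (fit$rank < length(coef(fit)) || anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")),
          class = "sncfam_rank_deficient")
  }
  stopifnot(fit$df.residual == design$df)
  sfit <- suppressWarnings(summary(fit))
  sm <- sfit$coefficients
  beta1 <- sm["G", "Estimate"]
  se <- sm["G", "Std. Error"]
  t_stat <- sm["G", "t value"]
  scale <- max(abs(design$E), 1)
  if (sfit$sigma < 1e-10 * scale || !is.finite(t_stat)) {
    # zero residual variance: a perfect fit carries either no evidence
    # (beta1 numerically 0) or infinitely strong evidence
    if (abs(beta1) < 1e-8 * scale) {
      beta1 <- 0
      t_stat <- 0
    } else {
      t_stat <- sign(beta1) * Inf
    }
  }
  p <- 2 * pt(-abs(t_stat), df = design$df)
  structure(
    list(beta1 = beta1, se = se, t_stat = t_stat, df = design$df,
         p_value = p,
         direction = if (t_stat > 0) "up" else if (t_stat < 0) "down" else "none",
         n_species = design$n, m_samples = design$m,
         reference_species = design$reference_species),
    class = "family_lm"
  )
}

#' @export
print.family_lm <- function(x, ...) {
  cat("Family-level linear model (", x$n_species, " species x ",
      x$m_samples, " samples)\n", sep = "")
  cat(sprintf("  beta1 = %.4g  t = %.4g  df = %d  p = %.4g  (%s)\n",
              x$beta1, x$t_stat, x$df, x$p_value, x$direction))
  invisible(x)
}

#' @rdname fit_family_model
#' @param x A `family_lm` object.
#' @param ... Unused.
#' @export
tidy.family_lm <- function(x, ...) {
  tibble::tibble(term = "G", estimate = x$beta1, std.error = x$se,
                 statistic = x$t_stat, p.value = x$p_value,
                 direction = x$direction)
}

#' @rdname fit_family_model
#' @export
glance.family_lm <- function(x, ...) {
  tibble::tibble(n_species = x$n_species, m_samples = x$m_samples,
                 df = x$df, t_stat = x$t_stat, p_value = x$p_value)
}

#' Family-level differential abundance for a multi-sample cohort
#'
#' Fits the family-level linear model for every family in the index and
#' returns one result row per family with Bonferroni-adjusted p-values
#' (multiplier = number of families attempted) and an `adjusted p < alpha`
#' significance flag. Families whose fit fails (rank deficiency,
#' insufficient degrees of freedom) are reported with `NA` statistics and a
#' reason in `status`; the run continues and the Bonferroni multiplier still
#' counts them.
#'
#' @param abund Long abundance tibble with `rpm` (already RPM-filtered).
#' @param index Constrained family index from [apply_family_constraints()].
#' @param metadata Tibble with `sample_id` and the phenotype column; binary
#'   group labels or a numeric phenotype.
#' @param phenotype Name of the phenotype column.
#' @param reference_group For binary phenotypes, the label coded 0
#'   (default: lexicographically first). `direction = "up"` means higher
#'   abundance at higher phenotype, i.e. in the non-reference group.
#' @param epsilon Offset for [log10_eps()].
#' @param alpha Significance level on the adjusted p-value.
#' @return Tibble with columns `family_id`, `n_species`, `beta1`, `t_stat`,
#'   `df`, `p_value`, `p_adjusted`, `direction`, `significant`, `status`,
#'   sorted by `p_value` (ties by `family_id`, failures last).
#' @export
run_family_lm <- function(abund, index, metadata, phenotype = "phenotype",
                          reference_group = NULL, epsilon = 0.01,
                          alpha = 0.05) {
  check_abundance(abund)
  samples <- unique(abund$sample_id)
  g_sample <- phenotype_coding(metadata, phenotype, samples, reference_group)
  idx <- dplyr::arrange(index, .data$family_id, dplyr::desc(.data$mean_rpm),
                        .data$species_id)
  big <- rpm_matrix(
    dplyr::distinct(abund[c("species_id", "sample_id", "rpm")]),
    unique(idx$species_id), samples
  )
  fams <- split(idx$species_id, idx$family_id)

  rows <- purrr::imap(fams, function(members, fam) {
    res <- tryCatch(
      fit_family_model(new_ms_design(big[members, , drop = FALSE], g_sample,
                                     epsilon = epsilon)),
      sncfam_rank_deficient = function(e) "rank_deficient",
      sncfam_insufficient_df = function(e) "insufficient_df",
      error = function(e) "fit_error"
    )
    if (is.character(res)) {
      tibble::tibble(family_id = fam, n_species = length(members),
                     beta1 = NA_real_, t_stat = NA_real_, df = NA_integer_,
                     p_value = NA_real_, direction = NA_character_,
                     status = res)
    } else {
      tibble::tibble(family_id = fam, n_species = res$n_species,
                     beta1 = res$beta1, t_stat = res$t_stat,
                     df = as.integer(res$df), p_value = res$p_value,
                     direction = res$direction, status = "ok")
    }
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- bonferroni_adjust(out$p_value, m_tests = nrow(out))
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  out |>
    dplyr::arrange(is.na(.data$p_value), .data$p_value, .data$family_id) |>
    dplyr::select("family_id", "n_species", "beta1", "t_stat", "df",
                  "p_value", "p_adjusted", "direction", "significant",
                  "status")
}
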