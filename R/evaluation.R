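#' Resampling robustness of the family-level t-statistics
#'
#' Repeatedly draws `n_per_group` samples per group without replacement,
#' reruns the family-level linear model on each subsample, and compares the
#' per-round t-statistic vector with the full-data one by Pearson
#' correlation. Families whose fit fails in the full data or in any round
#' are dropped from the t matrix so the correlations stay well defined.
#' With a fixed `seed` the report is fully reproducible.
#'
#' @inheritParams run_family_lm
#' @param n_per_group Samples drawn per group each round (>= 2 and at most
#'   the smaller group size).
#' @param rounds Number of resampling rounds (default 100).
#' @param seed Optional integer seed for the subsample draws.
#' @return A `resampling_report`: `t_matrix` (rounds x families), `t_full`,
#'   per-round `correlations`, and quantile summaries. Use [tidy()],
#'   [glance()] or [autoplot()] on it.
#' @export
resample_robustness <- function(abund, index, metadata, n_per_group,
                                rounds = 100, seed = NULL,
                                phenotype = "phenotype", ...) {
  if (rounds < 1) abort("rounds must be >= 1")
  groups <- split(metadata$sample_id, metadata[[phenotype]])
  if (length(groups) != 2) {
    abort("resampling needs a binary group phenotype")
  }
  sizes <- lengths(groups)
  if (n_per_group < 2 || n_per_group > min(sizes)) {
    abort(paste0("n_per_group must lie in [2, ", min(sizes),
                 "] (smaller group size)"))
  }
  full <- suppressMessages(
    run_family_lm(abund, index, metadata, phenotype = phenotype, ...)
  )
  ok <- full[full$status == "ok", ]
  t_full <- setNames(ok$t_stat, ok$family_id)

  draw_round <- function(round) {
    picked <- c(sample(groups[[1]], n_per_group),
                sample(groups[[2]], n_per_group))
    sub_md <- metadata[metadata$sample_id %in% picked, , drop = FALSE]
    sub_ab <- abund[abund$sample_id %in% picked, , drop = FALSE]
    res <- suppressMessages(
      run_family_lm(sub_ab, index, sub_md, phenotype = phenotype, ...)
    )
    res <- res[res$status == "ok", ]
    setNames(res$t_stat, res$family_id)
  }
  per_round <- if (is.null(seed)) {
    purrr::map(seq_len(rounds), draw_round)
  } else {
    withr::with_seed(seed, purrr::map(seq_len(rounds), draw_round))
  }

  fams <- Reduce(intersect, c(list(names(t_full)), purrr::map(per_round, names)))
  t_full <- t_full[fams]
  t_matrix <- do.call(rbind, purrr::map(per_round, function(v) v[fams]))
  rownames(t_matrix) <- paste0("round", seq_len(rounds))
  correlations <- apply(t_matrix, 1, function(v) {
    suppressWarnings(stats::cor(v, t_full))
  })

  q <- function(x, p) unname(quantile(x, p, na.rm = TRUE))
  family_summary <- tibble::tibble(
    family_id = fams,
    t_full = unname(t_full),
    t_mean = colMeans(t_matrix),
    t_q025 = apply(t_matrix, 2, q, 0.025),
    t_q975 = apply(t_matrix, 2, q, 0.975)
  )
  structure(
    list(
      n_per_group = n_per_group, rounds = rounds, seed = seed,
      families = fams, t_full = t_full, t_matrix = t_matrix,
      correlations = correlations,
      family_summary = family_summary,
      correlation_summary = c(mean = mean(correlations, na.rm = TRUE),
                              q025 = q(correlations, 0.025),
                              q975 = q(correlations, 0.975))
    ),
    class = "resampling_report"
  )
}

#' @export
print.resampling_report <- function(x, ...) {
  cat("Resampling robustness report: ", x$rounds, " rounds of ",
      x$n_per_group, " vs ", x$n_per_group, " samples, ",
      length(x$families), " families\n", sep = "")
  cat(sprintf("  correlation with full-data t: mean %.3f [%.3f, %.3f]\n",
              x$correlation_summary["mean"], x$correlation_summary["q025"],
              x$correlation_summary["q975"]))
  invisible(x)
}

#' @rdname resample_robustness
#' @param x A `resampling_report`.
#' @param ... Unused.
#' @export
tidy.resampling_report <- function(x, ...) x$family_summary

#' @rdname resample_robustness
#' @export
glance.resampling_report <- function(x, ...) {
  tibble::tibble(
    rounds = x$rounds, n_per_group = x$n_per_group,
    n_families = length(x$families),
    cor_mean = unname(x$correlation_summary["mean"]),
    cor_q025 = unname(x$correlation_summary["q025"]),
    cor_q975 = unname(x$correlation_summary["q975"])
  )
}

#' @rdname resample_robustness
#' @param object A `resampling_report`.
#' @export
autoplot.resampling_report <- function(object, ...) {
  df <- dplyr::arrange(object$family_summary, .data$t_full) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$t_q025,
                                      ymax = .data$t_q975),
                         fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$t_full), linewidth = 0.6) +
    ggplot2::labs(x = "families (ordered by full-data t)",
                  y = "t-statistic",
                  title = sprintf("Resampling %d vs %d (%d rounds)",
                                  object$n_per_group, object$n_per_group,
                                  object$rounds)) +
    ggplot2::theme_minimal()
}

#' Cross-cohort concordance of family-level t-statistics
#'
#' Pearson correlation between the t-statistics of two result tables over
#' their shared families, plus the list of common hits: families significant
#' (adjusted p < `alpha`) in both cohorts with the same direction.
#'
#' @param results_a,results_b Result tibbles from [run_family_lm()].
#' @param alpha Significance level for the common-hit call.
#' @return A `tstat_concordance` list with `r`, `p_value`, `n_shared`,
#'   `common_hits` and the joined `data` tibble.
#' @export
tstat_concordance <- function(results_a, results_b, alpha = 0.05) {
  joined <- dplyr::inner_join(
    dplyr::filter(results_a, .data$status == "ok"),
    dplyr::filter(results_b, .data$status == "ok"),
    by = "family_id", suffix = c("_a", "_b")
  )
  if (nrow(joined) < 3) {
    abort("need >= 3 families shared between the two result tables")
  }
  ct <- cor.test(joined$t_stat_a, joined$t_stat_b, method = "pearson")
  hits <- joined |>
    dplyr::filter(.data$p_adjusted_a < alpha, .data$p_adjusted_b < alpha,
                  .data$direction_a == .data$direction_b)
  structure(
    list(r = unname(ct$estimate), p_value = ct$p.value,
         n_shared = nrow(joined), common_hits = hits$family_id,
         data = joined),
    class = "tstat_concordance"
  )
}

#' @export
print.tstat_concordance <- function(x, ...) {
  cat(sprintf("t-statistic concordance over %d shared families: r = %.3f (p = %.3g)\n",
              x$n_shared, x$r, x$p_value))
  cat("  common hits:", length(x$common_hits), "\n")
  invisible(x)
}

#' @rdname tstat_concordance
#' @param x A `tstat_concordance` object.
#' @param ... Unused.
#' @export
glance.tstat_concordance <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value, n_shared = x$n_shared,
                 n_common_hits = length(x$common_hits))
}

#' @rdname tstat_concordance
#' @param object A `tstat_concordance` object.
#' @export
autoplot.tstat_concordance <- function(object, ...) {
  df <- object$data |>
    dplyr::mutate(hit = .data$family_id %in% object$common_hits)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_stat_a, y = .data$t_stat_b,
                                   colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 name = "common hit") +
    ggplot2::labs(x = "t-statistic, cohort A", y = "t-statistic, cohort B",
                  subtitle = sprintf("r = %.3f (p = %.3g)", object$r,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}

#' Per-sample coverage depth along a parental RNA
#'
#' For each sample, sums the RPM of every species whose annotated interval
#' `[start, end]` on the parent covers a position. Species mapped to the
#' parent without coordinates are excluded with a message.
#'
#' @param abund Long abundance tibble with `rpm`.
#' @param annotations Annotation tibble from [parse_annotations()].
#' @param parent Parent RNA id.
#' @param parent_length Length of the parent in nucleotides (must cover the
#'   largest annotated end).
#' @param samples Sample ids to profile (default: all).
#' @return Long tibble `sample_id`, `position`, `depth`.
#' @export
coverage_depth <- function(abund, annotations, parent, parent_length,
                           samples = NULL) {
  check_abundance(abund)
  samples <- samples %||% unique(abund$sample_id)
  restrict_samples(abund, samples)
  ann <- annotations[annotations$parent_id == parent, , drop = FALSE]
  no_coord <- is.na(ann$start) | is.na(ann$end)
  if (any(no_coord)) {
    inform(paste0(sum(no_coord), " species on ", parent,
                  " lack coordinates and are excluded from coverage"))
    ann <- ann[!no_coord, , drop = FALSE]
  }
  if (nrow(ann) > 0 && parent_length < max(ann$end)) {
    abort(paste0("parent_length ", parent_length,
                 " is smaller than the largest annotated end ",
                 max(ann$end)))
  }
  ann <- dplyr::distinct(ann[c("species_id", "start", "end")])
  rows <- purrr::map(samples, function(s) {
    sub <- abund[abund$sample_id == s & abund$species_id %in% ann$species_id, ]
    depth <- numeric(parent_length + 1)
    if (nrow(sub) > 0) {
      hit <- dplyr::left_join(ann, sub[c("species_id", "rpm")],
                              by = "species_id")
      hit <- hit[!is.na(hit$rpm), , drop = FALSE]
      for (i in seq_len(nrow(hit))) {
        depth[hit$start[i]] <- depth[hit$start[i]] + hit$rpm[i]
        depth[hit$end[i] + 1] <- depth[hit$end[i] + 1] - hit$rpm[i]
      }
      depth <- cumsum(depth)
    }
    tibble::tibble(sample_id = s, position = seq_len(parent_length),
                   depth = depth[seq_len(parent_length)])
  })
  dplyr::bind_rows(rows)
}

#' Mean coverage profile along a parental RNA
#'
#' Per-position mean RPM depth across a group of samples with the standard
#' error of the mean (`sd / sqrt(n)`; a single-sample group gets SEM 0 with
#' a warning).
#'
#' @inheritParams coverage_depth
#' @param group Optional label describing the sample group (stored on the
#'   result and used in plots).
#' @return A `coverage_profile` tibble: `position`, `mean_rpm`, `sem`.
#' @export
coverage_profile <- function(abund, annotations, parent, parent_length,
                             samples = NULL, group = NULL) {
  depth <- coverage_depth(abund, annotations, parent, parent_length,
                          samples = samples)
  n <- dplyr::n_distinct(depth$sample_id)
  if (n == 1) warn("single-sample group: SEM set to 0")
  prof <- depth |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(
      mean_rpm = mean(.data$depth),
      sem = if (dplyr::n() > 1) sd(.data$depth) / sqrt(dplyr::n()) else 0,
      .groups = "drop"
    )
  structure(prof, class = c("coverage_profile", class(prof)),
            parent = parent, n_samples = n, group = group)
}

#' @rdname coverage_profile
#' @param object A `coverage_profile`.
#' @param ... Unused.
#' @export
autoplot.coverage_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_rpm - .data$sem,
                                      ymax = .data$mean_rpm + .data$sem),
                         fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_rpm),
                       colour = "steelblue4") +
    ggplot2::labs(x = paste0("position on ", attr(object, "parent"), " (nt)"),
                  y = "mean RPM",
                  title = attr(object, "group")) +
    ggplot2::theme_minimal()
}

#' Per-family dysregulation proportions across a paired cohort
#'
#' Summarises a long per-pair result table ([run_signedrank_cohort()]) into
#' the fraction of pairs (patients) in which each family is significantly up,
#' significantly down, or not significant at the adjusted-p level `alpha`.
#' Proportions are exact fractions of the pair count and sum to 1.
#'
#' @param ps_results Long tibble with `pair_id`, `family_id`, `p_adjusted`,
#'   `direction`.
#' @param alpha Significance level on the adjusted p-value.
#' @return Tibble `family_id`, `n_pairs`, `prop_up`, `prop_down`, `prop_ns`.
#' @export
concordance_summary <- function(ps_results, alpha = 0.05) {
  ps_results |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_up = sum(.data$p_adjusted < alpha & .data$direction == "up"),
      n_down = sum(.data$p_adjusted < alpha & .data$direction == "down"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      prop_up = .data$n_up / .data$n_pairs,
      prop_down = .data$n_down / .data$n_pairs,
      prop_ns = (.data$n_pairs - .data$n_up - .data$n_down) / .data$n_pairs
    ) |>
    dplyr::select("family_id", "n_pairs", "prop_up", "prop_down", "prop_ns")
}
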