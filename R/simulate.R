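#' Simulate a multi-sample cohort with known family effects
#'
#' Generates a species-by-sample abundance table with log-normal species
#' abundances on the log10-RPM scale: species `i` of family `f` in sample
#' `s` has `log10 RPM = mu_i + gamma_f * x_s + e`, with `e ~ N(0, sigma^2)`
#' and `x_s` the 0/1 group indicator (1 = second group label). A fraction of
#' families carries a true group shift `gamma = effect_size`; the rest are
#' null. Counts are derived by rounding `RPM * library_size / 1e6` and the
#' returned RPM is recomputed from those counts, so the abundance table is
#' internally consistent (the quantisation perturbs the intended log-normal
#' values by at most half a count).
#'
#' @param n_families Number of families.
#' @param species_per_family Species per family: a single integer or a
#'   `c(min, max)` range sampled uniformly.
#' @param m_per_group Integer vector `c(m1, m2)` of samples per group.
#' @param effect_size True group shift `gamma` in log10-RPM units for
#'   dysregulated families.
#' @param fraction_dysregulated Fraction of families given the shift.
#' @param sigma Residual standard deviation in log10 units.
#' @param baseline_range `c(lo, hi)` range of species baseline means
#'   (log10 RPM); the default 0.5-2.5 spans roughly 3-300 RPM, comfortably
#'   above the 0.1 mean-RPM inclusion cut.
#' @param library_size Reads per sample used to derive counts (default 1e7,
#'   a typical small-RNA library depth).
#' @param group_labels Two phenotype labels; the first is the reference
#'   (lexicographic default coding in [run_family_lm()] expects
#'   `group_labels[1] < group_labels[2]`).
#' @param seed Optional integer seed; fixed seed gives identical cohorts.
#' @return An `snc_sim` list: `abundance` (long tibble), `metadata`,
#'   `index` (ready-to-use family index), `truth` (`family_id`, `gamma`,
#'   `direction`), and `params`.
#' @export
simulate_ms_cohort <- function(n_families = 100, species_per_family = 5,
                               m_per_group = c(5, 5), effect_size = 0.5,
                               fraction_dysregulated = 0.2, sigma = 0.3,
                               baseline_range = c(0.5, 2.5),
                               library_size = 1e7,
                               group_labels = c("control", "patient"),
                               seed = NULL) {
  check_sim_args(n_families, species_per_family, sigma, fraction_dysregulated)
  if (length(m_per_group) != 2 || any(m_per_group < 1)) {
    abort("m_per_group must be two positive integers")
  }
  run <- function() {
    samples <- c(sprintf("%s%02d", group_labels[1], seq_len(m_per_group[1])),
                 sprintf("%s%02d", group_labels[2], seq_len(m_per_group[2])))
    x <- rep(c(0, 1), times = m_per_group)
    metadata <- tibble::tibble(sample_id = samples,
                               phenotype = rep(group_labels, times = m_per_group))
    layout <- family_layout(n_families, species_per_family,
                            fraction_dysregulated, effect_size,
                            baseline_range)
    m <- length(samples)
    logrpm <- layout$mu + outer(layout$gamma_species, x) +
      matrix(stats::rnorm(nrow(layout) * m, sd = sigma), ncol = m)
    assemble_sim(layout, logrpm, samples, metadata, library_size,
                 params = list(kind = "ms", n_families = n_families,
                               m_per_group = m_per_group,
                               effect_size = effect_size,
                               fraction_dysregulated = fraction_dysregulated,
                               sigma = sigma, seed = seed))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a paired-sample cohort with known family effects
#'
#' For every pair, both members draw symmetric log10 noise around a shared
#' species baseline: `s1 = 10^(mu_i + e1)` and `s2 = 10^(mu_i + gamma_f + e2)`
#' with independent `e1, e2 ~ N(0, sigma^2)`, where sample 2 carries the
#' second condition label (e.g. tumor). Under `gamma = 0` the two profiles
#' are exchangeable, so paired differences are symmetric about zero — the
#' regime in which the signed-rank null holds exactly. Counts and RPM are
#' quantised as in [simulate_ms_cohort()].
#'
#' @inheritParams simulate_ms_cohort
#' @param species_per_family Species per family (default 20; paired
#'   rank tests need reasonably sized families to resolve small p-values).
#' @param n_pairs Number of sample pairs.
#' @param conditions Two condition labels; `gamma` shifts the second one.
#' @return An `snc_sim` list as in [simulate_ms_cohort()], with `metadata`
#'   carrying `pair_id`.
#' @export
simulate_paired_cohort <- function(n_families = 50, species_per_family = 20,
                                   n_pairs = 10, effect_size = 0.5,
                                   fraction_dysregulated = 0.2, sigma = 0.3,
                                   baseline_range = c(0.5, 2.5),
                                   library_size = 1e7,
                                   conditions = c("normal", "tumor"),
                                   seed = NULL) {
  check_sim_args(n_families, species_per_family, sigma, fraction_dysregulated)
  if (n_pairs < 1) abort("n_pairs must be >= 1")
  run <- function() {
    pair_ids <- sprintf("pair%02d", seq_len(n_pairs))
    samples <- as.vector(t(outer(pair_ids, conditions, paste, sep = "_")))
    metadata <- tibble::tibble(
      sample_id = samples,
      phenotype = rep(conditions, times = n_pairs),
      pair_id = rep(pair_ids, each = 2)
    )
    layout <- family_layout(n_families, species_per_family,
                            fraction_dysregulated, effect_size,
                            baseline_range)
    m <- length(samples)
    shift <- outer(layout$gamma_species,
                   rep(c(0, 1), times = n_pairs))  # gamma on condition 2
    logrpm <- layout$mu + shift +
      matrix(stats::rnorm(nrow(layout) * m, sd = sigma), ncol = m)
    assemble_sim(layout, logrpm, samples, metadata, library_size,
                 params = list(kind = "paired", n_families = n_families,
                               n_pairs = n_pairs,
                               effect_size = effect_size,
                               fraction_dysregulated = fraction_dysregulated,
                               sigma = sigma, seed = seed))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# internal: shared argument checks
check_sim_args <- function(n_families, species_per_family, sigma, fraction) {
  if (n_families < 1) abort("n_families must be >= 1")
  if (any(species_per_family < 2)) {
    abort("species_per_family must be >= 2 (family constraint)")
  }
  if (sigma < 0) abort("sigma must be >= 0")
  if (fraction < 0 || fraction > 1) {
    abort("fraction_dysregulated must lie in [0, 1]")
  }
}

# internal: per-species layout (family ids, baselines, true gammas)
family_layout <- function(n_families, species_per_family, fraction,
                          effect_size, baseline_range) {
  fam_ids <- sprintf("fam%04d", seq_len(n_families))
  n_dys <- round(fraction * n_families)
  dys <- if (n_dys > 0) sample(fam_ids, n_dys) else character(0)
  gamma_fam <- setNames(ifelse(fam_ids %in% dys, effect_size, 0), fam_ids)
  n_sp <- if (length(species_per_family) == 2) {
    sample(species_per_family[1]:species_per_family[2], n_families,
           replace = TRUE)
  } else {
    rep(species_per_family, n_families)
  }
  fam_of_species <- rep(fam_ids, times = n_sp)
  out <- tibble::tibble(
    family_id = fam_of_species,
    species_id = paste0(fam_of_species, "_sp",
                        sprintf("%04d", sequence(n_sp))),
    mu = stats::runif(length(fam_of_species), baseline_range[1],
                      baseline_range[2]),
    gamma_species = unname(gamma_fam[fam_of_species])
  )
  attr(out, "gamma_fam") <- gamma_fam
  out
}

# internal: quantise to counts and build the snc_sim object
assemble_sim <- function(layout, logrpm, samples, metadata, library_size,
                         params) {
  rpm <- 10^logrpm
  counts <- round(rpm * library_size / 1e6)
  n_sp <- nrow(layout)
  m <- length(samples)
  seqs <- random_sequences(n_sp)
  abundance <- tibble::tibble(
    species_id = rep(layout$species_id, each = m),
    sequence = rep(seqs, each = m),
    annotation = rep(layout$family_id, each = m),
    start = NA_real_, end = NA_real_,
    sample_id = rep(samples, times = n_sp),
    count = as.vector(t(counts)),
    library_size = library_size
  ) |>
    dplyr::mutate(rpm = .data$count / .data$library_size * 1e6)
  index <- abundance |>
    species_mean_rpm() |>
    dplyr::left_join(layout[c("species_id", "family_id")], by = "species_id") |>
    dplyr::mutate(uniquely_annotated = TRUE) |>
    dplyr::select("family_id", "species_id", "mean_rpm",
                  "uniquely_annotated") |>
    dplyr::arrange(.data$family_id, dplyr::desc(.data$mean_rpm),
                   .data$species_id)
  gamma_fam <- attr(layout, "gamma_fam")
  truth <- tibble::tibble(
    family_id = names(gamma_fam),
    gamma = unname(gamma_fam),
    direction = dplyr::case_when(gamma_fam > 0 ~ "up",
                                 gamma_fam < 0 ~ "down",
                                 TRUE ~ "none"),
    n_species = as.vector(table(layout$family_id)[names(gamma_fam)])
  )
  structure(
    list(abundance = abundance, metadata = metadata, index = index,
         truth = truth, params = params),
    class = "snc_sim"
  )
}

# internal: random RNA-like sequences (20-34 nt), unique by construction
random_sequences <- function(n) {
  len <- sample(20:34, n, replace = TRUE)
  seqs <- vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
  make.unique(seqs, sep = "N")
}

#' @export
print.snc_sim <- function(x, ...) {
  cat("Synthetic sncRNA cohort (", x$params$kind, "): ",
      dplyr::n_distinct(x$index$family_id), " families, ",
      dplyr::n_distinct(x$abundance$species_id), " species, ",
      dplyr::n_distinct(x$abundance$sample_id), " samples\n", sep = "")
  cat("  dysregulated families:", sum(x$truth$gamma != 0),
      "at gamma =", x$params$effect_size, "\n")
  invisible(x)
}

#' Write a synthetic cohort to TSV files
#'
#' Produces `<prefix>_species.tsv` (wide species table readable by
#' [read_species_table()]), `<prefix>_meta.tsv` and `<prefix>_truth.tsv`.
#'
#' @param sim An `snc_sim` object.
#' @param prefix Output path prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim <- function(sim, prefix) {
  paths <- c(species = paste0(prefix, "_species.tsv"),
             meta = paste0(prefix, "_meta.tsv"),
             truth = paste0(prefix, "_truth.tsv"))
  write_species_table(sim$abundance, paths["species"])
  readr::write_tsv(sim$metadata, paths["meta"], progress = FALSE)
  readr::write_tsv(sim$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}
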