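#' Default annotation-to-family rules
#'
#' A family rule set is a tibble with columns `pattern` (a regular
#' expression matched against one parental-RNA annotation) and `family`
#' (a replacement template that may use backreferences). Rules are tried in
#' order; the first match names the family. The defaults cover the common
#' noncanonical classes:
#' genomic tRNA anticodon families (`tRNA-Gly-GCC` -> `GtsRNA-Gly-GCC`),
#' mitochondrial tRNAs (`mt-tRNA-...` -> `MtsRNA-...`), rRNA subunits
#' (`28S`, `rRNA-28S`, `28S rRNA` -> `rsRNA-28S`), Y RNAs (`RNY1` ->
#' `ysRNA-RNY1`), snRNA/snoRNA parents and mature miRNA names.
#'
#' @return Tibble with columns `pattern` and `family`.
#' @export
default_family_rules <- function() {
  tibble::tribble(
    ~pattern,                                               ~family,
    "^mt[-_ ]?tRNA[-_]([A-Za-z]{3})[-_]([A-Za-z]{3})$",     "MtsRNA-\\1-\\2",
    "^(?:genomic[-_ ])?tRNA[-_]([A-Za-z]{3})[-_]([A-Za-z]{3})$", "GtsRNA-\\1-\\2",
    "^(?:rRNA[-_ ])?([0-9]+(?:\\.[0-9]+)?S)(?:[-_ ]rRNA)?$", "rsRNA-\\1",
    "^(?:Y[-_ ]?RNA[-_ ])?(RNY[0-9]+)$",                    "ysRNA-\\1",
    "^snRNA[-_ ](.+)$",                                     "snsRNA-\\1",
    "^snoRNA[-_ ](.+)$",                                    "snosRNA-\\1",
    "^(?:[a-z]{3}[-_])?((?:miR|let)[-_]?[0-9][0-9a-zA-Z-]*)$", "miRNA-\\1"
  )
}

#' Load family rules from a YAML file
#'
#' The file holds a list of mappings, each with keys `pattern` and `family`.
#'
#' @param path Path to the YAML rule file.
#' @return Tibble with columns `pattern` and `family`.
#' @export
family_rules_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) abort("empty family rule file")
  rules <- purrr::map_dfr(raw, function(entry) {
    extra <- setdiff(names(entry), c("pattern", "family"))
    if (length(extra) > 0) {
      abort(paste0("unknown key(s) in family rule: ",
                   paste(extra, collapse = ", ")))
    }
    tibble::tibble(pattern = entry$pattern, family = entry$family)
  })
  rules
}

#' Parse per-species parental annotations
#'
#' Splits multi-annotation cells, extracts `parent:start-end` coordinate
#' suffixes (1-based inclusive) and applies the family rule set. Annotations
#' matching no rule get `family_id = NA` and are reported by
#' [assign_families()] as unassigned rather than dropped silently.
#'
#' @param abund Long abundance tibble (needs `species_id`, `annotation`, and
#'   optionally `start`/`end` columns).
#' @param rules Family rule tibble, see [default_family_rules()].
#' @param delimiter Separator between annotations within a cell.
#' @return Tibble with one row per (species, annotation): `species_id`,
#'   `parent_id`, `family_id`, `start`, `end`.
#' @export
parse_annotations <- function(abund, rules = default_family_rules(),
                              delimiter = ";") {
  if (!"annotation" %in% names(abund)) {
    abort("abundance table lacks an 'annotation' column")
  }
  species <- dplyr::distinct(tibble::tibble(
    species_id = abund$species_id,
    annotation = abund$annotation,
    start = if ("start" %in% names(abund)) abund$start else NA_real_,
    end = if ("end" %in% names(abund)) abund$end else NA_real_
  ))
  if (any(is.na(species$annotation) | species$annotation == "")) {
    abort("every species entering family analysis needs >= 1 annotation")
  }
  ann <- species |>
    tidyr::separate_longer_delim("annotation", delim = delimiter) |>
    dplyr::mutate(annotation = trimws(.data$annotation))

  # coordinate suffix "parent:start-end" beats the table-level columns
  has_coord <- grepl(":[0-9]+-[0-9]+$", ann$annotation)
  coord <- regmatches(ann$annotation, regexpr(":[0-9]+-[0-9]+$", ann$annotation))
  ann$parent_id <- sub(":[0-9]+-[0-9]+$", "", ann$annotation)
  ann$start[has_coord] <- as.numeric(sub("^:([0-9]+)-[0-9]+$", "\\1", coord))
  ann$end[has_coord] <- as.numeric(sub("^:[0-9]+-([0-9]+)$", "\\1", coord))
  bad <- !is.na(ann$start) & !is.na(ann$end) &
    (ann$start < 1 | ann$start > ann$end)
  if (any(bad)) {
    abort(paste0("invalid coordinates (need 1 <= start <= end) for: ",
                 paste(head(unique(ann$parent_id[bad]), 3), collapse = ", ")))
  }

  ann$family_id <- apply_family_rules(ann$parent_id, rules)
  ann |>
    dplyr::select("species_id", "parent_id", "family_id", "start", "end")
}

# internal: first-matching-rule family derivation
apply_family_rules <- function(parents, rules) {
  fam <- rep(NA_character_, length(parents))
  todo <- rep(TRUE, length(parents))
  for (i in seq_len(nrow(rules))) {
    hit <- todo & grepl(rules$pattern[i], parents, perl = TRUE)
    if (any(hit)) {
      fam[hit] <- sub(rules$pattern[i], rules$family[i], parents[hit],
                      perl = TRUE)
      todo[hit] <- FALSE
    }
  }
  fam
}

#' Build the family membership index
#'
#' Maps every species to each family its annotations resolve to (species with
#' several parents join several families). A species is `uniquely_annotated`
#' when all of its annotations map to one single family. Members are ordered
#' within a family by mean RPM descending, ties broken by `species_id`.
#' Annotations matching no rule are collected in the `unassigned` attribute
#' and reported, never silently dropped.
#'
#' @inheritParams parse_annotations
#' @return Tibble with columns `family_id`, `species_id`, `mean_rpm`,
#'   `uniquely_annotated`; attribute `unassigned` holds the unmatched
#'   (species, parent) pairs.
#' @export
assign_families <- function(abund, rules = default_family_rules(),
                            delimiter = ";") {
  check_abundance(abund)
  ann <- parse_annotations(abund, rules = rules, delimiter = delimiter)
  unassigned <- ann |>
    dplyr::filter(is.na(.data$family_id)) |>
    dplyr::select("species_id", "parent_id")
  if (nrow(unassigned) > 0) {
    inform(paste0(nrow(unassigned), " annotation(s) from ",
                  dplyr::n_distinct(unassigned$species_id),
                  " species matched no family rule (kept in the ",
                  "'unassigned' attribute)"))
  }
  flags <- ann |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      uniquely_annotated = all(!is.na(.data$family_id)) &&
        dplyr::n_distinct(.data$family_id) == 1,
      .groups = "drop"
    )
  index <- ann |>
    dplyr::filter(!is.na(.data$family_id)) |>
    dplyr::distinct(.data$family_id, .data$species_id) |>
    dplyr::left_join(flags, by = "species_id") |>
    dplyr::left_join(species_mean_rpm(abund), by = "species_id") |>
    dplyr::select("family_id", "species_id", "mean_rpm", "uniquely_annotated") |>
    dplyr::arrange(.data$family_id, dplyr::desc(.data$mean_rpm), .data$species_id)
  attr(index, "unassigned") <- unassigned
  index
}

#' Apply family-size constraints
#'
#' Drops families with fewer than `min_species` members and truncates
#' families larger than `max_species` to their `max_species` highest-mean-RPM
#' members (ties by `species_id` ascending). The default window — at least
#' two species, at most the top 1000 by RPM — is the conventional testing
#' window for family-level analysis.
#'
#' @param index Family index tibble from [assign_families()].
#' @param min_species Minimum members per family (default 2).
#' @param max_species Cap on members per family (default 1000).
#' @return The constrained index, sorted as the input.
#' @export
apply_family_constraints <- function(index, min_species = 2,
                                     max_species = 1000) {
  if (max_species < min_species) abort("max_species must be >= min_species")
  if (min_species < 2) {
    warn("min_species < 2 departs from the standard >= 2 species rule")
  }
  out <- index |>
    dplyr::arrange(.data$family_id, dplyr::desc(.data$mean_rpm),
                   .data$species_id) |>
    dplyr::group_by(.data$family_id) |>
    dplyr::slice_head(n = max_species) |>
    dplyr::filter(dplyr::n() >= min_species) |>
    dplyr::ungroup()
  inform(paste0(dplyr::n_distinct(out$family_id), " of ",
                dplyr::n_distinct(index$family_id),
                " families within [", min_species, ", ", max_species,
                "] species"))
  out
}

#' Restrict a family index to uniquely annotated species
#'
#' Keeps only species whose annotations all resolve to a single family, then
#' re-applies the family-size constraints (families may fall below
#' `min_species` and be removed). This is the stricter option for users who
#' want to exclude multi-mapping species at the cost of sensitivity.
#'
#' @inheritParams apply_family_constraints
#' @return The restricted, re-constrained index.
#' @export
restrict_unique_annotation <- function(index, min_species = 2,
                                       max_species = 1000) {
  if (!"uniquely_annotated" %in% names(index)) {
    abort("index lacks the uniquely_annotated flag; rebuild with assign_families()")
  }
  index |>
    dplyr::filter(.data$uniquely_annotated) |>
    apply_family_constraints(min_species = min_species,
                             max_species = max_species)
}

#' Number of families in an index
#'
#' The Bonferroni multiplier for family-level testing counts families, not
#' species.
#'
#' @param index Family index tibble.
#' @return Integer count of distinct families.
#' @export
n_families <- function(index) dplyr::n_distinct(index$family_id)

#' Bonferroni multiple-testing adjustment
#'
#' `adjusted_i = min(1, p_i * m_tests)`, order preserved. The multiplier
#' defaults to the number of p-values but can be set explicitly (e.g. the
#' number of families attempted when some fits failed).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (NAs pass through).
#' @param m_tests Number of tests to correct for.
#' @return Adjusted p-values in \[0, 1\].
#' @export
bonferroni_adjust <- function(pvalues, m_tests = length(pvalues)) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) abort("p-values must lie in [0, 1]")
  pmin(1, pvalues * m_tests)
}
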