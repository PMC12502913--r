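#' Describe the column layout of a species-level quantification table
#'
#' Species-level small-RNA quantification tables (e.g. SPORTS-style output)
#' vary in their column naming. A format object maps the columns of a concrete
#' TSV onto the fields [read_species_table()] needs.
#'
#' @param sequence Name of the column holding the RNA sequence.
#' @param annotation Name of the column holding the parental-RNA annotation(s).
#'   A cell may contain several annotations separated by `delimiter`; an
#'   individual annotation may carry coordinates on its parent as a
#'   `parent:start-end` suffix (1-based, inclusive).
#' @param species_id Optional name of a column holding a unique species
#'   identifier. Defaults to `NULL`, in which case the sequence is the id.
#' @param counts Character vector of count column names, or `NULL` to use
#'   every column not otherwise mapped.
#' @param start,end Optional names of columns with 1-based inclusive
#'   coordinates on the parental RNA (used when the annotation strings carry
#'   no coordinate suffix).
#' @param delimiter Separator between multiple annotations in one cell.
#' @return A `species_format` list.
#' @export
#' @examples
#' species_format(sequence = "seq", annotation = "anno")
species_format <- function(sequence = "sequence", annotation = "annotation",
                           species_id = NULL, counts = NULL,
                           start = NULL, end = NULL, delimiter = ";") {
  structure(
    list(sequence = sequence, annotation = annotation,
         species_id = species_id, counts = counts,
         start = start, end = end, delimiter = delimiter),
    class = "species_format"
  )
}

#' Read a species-level quantification table
#'
#' Reads a tab-separated species-by-sample count table into the long "tidy
#' abundance" form used throughout the package: one row per species and
#' sample, with columns `species_id`, `sequence`, `annotation`, `start`,
#' `end`, `sample_id`, `count`, `library_size` and `rpm`. Reads-per-million
#' (RPM) values are computed immediately, with library sizes defaulting to
#' the per-sample column sums of the table.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @param format A [species_format()] describing the column layout.
#' @param library_sizes Optional per-sample library sizes (named numeric
#'   vector or two-column data frame `sample_id`, `library_size`) overriding
#'   the column-sum default.
#' @return A tibble in long abundance form.
#' @export
read_species_table <- function(path, format = species_format(),
                               library_sizes = NULL) {
  if (!file.exists(path)) {
    abort(paste0("species table not found: ", path))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  for (field in c("sequence", "annotation", "species_id", "start", "end")) {
    col <- format[[field]]
    if (!is.null(col) && !col %in% names(raw)) {
      abort(paste0("configured ", field, " column '", col,
                   "' is missing from ", path))
    }
  }
  if (is.null(format$species_id) && "species_id" %in% names(raw)) {
    format$species_id <- "species_id"
  }
  mapped <- c(format$sequence, format$annotation, format$species_id,
              format$start, format$end)
  count_cols <- format$counts %||% setdiff(names(raw), mapped)
  missing_counts <- setdiff(count_cols, names(raw))
  if (length(missing_counts) > 0) {
    abort(paste0("configured count column(s) missing: ",
                 paste(missing_counts, collapse = ", ")))
  }
  if (length(count_cols) == 0) abort("no count columns found in table")

  tab <- tibble::tibble(
    species_id = if (is.null(format$species_id)) raw[[format$sequence]]
                 else raw[[format$species_id]],
    sequence   = raw[[format$sequence]],
    annotation = raw[[format$annotation]],
    start      = if (is.null(format$start)) NA_real_
                 else suppressWarnings(as.numeric(raw[[format$start]])),
    end        = if (is.null(format$end)) NA_real_
                 else suppressWarnings(as.numeric(raw[[format$end]]))
  )
  dup <- tab$species_id[duplicated(tab$species_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate species_id in table: ",
                 paste(unique(dup), collapse = ", ")))
  }

  counts <- raw[count_cols]
  for (col in count_cols) {
    parsed <- suppressWarnings(as.numeric(counts[[col]]))
    bad <- which(is.na(parsed) | parsed < 0 | parsed != floor(parsed))
    if (length(bad) > 0) {
      abort(paste0("count column '", col, "' has a negative or non-integer ",
                   "value at data row ", bad[1]))
    }
    counts[[col]] <- parsed
  }

  abund <- dplyr::bind_cols(tab, counts) |>
    tidyr::pivot_longer(dplyr::all_of(count_cols),
                        names_to = "sample_id", values_to = "count") |>
    dplyr::arrange(match(.data$species_id, tab$species_id),
                   match(.data$sample_id, count_cols))
  abund <- compute_rpm(abund, library_sizes = library_sizes)
  inform(paste0("read ", nrow(tab), " species x ", length(count_cols),
                " samples from ", basename(path)))
  abund
}

#' Write a long abundance table back to species-by-sample TSV
#'
#' Inverse of [read_species_table()]: one row per species, one count column
#' per sample. Coordinates are written only when any are present.
#'
#' @param abund Long abundance tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(abund, path) {
  check_abundance(abund, need_rpm = FALSE)
  meta_cols <- c("species_id", "sequence", "annotation")
  if (any(!is.na(abund$start))) meta_cols <- c(meta_cols, "start", "end")
  wide <- abund |>
    dplyr::select(dplyr::all_of(c(meta_cols, "sample_id", "count"))) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Compute reads-per-million abundances
#'
#' Adds (or refreshes) `library_size` and `rpm` columns:
#' `rpm = count / library_size * 1e6`. By default each sample's library size
#' is the sum of its counts in `abund`; externally determined totals (e.g.
#' total clean reads) can be supplied instead.
#'
#' @param abund Long abundance tibble with `species_id`, `sample_id`, `count`.
#' @param library_sizes Optional named numeric vector (names = sample ids) or
#'   data frame with columns `sample_id` and `library_size`.
#' @return The tibble with `library_size` and `rpm` columns.
#' @export
compute_rpm <- function(abund, library_sizes = NULL) {
  check_abundance(abund, need_rpm = FALSE)
  samples <- unique(abund$sample_id)
  if (is.null(library_sizes)) {
    ls_tbl <- abund |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(library_size = sum(.data$count), .groups = "drop")
  } else {
    if (is.data.frame(library_sizes)) {
      ls_tbl <- tibble::as_tibble(library_sizes)[c("sample_id", "library_size")]
    } else {
      if (is.null(names(library_sizes)) && length(library_sizes) == length(samples)) {
        names(library_sizes) <- samples
      }
      ls_tbl <- tibble::tibble(sample_id = names(library_sizes),
                               library_size = as.numeric(library_sizes))
    }
    missing <- setdiff(samples, ls_tbl$sample_id)
    if (length(missing) > 0) {
      abort(paste0("no library size given for sample(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  bad <- ls_tbl$sample_id[is.na(ls_tbl$library_size) | ls_tbl$library_size <= 0]
  if (length(bad) > 0) {
    abort(paste0("library size must be positive; offending sample(s): ",
                 paste(bad, collapse = ", ")))
  }
  abund$library_size <- NULL
  abund$rpm <- NULL
  abund |>
    dplyr::left_join(ls_tbl, by = "sample_id") |>
    dplyr::mutate(rpm = .data$count / .data$library_size * 1e6)
}

#' Per-species mean RPM
#'
#' @param abund Long abundance tibble with an `rpm` column.
#' @param samples Optional character vector of sample ids to average over
#'   (default: all samples present).
#' @return Tibble with `species_id` and `mean_rpm`.
#' @export
species_mean_rpm <- function(abund, samples = NULL) {
  check_abundance(abund)
  sub <- restrict_samples(abund, samples)
  sub |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(mean_rpm = mean(.data$rpm), .groups = "drop")
}

#' Filter species by mean RPM
#'
#' Retains exactly the species whose mean RPM across the designated samples
#' is strictly greater than `threshold` (default 0.1, the conventional
#' inclusion cut for species-level small-RNA tables). All samples of a
#' retained species are kept; row order is preserved.
#'
#' @inheritParams species_mean_rpm
#' @param threshold Non-negative mean-RPM cut; species must exceed it
#'   strictly.
#' @return The filtered abundance tibble.
#' @export
filter_by_mean_rpm <- function(abund, threshold = 0.1, samples = NULL) {
  check_abundance(abund)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    abort("threshold must be a single non-negative number")
  }
  means <- species_mean_rpm(abund, samples = samples)
  keep <- means$species_id[means$mean_rpm > threshold]
  out <- abund[abund$species_id %in% keep, , drop = FALSE]
  inform(paste0(length(keep), " of ", nrow(means),
                " species retained at mean RPM > ", threshold))
  out
}

# internal: validate the long abundance layout
check_abundance <- function(abund, need_rpm = TRUE) {
  need <- c("species_id", "sample_id", "count")
  if (need_rpm) need <- c(need, "rpm")
  missing <- setdiff(need, names(abund))
  if (length(missing) > 0) {
    abort(paste0("abundance table lacks column(s): ",
                 paste(missing, collapse = ", "),
                 if ("rpm" %in% missing) " (run compute_rpm() first)" else ""))
  }
  if (any(abund$count < 0, na.rm = TRUE)) abort("negative counts in abundance table")
  invisible(abund)
}

# internal: subset samples with validation
restrict_samples <- function(abund, samples) {
  if (is.null(samples)) return(abund)
  if (length(samples) == 0) abort("sample subset is empty")
  unknown <- setdiff(samples, unique(abund$sample_id))
  if (length(unknown) > 0) {
    abort(paste0("unknown sample id(s): ", paste(unknown, collapse = ", ")))
  }
  abund[abund$sample_id %in% samples, , drop = FALSE]
}
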