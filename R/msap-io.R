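#' Read and binarize a capillary MSAP peak table
#'
#' Reads an instrument-style peak export (one row per detected peak) and
#' converts it to a binary fragment presence table. A fragment identity is a
#' (primer combination, size in bp) pair; a fragment is scored present in a
#' given sample, enzyme lane and replicate when a peak of at least
#' `height_threshold` fluorescence units was detected there. Every declared
#' fragment x sample x lane x replicate combination without such a peak is
#' scored absent, so the output is a complete binary grid.
#'
#' @param path Path to a CSV file with columns
#'   `sample,primer_combo,enzyme_lane,replicate,size_bp,height`.
#'   `enzyme_lane` must be `"H"` (EcoRI + HpaII digest) or `"M"`
#'   (EcoRI + MspI digest).
#' @param height_threshold Minimum peak height (relative fluorescence
#'   units) for a fragment to be scored present. Default 50.
#' @return A fragment table: tibble with columns `sample`, `primer_combo`,
#'   `size_bp`, `enzyme_lane`, `replicate`, `present` (0/1).
#' @details Duplicate peak rows for the same fragment, sample, lane and
#'   replicate are resolved by keeping the maximum height, with a warning.
#'   Malformed rows raise an error naming the offending line of the file.
#'   An empty file yields an empty (zero-row) fragment table.
#' @seealso [read_scored_matrix()] for pre-scored 0/1 input,
#'   [filter_size_range()], [filter_reproducible()].
#' @export
read_peak_table <- function(path, height_threshold = 50) {
  stopifnot(file.exists(path), height_threshold >= 0)
  empty <- tibble::tibble(
    sample = character(), primer_combo = character(),
    size_bp = integer(), enzyme_lane = character(),
    replicate = integer(), present = integer()
  )
  if (file.size(path) == 0) return(empty)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      sample = readr::col_character(),
      primer_combo = readr::col_character(),
      enzyme_lane = readr::col_character(),
      replicate = readr::col_integer(),
      size_bp = readr::col_integer(),
      height = readr::col_double()
    )
  )
  assert_cols(raw, c("sample", "primer_combo", "enzyme_lane", "replicate",
                     "size_bp", "height"), "peak table")
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop(sprintf("malformed peak table row at line %d of '%s' (%s)",
                 prob$row[1] + 1L, path, prob$expected[1]), call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty)
  bad <- which(
    is.na(raw$sample) | is.na(raw$primer_combo) | is.na(raw$height) |
      !(raw$enzyme_lane %in% c("H", "M")) |
      is.na(raw$size_bp) | raw$size_bp <= 0L |
      is.na(raw$replicate) | raw$replicate <= 0L | raw$height < 0
  )
  if (length(bad) > 0) {
    stop(sprintf("malformed peak table row at line %d of '%s'",
                 bad[1] + 1L, path), call. = FALSE)
  }

  peaks <- raw |>
    dplyr::summarise(
      n_rows = dplyr::n(),
      conflict = dplyr::n_distinct(.data$height) > 1L,
      height = max(.data$height),
      .by = c("sample", "primer_combo", "size_bp", "enzyme_lane", "replicate")
    )
  if (any(peaks$conflict)) {
    warning(sprintf(
      "%d duplicate peak(s) with conflicting heights; keeping the maximum",
      sum(peaks$conflict)
    ), call. = FALSE)
  }

  grid <- tidyr::expand_grid(
    dplyr::distinct(peaks, .data$primer_combo, .data$size_bp),
    sample = sort(unique(peaks$sample)),
    enzyme_lane = c("H", "M"),
    replicate = sort(unique(peaks$replicate))
  )
  grid |>
    dplyr::left_join(
      peaks,
      by = c("sample", "primer_combo", "size_bp", "enzyme_lane", "replicate")
    ) |>
    dplyr::mutate(present = as.integer(
      !is.na(.data$height) & .data$height >= .env$height_threshold
    )) |>
    dplyr::select("sample", "primer_combo", "size_bp", "enzyme_lane",
                  "replicate", "present") |>
    dplyr::arrange(.data$sample, .data$primer_combo, .data$size_bp,
                   .data$enzyme_lane, .data$replicate)
}

#' Read a pre-scored binary MSAP fragment matrix
#'
#' Reads a wide 0/1 matrix as commonly distributed with MSAP studies: one
#' row per fragment (identifier `<primer_combo>_<size_bp>`), one column per
#' `<sample>|<lane>|<replicate>` combination.
#'
#' @param path Path to a TSV file. The first column (any name) holds
#'   fragment identifiers; remaining column names must be
#'   `sample|lane|replicate` with lane `H` or `M`.
#' @return A fragment table in the same long format as [read_peak_table()].
#' @export
read_scored_matrix <- function(path) {
  stopifnot(file.exists(path))
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(wide)[1] <- "fragment_id"
  wide$fragment_id <- as.character(wide$fragment_id)
  long <- tidyr::pivot_longer(wide, -"fragment_id",
                              names_to = "key", values_to = "present")
  assert_binary(long$present, "scored matrix cell")
  parts <- strsplit(long$key, "|", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("scored matrix column names must be '<sample>|<lane>|<replicate>'",
         call. = FALSE)
  }
  us <- regexpr("_(?=[0-9]+$)", long$fragment_id, perl = TRUE)
  if (any(us < 0)) {
    stop("fragment identifiers must be '<primer_combo>_<size_bp>'",
         call. = FALSE)
  }
  long |>
    dplyr::mutate(
      sample = vapply(parts, `[`, "", 1L),
      enzyme_lane = vapply(parts, `[`, "", 2L),
      replicate = as.integer(vapply(parts, `[`, "", 3L)),
      primer_combo = substr(.data$fragment_id, 1L, us - 1L),
      size_bp = as.integer(substr(.data$fragment_id, us + 1L,
                                  nchar(.data$fragment_id))),
      present = as.integer(.data$present)
    ) |>
    dplyr::select("sample", "primer_combo", "size_bp", "enzyme_lane",
                  "replicate", "present")
}

#' Write a methylation profile report
#'
#' Writes per-sample methylation profiles as a TSV mirroring the layout of
#' a published methylation-status table: sample, ploidy, then non-, total,
#' fully and hemi-methylated percentages to one decimal place.
#'
#' @param profiles A profile tibble from [build_profiles()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profiles, path) {
  assert_cols(profiles, c("sample", "ploidy", "p_non", "p_total",
                          "p_full", "p_hemi"), "profile table")
  out <- profiles |>
    dplyr::transmute(
      sample = .data$sample,
      ploidy = .data$ploidy,
      non_pct = sprintf("%.1f", 100 * .data$p_non),
      total_pct = sprintf("%.1f", 100 * .data$p_total),
      full_pct = sprintf("%.1f", 100 * .data$p_full),
      hemi_pct = sprintf("%.1f", 100 * .data$p_hemi)
    )
  readr::write_tsv(out, path)
  invisible(path)
}
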