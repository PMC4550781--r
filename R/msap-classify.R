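#' Restrict a fragment table to a scoreable size window
#'
#' Keeps only fragments whose estimated size lies in the closed interval
#' `[min_bp, max_bp]`. Small and very large AFLP/MSAP fragments size
#' poorly against the internal standard, so scoring is conventionally
#' restricted to a window; the default window is 120--480 bp.
#'
#' @param table A fragment table (see [read_peak_table()]).
#' @param min_bp,max_bp Closed interval bounds in base pairs.
#' @return The fragment table restricted to the window.
#' @export
filter_size_range <- function(table, min_bp = 120, max_bp = 480) {
  assert_cols(table, c("primer_combo", "size_bp", "present"), "fragment table")
  stopifnot(min_bp <= max_bp)
  dplyr::filter(table, .data$size_bp >= .env$min_bp,
                .data$size_bp <= .env$max_bp)
}

#' Keep only fragments that score reproducibly across replicates
#'
#' MSAP scoring retains only fragments whose presence/absence calls agree
#' between replicate reactions. A fragment showing any replicate
#' discordance in any sample x lane is dropped from the whole table; for
#' the retained fragments the replicate dimension is collapsed to the
#' consensus call.
#'
#' @param table A fragment table with a `replicate` column.
#' @return A collapsed fragment table (columns `sample`, `primer_combo`,
#'   `size_bp`, `enzyme_lane`, `present`; no `replicate`).
#' @details With fewer than two replicates throughout, the call is passed
#'   through unchanged (bar dropping the replicate column) with a warning,
#'   since reproducibility cannot be assessed. The operation is idempotent
#'   on its own output.
#' @export
filter_reproducible <- function(table) {
  assert_cols(table, c("sample", "primer_combo", "size_bp", "enzyme_lane",
                       "present"), "fragment table")
  if (is_collapsed(table)) return(table)
  n_rep <- dplyr::n_distinct(table$replicate)
  if (n_rep < 2L) {
    warning("single replicate: reproducibility cannot be assessed; ",
            "passing calls through unchanged", call. = FALSE)
    return(dplyr::select(table, -"replicate"))
  }
  calls <- table |>
    dplyr::summarise(
      concordant = dplyr::n_distinct(.data$present) == 1L,
      present = .data$present[1],
      .by = c("sample", "primer_combo", "size_bp", "enzyme_lane")
    )
  bad <- calls |>
    dplyr::filter(!.data$concordant) |>
    dplyr::distinct(.data$primer_combo, .data$size_bp)
  calls |>
    dplyr::anti_join(bad, by = c("primer_combo", "size_bp")) |>
    dplyr::select("sample", "primer_combo", "size_bp", "enzyme_lane",
                  "present")
}

#' Classify a CCGG site from its HpaII/MspI band pattern
#'
#' Maps the presence pattern of a fragment in the two isoschizomer lanes to
#' a cytosine methylation state. HpaII cuts unmethylated and
#' hemi-methylated (external-cytosine) CCGG; MspI cuts unmethylated and
#' fully methylated (internal-cytosine) CCGG. Hence:
#'
#' * present in both lanes (1,1): non-methylated (type I band);
#' * M lane only (0,1): fully methylated, CmCGG (type II);
#' * H lane only (1,0): hemi-methylated, mCCGG (type III);
#' * absent from both (0,0): uninformative -- the site may be absent or
#'   methylated in a way neither enzyme cuts, and is excluded from
#'   profile denominators.
#'
#' @param h_present,m_present Binary vectors (0/1): fragment presence in
#'   the EcoRI+HpaII and EcoRI+MspI lanes.
#' @return A factor with levels `non_methylated`, `fully_methylated`,
#'   `hemi_methylated`, `uninformative`.
#' @examples
#' classify_site(c(1, 0, 1, 0), c(1, 1, 0, 0))
#' @export
classify_site <- function(h_present, m_present) {
  stopifnot(length(h_present) == length(m_present))
  assert_binary(h_present, "h_present")
  assert_binary(m_present, "m_present")
  levels <- c("non_methylated", "fully_methylated", "hemi_methylated",
              "uninformative")
  state <- dplyr::case_when(
    h_present == 1 & m_present == 1 ~ "non_methylated",
    h_present == 0 & m_present == 1 ~ "fully_methylated",
    h_present == 1 & m_present == 0 ~ "hemi_methylated",
    .default = "uninformative"
  )
  factor(state, levels = levels)
}

#' Classify every fragment x sample of a collapsed table
#'
#' @param table A collapsed fragment table (after [filter_reproducible()]).
#' @return A tibble with one row per fragment x sample: `sample`,
#'   `primer_combo`, `size_bp`, `h`, `m`, `state`.
#' @seealso [classify_site()], [build_profiles()]
#' @export
classify_table <- function(table) {
  assert_cols(table, c("sample", "primer_combo", "size_bp", "enzyme_lane",
                       "present"), "fragment table")
  if (!is_collapsed(table)) {
    stop("fragment table still has a replicate dimension; ",
         "run filter_reproducible() first", call. = FALSE)
  }
  wide <- table |>
    tidyr::pivot_wider(names_from = "enzyme_lane", values_from = "present",
                       values_fill = 0L)
  for (lane in c("H", "M")) if (!lane %in% names(wide)) wide[[lane]] <- 0L
  wide |>
    dplyr::mutate(state = classify_site(.data$H, .data$M)) |>
    dplyr::select("sample", "primer_combo", "size_bp",
                  h = "H", m = "M", "state")
}

#' Summarise per-sample methylation profiles
#'
#' Tallies classified CCGG sites into per-sample methylation profiles:
#' counts and proportions of non-, fully and hemi-methylated sites among
#' the informative sites (doubly-absent fragments are excluded from the
#' denominator). The total methylation level is full + hemi.
#'
#' @param table A collapsed fragment table (after [filter_reproducible()]).
#' @param ploidy Either a named integer vector mapping sample -> ploidy, or
#'   a data frame with columns `sample` and `ploidy`. May be `NULL` if
#'   ploidy is not needed downstream.
#' @return A profile tibble with one row per sample: `sample`, `ploidy`,
#'   `n_sites` (informative sites), `n_non`, `n_full`, `n_hemi`,
#'   `y_total` (= n_full + n_hemi), `p_non`, `p_full`, `p_hemi`, `p_total`
#'   (fractions in \[0, 1\]).
#' @details Errors if any sample has no informative site. Proportions sum
#'   to one per sample by construction.
#' @examples
#' tab <- generate_msap(msap_scenario(n_sites = 200, seed = 1))
#' profiles <- build_profiles(filter_reproducible(tab),
#'                            attr(tab, "ploidy"))
#' @export
build_profiles <- function(table, ploidy = NULL) {
  classified <- classify_table(table)
  prof <- classified |>
    dplyr::summarise(
      n_total_fragments = dplyr::n(),
      n_non = sum(.data$state == "non_methylated"),
      n_full = sum(.data$state == "fully_methylated"),
      n_hemi = sum(.data$state == "hemi_methylated"),
      .by = "sample"
    ) |>
    dplyr::mutate(
      n_sites = .data$n_non + .data$n_full + .data$n_hemi,
      y_total = .data$n_full + .data$n_hemi
    )
  if (any(prof$n_sites == 0)) {
    stop(sprintf("no informative sites for sample(s): %s",
                 paste(prof$sample[prof$n_sites == 0], collapse = ", ")),
         call. = FALSE)
  }
  prof <- prof |>
    dplyr::mutate(
      p_non = .data$n_non / .data$n_sites,
      p_full = .data$n_full / .data$n_sites,
      p_hemi = .data$n_hemi / .data$n_sites,
      p_total = .data$p_full + .data$p_hemi
    )
  prof$ploidy <- lookup_ploidy(prof$sample, ploidy)
  prof |>
    dplyr::select("sample", "ploidy", "n_sites", "n_non", "n_full",
                  "n_hemi", "y_total", "p_non", "p_full", "p_hemi",
                  "p_total")
}

#' Summarise the methylation profile of a single sample
#'
#' Single-sample convenience wrapper around [build_profiles()].
#'
#' @param table A collapsed fragment table.
#' @param sample_id Sample to profile.
#' @param ploidy Integer ploidy of the sample.
#' @return A one-row profile tibble (see [build_profiles()]).
#' @export
build_profile <- function(table, sample_id, ploidy = NA_integer_) {
  sub <- dplyr::filter(table, .data$sample == .env$sample_id)
  if (nrow(sub) == 0) {
    stop(sprintf("sample '%s' not present in fragment table", sample_id),
         call. = FALSE)
  }
  build_profiles(sub, setNames(as.integer(ploidy), sample_id))
}

lookup_ploidy <- function(samples, ploidy) {
  if (is.null(ploidy)) return(rep(NA_integer_, length(samples)))
  if (is.data.frame(ploidy)) {
    assert_cols(ploidy, c("sample", "ploidy"), "ploidy map")
    ploidy <- setNames(as.integer(ploidy$ploidy), ploidy$sample)
  }
  as.integer(unname(ploidy[samples]))
}
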