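#' Correlate methylation level with ploidy
#'
#' Pearson correlation between ploidy level (as an integer, e.g. 2--10)
#' and a per-sample methylation proportion, with the usual two-sided
#' p-value from the t transform on n - 2 degrees of freedom.
#'
#' @param profiles A profile tibble from [build_profiles()].
#' @param measure One of `"total"`, `"full"`, `"hemi"`.
#' @return A one-row tibble: `x_label`, `y_label`, `n`, `r`, `r2`,
#'   `p_value`.
#' @details Requires at least three profiles spanning at least two
#'   distinct ploidy levels; errors when either variable has zero
#'   variance.
#' @examples
#' profiles <- chrysanthemum_exact_profiles(n_sites = 1000)
#' pearson_ploidy_correlation(profiles, "total")
#' @export
pearson_ploidy_correlation <- function(profiles,
                                       measure = c("total", "full", "hemi")) {
  measure <- match.arg(measure)
  assert_cols(profiles, c("ploidy"), "profile table")
  y <- profiles[[paste0("p_", measure)]]
  x <- as.numeric(profiles$ploidy)
  if (length(x) < 3L || dplyr::n_distinct(x) < 2L) {
    stop("need >= 3 profiles spanning >= 2 ploidy levels", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in ploidy or methylation proportion", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(
    x_label = "ploidy",
    y_label = paste0("p_", measure),
    n = length(x),
    r = unname(ct$estimate),
    r2 = unname(ct$estimate)^2,
    p_value = ct$p.value
  )
}

#' Extremes and range of methylation levels across samples
#'
#' For each methylation measure, reports which sample carries the maximum
#' and minimum proportion and the range between them in percentage
#' points.
#'
#' @param profiles A profile tibble from [build_profiles()].
#' @return A tibble with one row per measure: `measure`, `max_sample`,
#'   `max_pct`, `min_sample`, `min_pct`, `range_pct` (all percentages,
#'   range in percentage points). Ties are resolved in favour of the
#'   first sample in table order.
#' @seealso [rank_profiles()] for the full descending ranking.
#' @export
summarize_profiles <- function(profiles) {
  assert_cols(profiles, c("sample", "p_total", "p_full", "p_hemi"),
              "profile table")
  stopifnot(nrow(profiles) >= 1L)
  purrr::map(meth_measures(), function(m) {
    p <- 100 * profiles[[paste0("p_", m)]]
    tibble::tibble(
      measure = m,
      max_sample = profiles$sample[which.max(p)],
      max_pct = max(p),
      min_sample = profiles$sample[which.min(p)],
      min_pct = min(p),
      range_pct = max(p) - min(p)
    )
  }) |> purrr::list_rbind()
}

#' Rank samples by methylation level
#'
#' @param profiles A profile tibble from [build_profiles()].
#' @param measure One of `"total"`, `"full"`, `"hemi"`.
#' @return The profiles sorted by descending proportion of the chosen
#'   measure, with a `rank` column (1 = highest).
#' @export
rank_profiles <- function(profiles, measure = c("total", "full", "hemi")) {
  measure <- match.arg(measure)
  col <- paste0("p_", measure)
  profiles |>
    dplyr::arrange(dplyr::desc(.data[[col]])) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::relocate("rank")
}
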