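#' Pooled two-proportion U statistic
#'
#' The test statistic used to compare methylation proportions between a
#' sample and a comparator (or between two ploidy groups). With successes
#' and totals \eqn{(y_1, n_1)} and \eqn{(y_2, n_2)}:
#' \deqn{p = \frac{y_1 + y_2}{n_1 + n_2},\quad q = 1 - p,\quad
#'       \delta = \sqrt{p q (1/n_1 + 1/n_2)},\quad
#'       U = \frac{|p_1 - p_2|}{\delta}}
#' i.e. the classical pooled two-proportion z statistic, reported as an
#' absolute value and compared against a fixed two-sided 5% critical value
#' of 1.96. No continuity correction is applied.
#'
#' @param y1,n1 Successes and trials for the focal proportion
#'   (`0 <= y1 <= n1`, `n1 > 0`). Vectorized.
#' @param y2,n2 Successes and trials for the comparator.
#' @param critical_value Significance threshold for `u` (default 1.96,
#'   the 5% two-sided normal quantile).
#' @param measure Optional label(s) carried into the output.
#' @return A tibble with one row per comparison: `measure`, `y1`, `n1`,
#'   `y2`, `n2`, `p1`, `p2`, `p_pooled`, `q`, `delta`, `u`, `significant`.
#' @details When the pooled proportion is exactly 0 or 1 the denominator
#'   `delta` is 0; then `u = 0` is returned if `p1 == p2` (no difference to
#'   test) and an error is raised otherwise.
#' @examples
#' u_statistic(500, 1000, 550, 1000)
#' @export
u_statistic <- function(y1, n1, y2, n2, critical_value = 1.96,
                        measure = NA_character_) {
  stopifnot(length(y1) == length(n1), length(y2) == length(n2),
            length(y1) == length(y2))
  if (any(n1 <= 0) || any(n2 <= 0) || any(y1 < 0) || any(y2 < 0) ||
      any(y1 > n1) || any(y2 > n2)) {
    stop("counts must satisfy 0 <= y <= n with n > 0", call. = FALSE)
  }
  p1 <- y1 / n1
  p2 <- y2 / n2
  p_pooled <- (y1 + y2) / (n1 + n2)
  q <- 1 - p_pooled
  delta <- sqrt(p_pooled * q * (1 / n1 + 1 / n2))
  degenerate <- delta == 0
  if (any(degenerate & p1 != p2)) {
    stop("degenerate pooled proportion (0 or 1) with unequal proportions",
         call. = FALSE)
  }
  u <- ifelse(degenerate, 0, abs(p1 - p2) / delta)
  tibble::tibble(
    measure = rep_len(measure, length(y1)),
    y1 = y1, n1 = n1, y2 = y2, n2 = n2,
    p1 = p1, p2 = p2, p_pooled = p_pooled, q = q, delta = delta,
    u = u, significant = u > critical_value
  )
}

# Extract (y, n) count pairs for one measure from a profile tibble.
measure_counts <- function(profiles, measure) {
  y <- switch(measure,
    total = profiles$y_total,
    full = profiles$n_full,
    hemi = profiles$n_hemi,
    stop(sprintf("unknown measure '%s'", measure), call. = FALSE)
  )
  list(y = y, n = profiles$n_sites)
}

#' Compare each sample with its ploidy-group mid-value
#'
#' For every sample and each methylation measure (total, fully, hemi),
#' tests the sample's proportion against the mid-value of its ploidy
#' group with the pooled two-proportion U statistic. The mid-value
#' comparator is the central proportion of the group's members (the focal
#' sample included) at the group's typical site count: `p2` is the mean
#' (or median) of member proportions, `n2` the rounded mean of member site
#' totals and `y2 = round(p2 * n2)`.
#'
#' @param profiles A profile tibble from [build_profiles()] with known
#'   ploidy for every sample.
#' @param critical_value Significance threshold for `u` (default 1.96).
#' @param midvalue `"mean"` (default) or `"median"`: how the group
#'   mid-value proportion is formed.
#' @return A tibble with one row per sample x measure: `sample`, `ploidy`,
#'   `measure`, then the [u_statistic()] columns.
#' @details Errors if any ploidy group has a single member (a mid-value
#'   comparison within a singleton group is meaningless).
#' @export
midvalue_comparisons <- function(profiles, critical_value = 1.96,
                                 midvalue = c("mean", "median")) {
  midvalue <- match.arg(midvalue)
  assert_cols(profiles, c("sample", "ploidy", "n_sites", "y_total",
                          "n_full", "n_hemi"), "profile table")
  if (anyNA(profiles$ploidy)) {
    stop("all samples need a known ploidy", call. = FALSE)
  }
  sizes <- table(profiles$ploidy)
  if (any(sizes < 2L)) {
    stop(sprintf("ploidy group(s) with a single member: %s",
                 paste(names(sizes)[sizes < 2L], collapse = ", ")),
         call. = FALSE)
  }
  centre <- if (midvalue == "mean") mean else stats::median
  groups <- split(profiles, profiles$ploidy)
  purrr::map(groups, function(g) {
    purrr::map(meth_measures(), function(m) {
      cnt <- measure_counts(g, m)
      p2 <- centre(cnt$y / cnt$n)
      n2 <- round(mean(cnt$n))
      y2 <- round(p2 * n2)
      dplyr::bind_cols(
        tibble::tibble(sample = g$sample, ploidy = g$ploidy),
        u_statistic(cnt$y, cnt$n, rep(y2, nrow(g)), rep(n2, nrow(g)),
                    critical_value = critical_value, measure = m)
      )
    }) |> purrr::list_rbind()
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$ploidy, .data$sample,
                   match(.data$measure, meth_measures()))
}

#' Pairwise U comparisons between ploidy groups
#'
#' Compares the mean methylation proportions of every unordered pair of
#' ploidy groups with the pooled two-proportion U statistic. Each group is
#' summarised by the unweighted mean of its members' proportions, entered
#' at the group's per-sample site scale: `n` is the rounded mean of member
#' site totals, not the pooled count over members (pooling would inflate
#' the effective sample size far beyond a single MSAP fingerprint).
#'
#' @inheritParams midvalue_comparisons
#' @return A tibble with one row per group pair x measure: `ploidy_1`,
#'   `ploidy_2` (ploidy_1 < ploidy_2), `measure`, then the
#'   [u_statistic()] columns.
#' @seealso [u_matrix()] to reshape one measure into a square matrix.
#' @export
cross_ploidy_comparisons <- function(profiles, critical_value = 1.96) {
  assert_cols(profiles, c("ploidy", "n_sites", "y_total", "n_full",
                          "n_hemi"), "profile table")
  ploidies <- sort(unique(profiles$ploidy))
  if (length(ploidies) < 2L) {
    stop("need at least two ploidy groups", call. = FALSE)
  }
  pairs <- utils::combn(ploidies, 2L)
  purrr::map(meth_measures(), function(m) {
    stats_by_group <- purrr::map(ploidies, function(pl) {
      g <- profiles[profiles$ploidy == pl, ]
      cnt <- measure_counts(g, m)
      n <- round(mean(cnt$n))
      list(p = mean(cnt$y / cnt$n), n = n)
    })
    names(stats_by_group) <- as.character(ploidies)
    purrr::map(seq_len(ncol(pairs)), function(k) {
      a <- stats_by_group[[as.character(pairs[1L, k])]]
      b <- stats_by_group[[as.character(pairs[2L, k])]]
      dplyr::bind_cols(
        tibble::tibble(ploidy_1 = pairs[1L, k], ploidy_2 = pairs[2L, k]),
        u_statistic(round(a$p * a$n), a$n, round(b$p * b$n), b$n,
                    critical_value = critical_value, measure = m)
      )
    }) |> purrr::list_rbind()
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(match(.data$measure, meth_measures()),
                   .data$ploidy_1, .data$ploidy_2)
}

#' Reshape pairwise group comparisons into a square U matrix
#'
#' @param comparisons Output of [cross_ploidy_comparisons()].
#' @param measure One of `"total"`, `"full"`, `"hemi"`.
#' @return A symmetric numeric matrix of U values with zero diagonal,
#'   dimnames = ploidy levels.
#' @export
u_matrix <- function(comparisons, measure = "total") {
  sub <- dplyr::filter(comparisons, .data$measure == .env$measure)
  ploidies <- sort(unique(c(sub$ploidy_1, sub$ploidy_2)))
  m <- matrix(0, length(ploidies), length(ploidies),
              dimnames = list(ploidies, ploidies))
  for (i in seq_len(nrow(sub))) {
    a <- as.character(sub$ploidy_1[i])
    b <- as.character(sub$ploidy_2[i])
    m[a, b] <- m[b, a] <- sub$u[i]
  }
  m
}
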