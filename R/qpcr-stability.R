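# Reference-gene stability evaluation. Two complementary statistics are
# offered: a pairwise-variation M value (low M = the gene's expression
# ratio to every other candidate is stable across samples) and an
# ANOVA-style variance score splitting the candidate's sample-centered
# log2 quantity into between- and within-ploidy-group components.

# Average technical replicates to one Ct per sample x gene.
average_tech_reps <- function(ct) {
  assert_cols(ct, c("species", "gene", "bio_rep", "ct"), "Ct table")
  if (!"role" %in% names(ct)) ct$role <- NA_character_
  if (!"ploidy" %in% names(ct)) ct$ploidy <- NA_integer_
  if (!"run_id" %in% names(ct)) ct$run_id <- NA_character_
  ct |>
    dplyr::summarise(ct = mean(.data$ct),
                     .by = c("species", "ploidy", "gene", "role",
                             "bio_rep", "run_id"))
}

candidate_genes <- function(ct, candidates) {
  if (!is.null(candidates)) return(candidates)
  if ("role" %in% names(ct)) {
    refs <- unique(ct$gene[ct$role == "reference"])
    if (length(refs) > 0) return(refs)
  }
  unique(ct$gene)
}

#' Pairwise-variation (M value) reference-gene stability
#'
#' For each candidate pair (j, k), the expression ratio per sample is
#' `2^(Ct_j - Ct_k)` (efficiency 2), so the log2 ratio is the Ct
#' difference; the pairwise variation `V_jk` is the standard deviation of
#' that log2 ratio over samples, and the stability value `M_j` is the mean
#' of `V_jk` over all other candidates k. The lowest M marks the most
#' stably transcribed gene. Because ratios are used, shifts common to all
#' genes of a sample (template amount, run effects) cancel.
#'
#' @param ct A Ct table (see [generate_ct()] for the column contract).
#'   Technical replicates are averaged first; the sample unit is
#'   (species, biological replicate).
#' @param candidates Character vector of candidate gene names; defaults
#'   to all genes with role `"reference"`.
#' @return A tibble with one row per candidate: `gene`, `m_value`,
#'   `rank` (1 = most stable, ties broken by gene name).
#' @details Requires at least three candidates (with two, each gene's M
#'   equals the single pairwise variation and the ranking is degenerate)
#'   and at least two samples.
#' @export
mvalue_stability <- function(ct, candidates = NULL) {
  candidates <- candidate_genes(ct, candidates)
  if (length(candidates) < 3L) {
    stop("need >= 3 candidate reference genes", call. = FALSE)
  }
  avg <- average_tech_reps(ct) |>
    dplyr::filter(.data$gene %in% .env$candidates)
  wide <- avg |>
    tidyr::pivot_wider(id_cols = c("species", "bio_rep"),
                       names_from = "gene", values_from = "ct")
  if (nrow(wide) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (anyNA(wide[candidates])) {
    stop("every candidate gene must be measured in every sample",
         call. = FALSE)
  }
  m <- purrr::map_dbl(candidates, function(j) {
    v <- purrr::map_dbl(setdiff(candidates, j), function(k) {
      sd(wide[[j]] - wide[[k]])
    })
    mean(v)
  })
  tibble::tibble(gene = candidates, m_value = m) |>
    dplyr::arrange(.data$m_value, .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::arrange(.data$gene)
}

#' ANOVA-style variance reference-gene stability
#'
#' Decomposes each candidate's variability across ploidy groups after
#' removing per-sample effects. Each sample's Ct vector is centered by
#' its across-candidate mean (removing template and run shifts); the
#' candidate's centered log2 quantity is then split into a between-group
#' component (SD of ploidy-group means) and a within-group component
#' (root mean within-group variance). The variance score combines them as
#' `sqrt(between^2 + within^2)`; low scores rank first.
#'
#' @inheritParams mvalue_stability
#' @param groups Optional data frame `species`/`group` overriding the
#'   default grouping by `ploidy`.
#' @return A tibble with one row per candidate: `gene`, `between_sd`,
#'   `within_sd`, `variance_score`, `rank`.
#' @details Errors if any group contains a single sample (its
#'   within-group variance is undefined).
#' @export
variance_stability <- function(ct, candidates = NULL, groups = NULL) {
  candidates <- candidate_genes(ct, candidates)
  if (length(candidates) < 2L) {
    stop("need >= 2 candidate reference genes", call. = FALSE)
  }
  avg <- average_tech_reps(ct) |>
    dplyr::filter(.data$gene %in% .env$candidates)
  if (is.null(groups)) {
    if (anyNA(avg$ploidy)) {
      stop("Ct table has no ploidy column; supply `groups`", call. = FALSE)
    }
    avg$group <- as.character(avg$ploidy)
  } else {
    assert_cols(groups, c("species", "group"), "groups table")
    avg <- dplyr::left_join(avg, groups, by = "species")
  }
  # centered log2 quantity: -(ct - sample mean ct over candidates)
  centred <- avg |>
    dplyr::mutate(log2_q = -(.data$ct - mean(.data$ct)),
                  .by = c("species", "bio_rep"))
  sizes <- centred |>
    dplyr::distinct(.data$group, .data$species, .data$bio_rep) |>
    dplyr::count(.data$group)
  if (any(sizes$n < 2L)) {
    stop(sprintf("singleton group(s): %s",
                 paste(sizes$group[sizes$n < 2L], collapse = ", ")),
         call. = FALSE)
  }
  scores <- centred |>
    dplyr::summarise(gmean = mean(.data$log2_q),
                     gvar = var(.data$log2_q),
                     .by = c("gene", "group")) |>
    dplyr::summarise(
      between_sd = if (dplyr::n() > 1L) sd(.data$gmean) else 0,
      within_sd = sqrt(mean(.data$gvar)),
      .by = "gene"
    ) |>
    dplyr::mutate(
      variance_score = sqrt(.data$between_sd^2 + .data$within_sd^2)
    )
  scores |>
    dplyr::arrange(.data$variance_score, .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::arrange(.data$gene)
}

#' Combined stability ranking
#'
#' Runs both stability statistics and combines them by mean rank.
#'
#' @inheritParams mvalue_stability
#' @return A tibble: `gene`, `m_value`, `m_rank`, `variance_score`,
#'   `variance_rank`, `mean_rank`, sorted most stable first (ties broken
#'   by M value, then gene name).
#' @export
stability_ranking <- function(ct, candidates = NULL) {
  m <- mvalue_stability(ct, candidates) |>
    dplyr::rename(m_rank = "rank")
  v <- variance_stability(ct, candidates) |>
    dplyr::select("gene", "variance_score", variance_rank = "rank")
  dplyr::inner_join(m, v, by = "gene") |>
    dplyr::mutate(mean_rank = (.data$m_rank + .data$variance_rank) / 2) |>
    dplyr::arrange(.data$mean_rank, .data$m_value, .data$gene)
}

#' Select the best reference gene per ploidy comparison
#'
#' For each requested ploidy comparison, restricts the Ct table to the
#' species of those ploidy levels, computes the combined stability
#' ranking and picks the top gene (lowest mean rank; ties broken by M
#' value, then gene name). The result doubles as a segment plan for
#' [chained_normalization()].
#'
#' @inheritParams mvalue_stability
#' @param comparisons Named list of integer ploidy vectors, e.g.
#'   `list("2x-4x-6x" = c(2, 4, 6), "6x-8x" = c(6, 8))`.
#' @return A tibble: `segment`, `gene`, `m_value`, `mean_rank`,
#'   `ploidies` (list-column).
#' @export
select_references <- function(ct, comparisons, candidates = NULL) {
  stopifnot(is.list(comparisons), length(comparisons) > 0,
            !is.null(names(comparisons)))
  purrr::imap(comparisons, function(ploidies, label) {
    sub <- dplyr::filter(ct, .data$ploidy %in% .env$ploidies)
    ranking <- stability_ranking(sub, candidates)
    best <- ranking[1L, ]
    tibble::tibble(segment = label, gene = best$gene,
                   m_value = best$m_value, mean_rank = best$mean_rank,
                   ploidies = list(as.integer(ploidies)))
  }) |> purrr::list_rbind()
}
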