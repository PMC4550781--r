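#' Relative nuclear DNA content from flow-cytometry peaks
#'
#' Averages accepted replicate peak means per species and expresses each
#' species' nuclear DNA content relative to a reference species.
#' Replicates are accepted only when their peak coefficient of variation
#' is below the threshold (conventionally 5%).
#'
#' @param samples A tibble with columns `species`, `replicate`,
#'   `peak_mean` (> 0) and `cv` (fraction), e.g. from [generate_flow()].
#' @param reference_species Species defining relative content 1.
#' @param cv_threshold Acceptance threshold on `cv` (default 0.05,
#'   strict `<`).
#' @return A tibble: `species`, `n_accepted`, `relative_content`
#'   (reference species exactly 1). Species without any accepted
#'   replicate are omitted with a warning.
#' @examples
#' flow <- generate_flow(seed = 1)
#' dna_content_ratio(flow, "C. nankingense")
#' @export
dna_content_ratio <- function(samples, reference_species,
                              cv_threshold = 0.05) {
  assert_cols(samples, c("species", "replicate", "peak_mean", "cv"),
              "flow-cytometry table")
  stopifnot(all(samples$peak_mean > 0))
  accepted <- dplyr::filter(samples, .data$cv < .env$cv_threshold)
  dropped <- setdiff(unique(samples$species), unique(accepted$species))
  if (length(dropped) > 0) {
    warning(sprintf("no accepted replicate (cv < %g) for: %s; omitted",
                    cv_threshold, paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  if (!reference_species %in% accepted$species) {
    stop(sprintf("reference species '%s' has no accepted replicate",
                 reference_species), call. = FALSE)
  }
  means <- accepted |>
    dplyr::summarise(peak = mean(.data$peak_mean),
                     n_accepted = dplyr::n(), .by = "species")
  ref <- means$peak[means$species == reference_species]
  means |>
    dplyr::transmute(.data$species, .data$n_accepted,
                     relative_content = .data$peak / ref)
}

#' Correlate transcript abundance with relative nuclear DNA content
#'
#' Pearson correlation between a target gene's normalized relative
#' quantity and the species' relative nuclear DNA content, either at the
#' species-mean level or at the biological-replicate level (each
#' replicate paired with its species' DNA content).
#'
#' @param expr A `chained_norm` object (see [chained_normalization()]) or
#'   a tidy tibble with columns `gene`, `species` and `quantity`.
#' @param content A tibble with columns `species`, `relative_content`
#'   (e.g. from [dna_content_ratio()] or [chrysanthemum_dna_content()]).
#' @param gene Target gene to correlate.
#' @param replicate_level If `TRUE`, use per-biological-replicate
#'   quantities (requires `expr` to be a `chained_norm`); otherwise
#'   species means (default).
#' @return A one-row tibble: `x_label`, `y_label`, `n`, `r`, `r2`,
#'   `p_value`.
#' @export
expression_content_correlation <- function(expr, content, gene,
                                           replicate_level = FALSE) {
  assert_cols(content, c("species", "relative_content"), "content table")
  if (inherits(expr, "chained_norm")) {
    tab <- if (replicate_level) expr$quantities else expr$summary
  } else {
    if (replicate_level) {
      stop("replicate-level correlation needs a chained_norm object",
           call. = FALSE)
    }
    tab <- expr
  }
  assert_cols(tab, c("gene", "species", "quantity"), "expression table")
  sub <- tab |>
    dplyr::filter(.data$gene == .env$gene) |>
    dplyr::inner_join(content, by = "species")
  if (dplyr::n_distinct(sub$species) < 3L) {
    stop("need >= 3 shared species", call. = FALSE)
  }
  if (sd(sub$quantity) == 0 || sd(sub$relative_content) == 0) {
    stop("zero variance in expression or DNA content", call. = FALSE)
  }
  ct <- cor.test(sub$relative_content, sub$quantity, method = "pearson")
  tibble::tibble(
    x_label = "relative_content",
    y_label = paste0(gene, "_quantity"),
    n = nrow(sub),
    r = unname(ct$estimate),
    r2 = unname(ct$estimate)^2,
    p_value = ct$p.value
  )
}
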