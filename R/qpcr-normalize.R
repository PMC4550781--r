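#' Chained multi-reference qRT-PCR normalization across a ploidy series
#'
#' When no single reference gene is stable across an entire ploidy series,
#' normalization proceeds segment-wise: each plan segment names the
#' reference gene that is stable across a subset of ploidy levels, and
#' segments are chained through the species they share, so every species'
#' relative quantity can be expressed against one calibrator species.
#'
#' Within a segment, the relative quantity of a target in each biological
#' replicate is `efficiency^(Ct_ref - Ct_target)` (the classic delta-Ct
#' with assumed amplification efficiency 2, i.e. 100%). Any Ct shift
#' common to the reference and target of a sample -- template amount, run
#' offset -- cancels in the difference. Adjacent segments are linked by
#' the geometric mean, over shared species and replicates, of the ratio
#' between their quantity scales; finally everything is rescaled so the
#' calibrator species' mean quantity is exactly 1.
#'
#' An optional inter-run calibrator (IRC) gene provides an independent
#' single-reference normalization over the ploidy levels it covers; the
#' coefficient of variation of the ratio between the chained and IRC
#' estimates across shared species validates the chain (conventional
#' acceptance: CV < 5%).
#'
#' @param ct A Ct table (columns as produced by [generate_ct()]).
#' @param plan Segment plan: data frame with columns `segment`, `gene` and
#'   list-column `ploidies` (see [select_references()] and
#'   [chrysanthemum_reference_plan()]).
#' @param calibrator_species Species whose quantity defines 1.
#' @param efficiency Assumed amplification efficiency (default 2).
#' @param irc_gene,irc_ploidies Optional IRC gene and the ploidy levels it
#'   covers.
#' @param cv_threshold IRC acceptance threshold (default 0.05).
#' @param targets Target gene names; defaults to all genes with role
#'   `"target"`.
#' @return An object of class `chained_norm` with components
#'   `quantities` (per gene x species x biological replicate),
#'   `summary` (per gene x species: `quantity`, `se`, `n`), `irc`
#'   (per gene: `irc_cv`, `valid`), plus the call parameters. Use
#'   [tidy()], [glance()], [fold_changes()] and [autoplot()] on it.
#' @examples
#' ct <- generate_ct(ct_scenario_chrysanthemum(seed = 2))
#' fit <- chained_normalization(ct, chrysanthemum_reference_plan()$plan,
#'                              calibrator_species = "C. nankingense",
#'                              irc_gene = "PP2A",
#'                              irc_ploidies = c(4, 8, 10))
#' tidy(fit)
#' glance(fit)
#' @export
chained_normalization <- function(ct, plan, calibrator_species,
                                  efficiency = 2,
                                  irc_gene = NULL, irc_ploidies = NULL,
                                  cv_threshold = 0.05, targets = NULL) {
  plan <- tibble::as_tibble(plan)
  assert_cols(plan, c("segment", "gene", "ploidies"), "segment plan")
  stopifnot(efficiency > 1)
  avg <- average_tech_reps(ct)
  if (is.null(targets)) {
    targets <- unique(avg$gene[avg$role == "target"])
  }
  if (length(targets) == 0) stop("no target genes", call. = FALSE)
  if (!calibrator_species %in% avg$species) {
    stop(sprintf("calibrator species '%s' absent from Ct table",
                 calibrator_species), call. = FALSE)
  }
  species_ploidy <- dplyr::distinct(avg, .data$species, .data$ploidy)

  quantities <- purrr::map(targets, function(tg) {
    seg_rq <- purrr::map(seq_len(nrow(plan)), function(i) {
      segment_quantities(avg, plan$gene[i], tg, plan$ploidies[[i]],
                         efficiency) |>
        dplyr::mutate(segment = plan$segment[i])
    })
    names(seg_rq) <- plan$segment
    chain_segments(seg_rq, calibrator_species) |>
      dplyr::mutate(gene = tg)
  }) |> purrr::list_rbind()

  summary <- quantities |>
    dplyr::summarise(
      se = sd(.data$quantity) / sqrt(dplyr::n()),
      n = dplyr::n(),
      quantity = mean(.data$quantity),
      .by = c("gene", "species", "ploidy")
    ) |>
    dplyr::select("gene", "species", "ploidy", "quantity", "se", "n")

  irc <- NULL
  if (!is.null(irc_gene)) {
    if (is.null(irc_ploidies)) {
      stop("irc_ploidies must accompany irc_gene", call. = FALSE)
    }
    covered <- species_ploidy$species[species_ploidy$ploidy %in%
                                        irc_ploidies]
    irc <- purrr::map(targets, function(tg) {
      single <- segment_quantities(avg, irc_gene, tg,
                                   irc_ploidies, efficiency) |>
        dplyr::summarise(irc_quantity = mean(.data$quantity),
                         .by = c("species", "ploidy"))
      chained <- summary |>
        dplyr::filter(.data$gene == tg, .data$species %in% covered)
      both <- dplyr::inner_join(chained, single,
                                by = c("species", "ploidy"))
      if (nrow(both) < 2L) {
        warning(sprintf(
          "IRC gene '%s' covers < 2 species shared with the chain for ",
          irc_gene), "target '", tg, "'; irc_cv undefined", call. = FALSE)
        return(tibble::tibble(gene = tg, irc_cv = NA_real_,
                              valid = NA))
      }
      ratio <- both$quantity / both$irc_quantity
      cv <- sd(ratio) / mean(ratio)
      tibble::tibble(gene = tg, irc_cv = cv, valid = cv < cv_threshold)
    }) |> purrr::list_rbind()
  }

  structure(
    list(quantities = quantities, summary = summary, irc = irc,
         calibrator = calibrator_species, efficiency = efficiency,
         plan = plan, cv_threshold = cv_threshold),
    class = "chained_norm"
  )
}

# Per-replicate delta-Ct quantities of one target against one reference
# gene over the species of the given ploidy levels.
segment_quantities <- function(avg, ref_gene, target_gene, ploidies,
                               efficiency) {
  sub <- avg |>
    dplyr::filter(.data$ploidy %in% .env$ploidies,
                  .data$gene %in% c(ref_gene, target_gene))
  wide <- sub |>
    tidyr::pivot_wider(id_cols = c("species", "ploidy", "bio_rep"),
                       names_from = "gene", values_from = "ct")
  if (!all(c(ref_gene, target_gene) %in% names(wide)) ||
      anyNA(wide[[ref_gene]]) || anyNA(wide[[target_gene]])) {
    stop(sprintf("genes '%s'/'%s' not fully measured at ploidies %s",
                 ref_gene, target_gene,
                 paste(ploidies, collapse = ",")), call. = FALSE)
  }
  wide |>
    dplyr::transmute(
      .data$species, .data$ploidy, .data$bio_rep,
      quantity = efficiency^(.data[[ref_gene]] - .data[[target_gene]])
    )
}

# Link segment-wise quantities through shared species, then anchor the
# calibrator species' mean quantity at exactly 1.
chain_segments <- function(seg_rq, calibrator_species) {
  start <- which(purrr::map_lgl(seg_rq, function(s) {
    calibrator_species %in% s$species
  }))
  if (length(start) == 0) {
    stop("no plan segment covers the calibrator species", call. = FALSE)
  }
  resolved <- seg_rq[[start[1]]]
  pending <- seg_rq[-start[1]]
  while (length(pending) > 0) {
    linked <- FALSE
    for (i in seq_along(pending)) {
      seg <- pending[[i]]
      shared <- dplyr::inner_join(
        resolved, seg, by = c("species", "ploidy", "bio_rep"),
        suffix = c("_res", "_new")
      )
      if (nrow(shared) > 0) {
        scale <- exp(mean(log(shared$quantity_res /
                                shared$quantity_new)))
        add <- seg |>
          dplyr::anti_join(resolved, by = "species") |>
          dplyr::mutate(quantity = .data$quantity * scale)
        resolved <- dplyr::bind_rows(resolved, add)
        pending <- pending[-i]
        linked <- TRUE
        break
      }
    }
    if (!linked) {
      stop("segment plan is disconnected: some segments share no ",
           "species with the chain reaching the calibrator",
           call. = FALSE)
    }
  }
  anchor <- mean(resolved$quantity[resolved$species ==
                                     calibrator_species])
  resolved |>
    dplyr::mutate(quantity = .data$quantity / anchor) |>
    dplyr::select("species", "ploidy", "bio_rep", "quantity", "segment")
}

#' Fold changes between species under a chained normalization
#'
#' @param x A `chained_norm` object.
#' @param from,to Optional species names; by default all ordered pairs
#'   are returned.
#' @return A tibble: `gene`, `from`, `to`, `fold_change`
#'   (= quantity\[to\] / quantity\[from\]).
#' @export
fold_changes <- function(x, from = NULL, to = NULL) {
  stopifnot(inherits(x, "chained_norm"))
  s <- x$summary
  pairs <- tidyr::expand_grid(
    gene = unique(s$gene),
    from = unique(s$species),
    to = unique(s$species)
  ) |> dplyr::filter(.data$from != .data$to)
  if (!is.null(from)) pairs <- dplyr::filter(pairs, .data$from %in% .env$from)
  if (!is.null(to)) pairs <- dplyr::filter(pairs, .data$to %in% .env$to)
  pairs |>
    dplyr::left_join(dplyr::select(s, "gene", from = "species",
                                   q_from = "quantity"),
                     by = c("gene", "from")) |>
    dplyr::left_join(dplyr::select(s, "gene", to = "species",
                                   q_to = "quantity"),
                     by = c("gene", "to")) |>
    dplyr::transmute(.data$gene, .data$from, .data$to,
                     fold_change = .data$q_to / .data$q_from)
}

#' @export
print.chained_norm <- function(x, ...) {
  cat("Chained qRT-PCR normalization\n")
  cat("  calibrator:", x$calibrator, " efficiency:", x$efficiency, "\n")
  cat("  segments:", paste(x$plan$segment, "(", x$plan$gene, ")",
                           collapse = ", "), "\n")
  if (!is.null(x$irc)) {
    for (i in seq_len(nrow(x$irc))) {
      cat(sprintf("  IRC CV [%s]: %.3f (%s)\n", x$irc$gene[i],
                  x$irc$irc_cv[i],
                  ifelse(isTRUE(x$irc$valid[i]), "valid",
                         "check chain")))
    }
  }
  print(x$summary)
  invisible(x)
}

#' Tidy a chained normalization into per-species quantities
#'
#' @param x A `chained_norm` object.
#' @param ... Unused.
#' @return The per-species summary tibble: `gene`, `species`, `ploidy`,
#'   `quantity` (relative to the calibrator = 1), `se`, `n`.
#' @exportS3Method generics::tidy
tidy.chained_norm <- function(x, ...) x$summary

#' One-row-per-gene summary of a chained normalization
#'
#' @param x A `chained_norm` object.
#' @param ... Unused.
#' @return A tibble per target gene: `gene`, `n_species`, `irc_cv`,
#'   `valid`, `calibrator`, `efficiency`.
#' @exportS3Method generics::glance
glance.chained_norm <- function(x, ...) {
  base <- x$summary |>
    dplyr::summarise(n_species = dplyr::n_distinct(.data$species),
                     .by = "gene")
  if (!is.null(x$irc)) {
    base <- dplyr::left_join(base, x$irc, by = "gene")
  } else {
    base$irc_cv <- NA_real_
    base$valid <- NA
  }
  base |>
    dplyr::mutate(calibrator = x$calibrator,
                  efficiency = x$efficiency)
}
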