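#' Published methylation profile of the Chrysanthemum ploidy series
#'
#' Per-species MSAP methylation proportions for 20 *Chrysanthemum* species
#' and close relatives spanning a diploid-to-decaploid (2x--10x) series, as
#' percentages of informative CCGG sites: non-methylated, total methylated,
#' fully methylated (internal cytosine, cut by MspI only) and hemi-methylated
#' (external cytosine, cut by HpaII only). This table is the canonical
#' scenario for the synthetic MSAP generator and the desk-scale fixture used
#' throughout the test-suite.
#'
#' Note that in four rows the published full + hemi percentages differ from
#' the published total by 0.1 points (rounding in the source table), while
#' non + total is exactly 100 in every row. Downstream exact-count
#' generation therefore honours the non/total split first; see
#' [msap_scenario()].
#'
#' @return A tibble with columns `species`, `ploidy` (integer, 2--10),
#'   `non_pct`, `total_pct`, `full_pct`, `hemi_pct` (percentages).
#' @examples
#' chrysanthemum_methylation()
#' @export
chrysanthemum_methylation <- function() {
  path <- system.file("extdata", "chrysanthemum_methylation_table.tsv",
                      package = "ploidymeth", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    species = readr::col_character(),
    ploidy = readr::col_integer(),
    .default = readr::col_double()
  ))
}

#' Reported transcript fold-change ladders for MET1 and DDM1
#'
#' Relative transcript abundance of the CpG maintenance methyltransferase
#' gene *MET1* and the chromatin remodeller gene *DDM1* across the five
#' intensively studied species of the ploidy series, expressed relative to
#' the diploid *C. nankingense* (= 1). The *DDM1* ladder is reported
#' directly on that scale; the *MET1* ladder is derived from the reported
#' decaploid-relative ratios (the decaploid is 2.87x the diploid, 2.11x the
#' tetraploid, 1.77x the hexaploid and 1.23x the octoploid).
#'
#' @return A tibble with columns `gene`, `species`, `ploidy`,
#'   `fold_vs_diploid`.
#' @examples
#' chrysanthemum_fold_changes()
#' @export
chrysanthemum_fold_changes <- function() {
  species <- c("C. nankingense", "C. indicum", "C. morifolium",
               "C. ornatum", "C. crassum")
  ploidy <- c(2L, 4L, 6L, 8L, 10L)
  tibble::tibble(
    gene = rep(c("MET1", "DDM1"), each = 5L),
    species = rep(species, 2L),
    ploidy = rep(ploidy, 2L),
    fold_vs_diploid = c(
      1, 2.87 / 2.11, 2.87 / 1.77, 2.87 / 1.23, 2.87,
      1, 1.60, 3.88, 5.62, 6.19
    )
  )
}

#' Reported relative nuclear DNA contents of the ploidy series
#'
#' Flow-cytometric relative nuclear DNA content of the five intensively
#' studied species, expressed relative to the diploid reference
#' *C. nankingense*. The series is sub-proportional to ploidy (genome
#' downsizing after polyploidization).
#'
#' @return A tibble with columns `species`, `ploidy`, `relative_content`.
#' @examples
#' chrysanthemum_dna_content()
#' @export
chrysanthemum_dna_content <- function() {
  tibble::tibble(
    species = c("C. nankingense", "C. indicum", "C. morifolium",
                "C. ornatum", "C. crassum"),
    ploidy = c(2L, 4L, 6L, 8L, 10L),
    relative_content = c(1, 1.94, 2.91, 3.25, 4.25)
  )
}

#' Reference-gene chaining plan for the cross-ploidy expression comparison
#'
#' The segment-wise normalization plan used for the five-species ploidy
#' series: *EF1a* normalizes the 2x/4x/6x segment, *TUB* the 6x/8x segment
#' and *ACTIN* the 8x/10x segment, the segments being linked through their
#' shared ploidy levels; *PP2A* serves as the inter-run calibrator gene
#' across the 4x/8x/10x levels, giving an independent single-reference
#' estimate against which the chained one is validated (coefficient of
#' variation < 5%).
#'
#' @return A list with elements `plan` (tibble: `segment`, `gene`,
#'   `ploidies` list-column) and `irc` (list: `gene`, `ploidies`).
#' @examples
#' chrysanthemum_reference_plan()
#' @export
chrysanthemum_reference_plan <- function() {
  list(
    plan = tibble::tibble(
      segment = c("2x-4x-6x", "6x-8x", "8x-10x"),
      gene = c("EF1a", "TUB", "ACTIN"),
      ploidies = list(c(2L, 4L, 6L), c(6L, 8L), c(8L, 10L))
    ),
    irc = list(gene = "PP2A", ploidies = c(4L, 8L, 10L))
  )
}
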