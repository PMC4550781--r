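# Synthetic-data generators. These emulate the statistical structure the
# analysis assumes (state proportions, replicate concordance, Ct ladders,
# flow-cytometry peak ratios) -- not electrophoretic physics or PCR
# chemistry.

# Primer combinations used for the selective MSAP amplifications; fragment
# identities cycle through these.
msap_primer_combos <- function() {
  c("E2+HM5", "E2+HM7", "E3+HM3", "E4+HM3", "E4+HM7", "E4+HM8",
    "E6+HM6", "E6+HM8", "E7+HM1", "E7+HM3", "E8+HM2", "E8+HM8")
}

#' Define an MSAP simulation scenario
#'
#' A scenario bundles everything [generate_msap()] needs: the species
#' (samples) with their ploidies and target methylation-state proportions,
#' the number of scoreable fragments per sample, the replicate structure
#' and how states are allocated.
#'
#' @param species A data frame with columns `species`, `ploidy`, and
#'   either percentage columns `non_pct`, `total_pct`, `full_pct`,
#'   `hemi_pct` (as in [chrysanthemum_methylation()], the default) or
#'   fraction columns `p_non`, `p_full`, `p_hemi` (an optional `p_total`
#'   is honoured when the published full/hemi split disagrees with the
#'   total in the last printed digit).
#' @param n_sites Scoreable fragments per sample (default 1000, the order
#'   of magnitude a 12-primer-combination MSAP fingerprint yields in a
#'   120--480 bp window).
#' @param replicates Replicate reactions per sample and lane (default 2).
#' @param discordance_rate Probability that a fragment x sample x lane
#'   call is flipped in one randomly chosen replicate (default 0:
#'   perfectly reproducible data).
#' @param mode `"exact_count"` (default): state counts are allocated
#'   deterministically by largest-remainder rounding, hierarchically --
#'   first non-methylated vs methylated, then fully vs hemi within the
#'   methylated count -- so realized non/total percentages match the
#'   targets to 1/n_sites resolution. `"multinomial"`: states drawn
#'   independently per site from the target proportions.
#' @param seed Integer seed; all randomness is local to the generator.
#' @return An object of class `msap_scenario`.
#' @export
msap_scenario <- function(species = chrysanthemum_methylation(),
                          n_sites = 1000, replicates = 2,
                          discordance_rate = 0,
                          mode = c("exact_count", "multinomial"),
                          seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_sites >= 1, replicates >= 1,
            discordance_rate >= 0, discordance_rate < 1)
  species <- tibble::as_tibble(species)
  assert_cols(species, c("species", "ploidy"), "species table")
  if (all(c("non_pct", "full_pct", "hemi_pct") %in% names(species))) {
    has_total <- "total_pct" %in% names(species)
    species <- species |>
      dplyr::mutate(
        p_non = .data$non_pct / 100,
        p_full = .data$full_pct / 100,
        p_hemi = .data$hemi_pct / 100,
        p_total = if (has_total) .data$total_pct / 100
                  else .data$full_pct / 100 + .data$hemi_pct / 100
      )
  }
  assert_cols(species, c("p_non", "p_full", "p_hemi"), "species table")
  if (!"p_total" %in% names(species)) {
    species$p_total <- species$p_full + species$p_hemi
  }
  if (any(abs(species$p_non + species$p_total - 1) > 1e-9)) {
    stop("p_non + p_total must equal 1 for every species", call. = FALSE)
  }
  # full/hemi are split weights within the methylated share; allow the
  # 0.1-point rounding slack published tables carry.
  if (any(abs(species$p_full + species$p_hemi - species$p_total) > 2e-3)) {
    stop("p_full + p_hemi must equal p_total (within rounding)",
         call. = FALSE)
  }
  if (n_sites < 3) stop("n_sites must allow all three states", call. = FALSE)
  structure(
    list(species = species, n_sites = as.integer(n_sites),
         replicates = as.integer(replicates),
         discordance_rate = discordance_rate, mode = mode,
         seed = as.integer(seed)),
    class = "msap_scenario"
  )
}

# Deterministic fragment identities: cycle primer combos fastest, sizes
# across the scoreable window. Once the 12 x 361 window is exhausted the
# primer label gets a batch suffix so identities stay unique.
fragment_identities <- function(n_sites) {
  pcs <- msap_primer_combos()
  sizes <- 120:480
  idx <- seq_len(n_sites) - 1L
  batch <- idx %/% (length(pcs) * length(sizes))
  pc <- pcs[idx %% length(pcs) + 1L]
  tibble::tibble(
    primer_combo = ifelse(batch > 0L, paste0(pc, "#", batch + 1L), pc),
    size_bp = sizes[(idx %/% length(pcs)) %% length(sizes) + 1L]
  )
}

# State counts for one species under the scenario's allocation mode.
allocate_states <- function(sp_row, n_sites, mode) {
  if (mode == "exact_count") {
    split1 <- largest_remainder(c(sp_row$p_non, sp_row$p_total), n_sites)
    split2 <- largest_remainder(c(sp_row$p_full, sp_row$p_hemi), split1[2])
    counts <- c(non = split1[1], full = split2[1], hemi = split2[2])
    rep(c("non_methylated", "fully_methylated", "hemi_methylated"), counts)
  } else {
    p <- c(sp_row$p_non, sp_row$p_full, sp_row$p_hemi)
    sample(c("non_methylated", "fully_methylated", "hemi_methylated"),
           n_sites, replace = TRUE, prob = p / sum(p))
  }
}

#' Generate a synthetic MSAP fragment table
#'
#' Emits a complete binary fragment table (fragment x sample x lane x
#' replicate) whose per-sample methylation-state composition follows the
#' scenario's target proportions, with each state rendered as its
#' isoschizomer band pattern (non-methylated: both lanes; fully
#' methylated: M lane only; hemi-methylated: H lane only). States are
#' assigned to a seeded per-sample permutation of the fragment identities,
#' and replicate discordance is injected at the scenario's rate.
#'
#' @param scenario An [msap_scenario()].
#' @return A fragment table tibble (`sample`, `primer_combo`, `size_bp`,
#'   `enzyme_lane`, `replicate`, `present`) with attribute `ploidy` (a
#'   `sample`/`ploidy` tibble usable by [build_profiles()]).
#' @details Bit-reproducible for a fixed seed.
#' @examples
#' tab <- generate_msap(msap_scenario(n_sites = 300, seed = 7))
#' @export
generate_msap <- function(scenario) {
  stopifnot(inherits(scenario, "msap_scenario"))
  frags <- fragment_identities(scenario$n_sites)
  withr::with_seed(scenario$seed, {
    per_sample <- purrr::map(seq_len(nrow(scenario$species)), function(i) {
      sp <- scenario$species[i, ]
      states <- allocate_states(sp, scenario$n_sites, scenario$mode)
      states <- states[sample.int(length(states))]
      h <- as.integer(states != "fully_methylated")
      m <- as.integer(states != "hemi_methylated")
      tibble::tibble(
        sample = sp$species,
        primer_combo = frags$primer_combo,
        size_bp = frags$size_bp,
        H = h, M = m
      )
    }) |> purrr::list_rbind()

    long <- per_sample |>
      tidyr::pivot_longer(c("H", "M"), names_to = "enzyme_lane",
                          values_to = "present")
    out <- tidyr::expand_grid(long,
                              replicate = seq_len(scenario$replicates))
    if (scenario$discordance_rate > 0 && scenario$replicates >= 2) {
      keys <- dplyr::distinct(long, .data$sample, .data$primer_combo,
                              .data$size_bp, .data$enzyme_lane)
      hit <- runif(nrow(keys)) < scenario$discordance_rate
      flips <- keys[hit, , drop = FALSE]
      if (nrow(flips) > 0) {
        flips$replicate <- sample.int(scenario$replicates, nrow(flips),
                                      replace = TRUE)
        out <- out |>
          dplyr::left_join(dplyr::mutate(flips, flip = TRUE),
                           by = c("sample", "primer_combo", "size_bp",
                                  "enzyme_lane", "replicate")) |>
          dplyr::mutate(
            present = ifelse(is.na(.data$flip), .data$present,
                             1L - .data$present)
          ) |>
          dplyr::select(-"flip")
      }
    }
    out <- out |>
      dplyr::mutate(present = as.integer(.data$present)) |>
      dplyr::select("sample", "primer_combo", "size_bp", "enzyme_lane",
                    "replicate", "present") |>
      dplyr::arrange(.data$sample, .data$primer_combo, .data$size_bp,
                     .data$enzyme_lane, .data$replicate)
    attr(out, "ploidy") <- dplyr::distinct(
      tibble::tibble(sample = scenario$species$species,
                     ploidy = as.integer(scenario$species$ploidy))
    )
    out
  })
}

#' Exact-count methylation profiles of the canonical ploidy series
#'
#' Convenience wrapper: generates the canonical 20-species scenario in
#' exact-count mode, collapses replicates and builds per-sample profiles.
#' Realized non/total percentages equal the published ones to 1/n_sites
#' resolution.
#'
#' @param n_sites Fragments per sample (default 1000).
#' @param seed Integer seed (affects only the internal state permutation,
#'   not the profile counts).
#' @return A profile tibble (see [build_profiles()]).
#' @export
chrysanthemum_exact_profiles <- function(n_sites = 1000, seed = 1) {
  sc <- msap_scenario(n_sites = n_sites, seed = seed)
  tab <- generate_msap(sc)
  build_profiles(filter_reproducible(tab), attr(tab, "ploidy"))
}

#' Define a qRT-PCR simulation scenario
#'
#' Encodes the generative model for a cross-species Ct table:
#' \deqn{Ct = base_{gene} - \log_2 Q + run + sample + \epsilon}
#' where \eqn{Q} is the true relative quantity (1 for a perfectly stable
#' reference gene), `run` a per-run offset, `sample` a per-biological-
#' replicate shift common to all genes (template amount), and
#' \eqn{\epsilon} gaussian technical noise. Reference-gene instability is
#' modelled as a per-sample gaussian perturbation of \eqn{\log_2 Q} with
#' gene-specific (optionally ploidy-specific) SD.
#'
#' @param species Data frame with columns `species`, `ploidy`.
#' @param targets Data frame with columns `gene`, `species`,
#'   `log2_quantity` (true log2 relative quantity per species) and
#'   optionally `base_ct` (default 24).
#' @param references Data frame with columns `gene`, `base_ct`,
#'   `stability_sd` and optionally `ploidy` (NA or absent = applies to
#'   all ploidies) for ploidy-specific instability.
#' @param bio_reps,tech_reps Biological / technical replicates (default 3
#'   each).
#' @param ct_noise_sd Technical Ct noise SD in cycles (default 0.1).
#' @param run_offset_sd SD of per-run offsets in cycles (default 0.3);
#'   one run per biological replicate (all genes and species of a
#'   biological replicate share a plate).
#' @param sample_effect_sd SD of per-(species, bio rep) template shifts in
#'   cycles (default 0.2).
#' @param seed Integer seed.
#' @return An object of class `ct_scenario`.
#' @export
ct_scenario <- function(species, targets, references,
                        bio_reps = 3, tech_reps = 3,
                        ct_noise_sd = 0.1, run_offset_sd = 0.3,
                        sample_effect_sd = 0.2, seed = 1) {
  species <- tibble::as_tibble(species)
  targets <- tibble::as_tibble(targets)
  references <- tibble::as_tibble(references)
  assert_cols(species, c("species", "ploidy"), "species table")
  assert_cols(targets, c("gene", "species", "log2_quantity"),
              "targets table")
  assert_cols(references, c("gene", "base_ct", "stability_sd"),
              "references table")
  stopifnot(bio_reps >= 1, tech_reps >= 1, ct_noise_sd >= 0,
            run_offset_sd >= 0, sample_effect_sd >= 0)
  if (!"base_ct" %in% names(targets)) targets$base_ct <- 24
  if (!"ploidy" %in% names(references)) references$ploidy <- NA_integer_
  structure(
    list(species = species, targets = targets, references = references,
         bio_reps = as.integer(bio_reps), tech_reps = as.integer(tech_reps),
         ct_noise_sd = ct_noise_sd, run_offset_sd = run_offset_sd,
         sample_effect_sd = sample_effect_sd, seed = as.integer(seed)),
    class = "ct_scenario"
  )
}

#' Canonical qRT-PCR scenario for the five-species ploidy series
#'
#' The default expression scenario: the five intensively studied species
#' (2x--10x), MET1 and DDM1 target ladders from
#' [chrysanthemum_fold_changes()], and four candidate reference genes at
#' their observed expression strata (EF1a most abundant, then ACTIN, TUB
#' and PP2A) with modest, gene-specific instability.
#'
#' @param ct_noise_sd Technical Ct noise SD (default 0.1 cycles).
#' @param seed Integer seed.
#' @return A `ct_scenario`.
#' @export
ct_scenario_chrysanthemum <- function(ct_noise_sd = 0.1, seed = 1) {
  fc <- chrysanthemum_fold_changes()
  species <- dplyr::distinct(fc, .data$species, .data$ploidy)
  targets <- fc |>
    dplyr::transmute(.data$gene, .data$species,
                     log2_quantity = log2(.data$fold_vs_diploid),
                     base_ct = ifelse(.data$gene == "MET1", 24, 26))
  references <- tibble::tibble(
    gene = c("EF1a", "ACTIN", "TUB", "PP2A"),
    base_ct = c(17, 19.3, 21, 25.9),
    stability_sd = c(0.02, 0.06, 0.04, 0.03)
  )
  ct_scenario(species, targets, references,
              ct_noise_sd = ct_noise_sd, seed = seed)
}

#' Generate a synthetic Ct table
#'
#' @param scenario A [ct_scenario()].
#' @return A Ct table tibble: `species`, `ploidy`, `gene`, `role`
#'   (`"target"`/`"reference"`), `bio_rep`, `tech_rep`, `run_id`, `ct`.
#'   Bit-reproducible for a fixed seed.
#' @examples
#' ct <- generate_ct(ct_scenario_chrysanthemum(seed = 3))
#' @export
generate_ct <- function(scenario) {
  stopifnot(inherits(scenario, "ct_scenario"))
  sp <- scenario$species
  genes <- dplyr::bind_rows(
    scenario$targets |>
      dplyr::distinct(.data$gene, .data$base_ct) |>
      dplyr::mutate(role = "target"),
    scenario$references |>
      dplyr::distinct(.data$gene, .data$base_ct) |>
      dplyr::mutate(role = "reference")
  )
  withr::with_seed(scenario$seed, {
    runs <- setNames(rnorm(scenario$bio_reps, 0, scenario$run_offset_sd),
                     paste0("run_", seq_len(scenario$bio_reps)))
    grid <- tidyr::expand_grid(
      sp,
      genes,
      bio_rep = seq_len(scenario$bio_reps)
    ) |>
      dplyr::mutate(run_id = paste0("run_", .data$bio_rep))
    # per-(species, bio rep) template shift, shared by all genes
    shifts <- grid |>
      dplyr::distinct(.data$species, .data$bio_rep) |>
      dplyr::mutate(sample_shift = rnorm(dplyr::n(), 0,
                                         scenario$sample_effect_sd))
    # true log2 quantity: target ladders; reference instability per sample
    grid <- grid |>
      dplyr::left_join(shifts, by = c("species", "bio_rep")) |>
      dplyr::left_join(
        scenario$targets |>
          dplyr::select("gene", "species", "log2_quantity"),
        by = c("gene", "species")
      )
    ref_sd <- function(gene, ploidy) {
      r <- scenario$references
      hit <- r$gene == gene & !is.na(r$ploidy) & r$ploidy == ploidy
      if (any(hit)) return(r$stability_sd[which(hit)[1]])
      hit <- r$gene == gene & is.na(r$ploidy)
      if (any(hit)) return(r$stability_sd[which(hit)[1]])
      0
    }
    grid <- grid |>
      dplyr::mutate(
        log2_quantity = dplyr::if_else(
          .data$role == "reference",
          rnorm(dplyr::n(), 0,
                purrr::map2_dbl(.data$gene, .data$ploidy, ref_sd)),
          .data$log2_quantity
        )
      )
    if (anyNA(grid$log2_quantity)) {
      stop("targets table must cover every species", call. = FALSE)
    }
    out <- tidyr::expand_grid(grid,
                              tech_rep = seq_len(scenario$tech_reps)) |>
      dplyr::mutate(
        ct = .data$base_ct - .data$log2_quantity +
          .env$runs[.data$run_id] + .data$sample_shift +
          rnorm(dplyr::n(), 0, scenario$ct_noise_sd)
      ) |>
      dplyr::select("species", "ploidy", "gene", "role", "bio_rep",
                    "tech_rep", "run_id", "ct") |>
      dplyr::arrange(.data$species, .data$gene, .data$bio_rep,
                     .data$tech_rep)
    out
  })
}

#' Generate synthetic flow-cytometry peak data
#'
#' Emits per-replicate fluorescence peak means whose species ratios follow
#' the requested relative nuclear DNA contents, with lognormal measurement
#' noise and per-replicate CVs; a configurable fraction of replicates is
#' given CV >= 5% so acceptance filtering can be exercised.
#'
#' @param ratios Named numeric vector (species -> relative content) or a
#'   data frame with columns `species`, `relative_content`. Defaults to
#'   the canonical five-species series.
#' @param reference_peak Mean fluorescence assigned to relative content 1
#'   (arbitrary units, default 100).
#' @param noise_sd SD of lognormal peak noise on the log scale (default
#'   0).
#' @param replicates Replicates per species (default 3).
#' @param reject_fraction Fraction of replicates drawn with CV >= 0.05
#'   (default 0).
#' @param seed Integer seed.
#' @return A tibble: `species`, `replicate`, `peak_mean`, `cv`.
#' @export
generate_flow <- function(ratios = chrysanthemum_dna_content(),
                          reference_peak = 100, noise_sd = 0,
                          replicates = 3, reject_fraction = 0, seed = 1) {
  if (is.data.frame(ratios)) {
    assert_cols(ratios, c("species", "relative_content"), "ratios table")
    ratios <- setNames(ratios$relative_content, ratios$species)
  }
  stopifnot(all(ratios > 0), replicates >= 1, noise_sd >= 0,
            reject_fraction >= 0, reject_fraction < 1)
  withr::with_seed(seed, {
    out <- tidyr::expand_grid(
      species = names(ratios),
      replicate = seq_len(replicates)
    ) |>
      dplyr::mutate(
        peak_mean = reference_peak * unname(ratios[.data$species]) *
          exp(rnorm(dplyr::n(), 0, .env$noise_sd)),
        rejected = runif(dplyr::n()) < .env$reject_fraction,
        cv = ifelse(.data$rejected, runif(dplyr::n(), 0.05, 0.12),
                    runif(dplyr::n(), 0.005, 0.045))
      ) |>
      dplyr::select("species", "replicate", "peak_mean", "cv")
    out
  })
}
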