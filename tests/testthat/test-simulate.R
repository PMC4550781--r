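test_that("exact-count generation round-trips the target proportions", {
  pac <- dplyr::filter(chrysanthemum_methylation(),
                       species == "A. pacificum")
  sc <- msap_scenario(pac, n_sites = 1000, seed = 3)
  tab <- generate_msap(sc)
  prof <- build_profiles(filter_reproducible(tab), attr(tab, "ploidy"))
  expect_equal(100 * prof$p_non, 40.8)
  expect_equal(100 * prof$p_total, 59.2)
  # full/hemi reconciled within the methylated share (printed columns are
  # rounding-inconsistent for this species by 0.1 points)
  expect_equal(100 * prof$p_full, pac$full_pct, tolerance = 0.101)
  expect_equal(100 * prof$p_hemi, pac$hemi_pct, tolerance = 0.101)
})

test_that("the round-trip identity holds at 1/n resolution for all species", {
  for (n in c(250, 1000)) {
    prof <- chrysanthemum_exact_profiles(n_sites = n, seed = 2)
    pub <- chrysanthemum_methylation()
    real <- 100 * prof$p_total[match(pub$species, prof$sample)]
    expect_true(all(abs(real - pub$total_pct) <= 100 / n + 1e-9))
  }
})

test_that("discordance-free tables survive the reproducibility filter intact", {
  sc <- msap_scenario(n_sites = 200, discordance_rate = 0, seed = 5)
  tab <- generate_msap(sc)
  out <- filter_reproducible(tab)
  expect_identical(dplyr::n_distinct(out$primer_combo, out$size_bp), 200L)
})

test_that("injected discordance removes fragments table-wide", {
  sc <- msap_scenario(n_sites = 400, discordance_rate = 0.02, seed = 5)
  tab <- generate_msap(sc)
  out <- filter_reproducible(tab)
  n_kept <- dplyr::n_distinct(out$primer_combo, out$size_bp)
  expect_lt(n_kept, 400L)
  expect_gt(n_kept, 0L)
})

test_that("multinomial generation recovers targets within binomial error", {
  one <- tibble::tibble(species = "S1", ploidy = 2L,
                        p_non = 0.45, p_full = 0.30, p_hemi = 0.25)
  sc <- msap_scenario(one, n_sites = 10000, mode = "multinomial", seed = 11)
  tab <- generate_msap(sc)
  prof <- build_profiles(filter_reproducible(tab), attr(tab, "ploidy"))
  for (m in c("non", "full", "hemi")) {
    p0 <- one[[paste0("p_", m)]]
    tol <- 3 * sqrt(p0 * (1 - p0) / 10000)
    expect_lt(abs(prof[[paste0("p_", m)]] - p0), tol)
  }
})

test_that("generators are bit-reproducible under a fixed seed", {
  sc <- msap_scenario(n_sites = 150, discordance_rate = 0.05, seed = 9)
  expect_identical(generate_msap(sc), generate_msap(sc))
  sc2 <- msap_scenario(n_sites = 150, discordance_rate = 0.05, seed = 10)
  expect_false(identical(generate_msap(sc), generate_msap(sc2)))

  cts <- ct_scenario_chrysanthemum(seed = 4)
  expect_identical(generate_ct(cts), generate_ct(cts))

  expect_identical(generate_flow(noise_sd = 0.02, seed = 4),
                   generate_flow(noise_sd = 0.02, seed = 4))
})

test_that("scenario validation rejects inconsistent proportions", {
  bad <- tibble::tibble(species = "S1", ploidy = 2L,
                        p_non = 0.5, p_full = 0.4, p_hemi = 0.3)
  expect_error(msap_scenario(bad), "p_non \\+ p_total")
  expect_error(msap_scenario(n_sites = 2), "n_sites")
  expect_error(msap_scenario(discordance_rate = 1), "discordance_rate")
})

test_that("noise-free Ct tables encode fold changes exactly", {
  species <- tibble::tibble(species = c("cal", "A"), ploidy = c(2L, 4L))
  targets <- tibble::tibble(gene = "T1", species = c("cal", "A"),
                            log2_quantity = c(0, 1))
  refs <- tibble::tibble(gene = paste0("R", 1:3), base_ct = c(17, 20, 23),
                         stability_sd = 0)
  sc <- ct_scenario(species, targets, refs, ct_noise_sd = 0,
                    run_offset_sd = 0.5, sample_effect_sd = 0.4, seed = 6)
  ct <- generate_ct(sc)
  fit <- chained_normalization(ct, one_segment_plan("R1", c(2L, 4L)), "cal")
  q <- tidy(fit)
  expect_equal(q$quantity[q$species == "A"], 2, tolerance = 1e-12)
  expect_equal(q$quantity[q$species == "cal"], 1)
})

test_that("flow generation reproduces requested content ratios", {
  flow <- generate_flow(noise_sd = 0, seed = 2)
  ratios <- dna_content_ratio(flow, "C. nankingense")
  expected <- chrysanthemum_dna_content()
  expect_equal(
    ratios$relative_content[match(expected$species, ratios$species)],
    expected$relative_content, tolerance = 1e-12
  )
  # requested rejection fraction materializes in the CV column
  big <- generate_flow(replicates = 400, reject_fraction = 0.2, seed = 8)
  expect_equal(mean(big$cv >= 0.05), 0.2, tolerance = 0.03)
})
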