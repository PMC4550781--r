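test_that("a zero-variation pair attains the minimal M values", {
  base <- tidyr::expand_grid(species = paste0("s", 1:6), bio_rep = 1L)
  base$ploidy <- rep(c(2L, 4L, 6L), each = 2)
  ct <- withr::with_seed(1, dplyr::bind_rows(
    dplyr::mutate(base, gene = "gA", ct = 20 + seq_len(6)),
    dplyr::mutate(base, gene = "gB", ct = 22 + seq_len(6)),  # parallel to gA
    dplyr::mutate(base, gene = "gC", ct = 21 + rnorm(6, 0, 2))
  ))
  ct$role <- "reference"; ct$tech_rep <- 1L; ct$run_id <- "r1"
  m <- mvalue_stability(ct, c("gA", "gB", "gC"))
  expect_lt(max(m$m_value[m$gene != "gC"]), m$m_value[m$gene == "gC"])
  # the parallel pair's mutual variation is zero, so their M values agree
  expect_equal(m$m_value[m$gene == "gA"], m$m_value[m$gene == "gB"])
})

test_that("sample-wise Ct shifts cancel in both stability statistics", {
  ct <- sim_reference_ct(2, sds = c(0.05, 0.1, 0.2, 0.4))
  shifted <- dplyr::mutate(
    ct, ct = ct + 3 * match(paste(species, bio_rep),
                            unique(paste(species, bio_rep)))
  )
  expect_equal(mvalue_stability(shifted)$m_value,
               mvalue_stability(ct)$m_value, tolerance = 1e-9)
  expect_equal(variance_stability(shifted)$variance_score,
               variance_stability(ct)$variance_score, tolerance = 1e-9)
})

test_that("a residual-free gene scores zero and ranks first", {
  # gene gA carries exactly the sample mean after centering
  base <- tidyr::expand_grid(species = paste0("s", 1:4), bio_rep = 1:2)
  base$ploidy <- rep(c(2L, 4L), each = 4)
  shift <- seq_len(nrow(base))
  ct <- dplyr::bind_rows(
    dplyr::mutate(base, gene = "gA", ct = 20 + shift),
    dplyr::mutate(base, gene = "gB", ct = 22 + shift + rep(c(0, 0.8), 4)),
    dplyr::mutate(base, gene = "gC", ct = 24 + shift + rep(c(0.5, -0.5), 4))
  )
  ct$role <- "reference"; ct$tech_rep <- 1L; ct$run_id <- "r1"
  v <- variance_stability(ct, c("gA", "gB", "gC"))
  a <- dplyr::filter(v, gene == "gA")
  expect_lt(a$variance_score, min(v$variance_score[v$gene != "gA"]))
  expect_identical(a$rank, 1L)
})

test_that("stability statistics separate clearly different noise levels", {
  sds <- c(0.05, 0.1, 0.2, 0.4)
  top_low_m <- last_m <- top_low_v <- last_v <- 0L
  for (s in 1:200) {
    ct <- sim_reference_ct(s, sds)
    m <- mvalue_stability(ct, paste0("g", 1:4))
    v <- variance_stability(ct, paste0("g", 1:4))
    top_low_m <- top_low_m + (m$gene[m$rank == 1] %in% c("g1", "g2"))
    last_m <- last_m + (m$gene[m$rank == 4] == "g4")
    top_low_v <- top_low_v + (v$gene[v$rank == 1] %in% c("g1", "g2"))
    last_v <- last_v + (v$gene[v$rank == 4] == "g4")
  }
  expect_gte(top_low_m / 200, 0.95)
  expect_gte(last_m / 200, 0.95)
  expect_gte(top_low_v / 200, 0.95)
  expect_gte(last_v / 200, 0.95)
})

test_that("a noise-free gene among noisy ones is always ranked first", {
  for (s in 1:20) {
    ct <- sim_reference_ct(s, sds = c(0, 0.4, 0.4, 0.4), n_species = 12)
    expect_identical(mvalue_stability(ct)$rank[1], 1L)
    v <- variance_stability(ct)
    expect_identical(v$gene[v$rank == 1], "g1")
  }
})

test_that("degenerate stability inputs are rejected", {
  ct <- sim_reference_ct(1, sds = c(0.1, 0.2))
  expect_error(mvalue_stability(ct, c("g1", "g2")), ">= 3 candidate")
  singleton <- sim_reference_ct(1, sds = c(0.1, 0.2, 0.3), n_species = 3,
                                bio_reps = 1)
  singleton$ploidy <- c(2L, 4L, 6L)[match(singleton$species,
                                          paste0("s", 1:3))]
  expect_error(variance_stability(singleton), "singleton")
})

test_that("reference selection picks per-comparison winners and breaks ties", {
  # EF1a engineered stable in the low-ploidy set, TUB in the high set
  species <- tibble::tibble(species = paste0("s", 1:6),
                            ploidy = rep(c(2L, 4L, 6L, 8L), c(2, 1, 2, 1)))
  refs <- tibble::tibble(
    gene = rep(c("EF1a", "TUB", "ACTIN"), each = 2),
    ploidy = rep(c(NA, 8L, NA, 2L, NA, NA), 1),
    base_ct = rep(c(17, 21, 19), each = 2),
    stability_sd = c(0.02, 0.8, 0.02, 0.8, 0.4, 0.4)
  ) |> dplyr::distinct(gene, ploidy, .keep_all = TRUE)
  targets <- tibble::tibble(gene = "T1", species = species$species,
                            log2_quantity = 0)
  sc <- ct_scenario(species, targets, refs, ct_noise_sd = 0.02, seed = 3)
  ct <- generate_ct(sc)
  plan <- select_references(
    ct, list(low = c(2, 4, 6), high = c(6, 8)),
    candidates = c("EF1a", "TUB", "ACTIN")
  )
  expect_identical(plan$gene[plan$segment == "low"], "EF1a")
  expect_identical(plan$gene[plan$segment == "high"], "TUB")
  # exact tie (duplicated gene profiles): lexicographic fall-back
  dup <- dplyr::bind_rows(
    sim_reference_ct(4, sds = c(0.1, 0.3)),
    dplyr::mutate(dplyr::filter(sim_reference_ct(4, sds = c(0.1, 0.3)),
                                gene == "g1"), gene = "g0")
  )
  r <- stability_ranking(dup, c("g0", "g1", "g2"))
  expect_identical(r$gene[1], "g0")
})
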