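# A deterministic hand-made Ct table spanning three chained segments:
# 2x/4x share EF-like ref rA, 4x/6x share rB. True quantities are known.
chain_ct <- function() {
  tibble::tribble(
    ~species, ~ploidy, ~gene, ~role, ~ct,
    "cal", 2L, "T1", "target", 24,
    "cal", 2L, "rA", "reference", 20,
    "mid", 4L, "T1", "target", 22,    # 2^2 = 4x the calibrator vs rA
    "mid", 4L, "rA", "reference", 20,
    "mid", 4L, "rB", "reference", 18,
    "top", 6L, "T1", "target", 21,
    "top", 6L, "rB", "reference", 18  # 2x "mid" within the rB segment
  ) |>
    dplyr::mutate(bio_rep = 1L, tech_rep = 1L, run_id = "r1")
}

chain_plan <- function() {
  tibble::tibble(segment = c("lo", "hi"), gene = c("rA", "rB"),
                 ploidies = list(c(2L, 4L), c(4L, 6L)))
}

test_that("delta-Ct arithmetic gives a fold change of 2 per cycle", {
  ct <- tibble::tibble(
    species = rep(c("cal", "A"), each = 2),
    ploidy = rep(c(2L, 4L), each = 2),
    gene = rep(c("T1", "ref"), 2), role = rep(c("target", "reference"), 2),
    bio_rep = 1L, tech_rep = 1L, run_id = "r1",
    ct = c(20, 20, 19, 20)  # target one cycle below reference in A only
  )
  fit <- chained_normalization(ct, one_segment_plan("ref", c(2L, 4L)),
                               "cal")
  q <- tidy(fit)
  expect_equal(q$quantity[q$species == "A"], 2)
  expect_equal(q$quantity[q$species == "cal"], 1)
})

test_that("segments chain through shared species to the calibrator", {
  fit <- chained_normalization(chain_ct(), chain_plan(), "cal")
  q <- tidy(fit)
  expect_equal(q$quantity[q$species == "cal"], 1)
  expect_equal(q$quantity[q$species == "mid"], 4)
  expect_equal(q$quantity[q$species == "top"], 8)
})

test_that("fold changes compose consistently across species", {
  fit <- chained_normalization(chain_ct(), chain_plan(), "cal")
  fc <- fold_changes(fit)
  get <- function(a, b) fc$fold_change[fc$from == a & fc$to == b]
  expect_equal(get("cal", "top"), get("cal", "mid") * get("mid", "top"),
               tolerance = 1e-9)
  expect_equal(get("top", "cal"), 1 / get("cal", "top"), tolerance = 1e-9)
})

test_that("run-wide Ct shifts cancel out of the normalization", {
  sc <- ct_scenario_chrysanthemum(seed = 5)
  ct <- generate_ct(sc)
  shifted <- dplyr::mutate(ct, ct = ct + ifelse(run_id == "run_2", 4.5, 0))
  plan <- chrysanthemum_reference_plan()$plan
  q0 <- tidy(chained_normalization(ct, plan, "C. nankingense"))
  q1 <- tidy(chained_normalization(shifted, plan, "C. nankingense"))
  expect_equal(q1$quantity, q0$quantity, tolerance = 1e-9)
})

test_that("the inter-run calibrator validates a noise-free chain", {
  sc <- ct_scenario_chrysanthemum(ct_noise_sd = 0, seed = 1)
  sc$references$stability_sd <- 0
  ct <- generate_ct(sc)
  fit <- chained_normalization(ct, chrysanthemum_reference_plan()$plan,
                               "C. nankingense", irc_gene = "PP2A",
                               irc_ploidies = c(4, 8, 10))
  g <- glance(fit)
  expect_true(all(g$irc_cv < 0.01))
  expect_true(all(g$valid))
  # and the encoded ladders are recovered exactly
  truth <- chrysanthemum_fold_changes()
  q <- dplyr::inner_join(tidy(fit), truth, by = c("gene", "species"))
  expect_equal(q$quantity, q$fold_vs_diploid, tolerance = 1e-9)
})

test_that("biological replicates carry a standard error; calibrator is 1", {
  ct <- generate_ct(ct_scenario_chrysanthemum(seed = 2))
  fit <- chained_normalization(ct, chrysanthemum_reference_plan()$plan,
                               "C. nankingense")
  q <- tidy(fit)
  expect_true(all(q$n == 3L))
  expect_true(all(q$se >= 0))
  expect_true(all(q$se[q$species != "C. nankingense"] > 0))
  expect_equal(q$quantity[q$species == "C. nankingense"], c(1, 1))
})

test_that("a disconnected segment plan is rejected", {
  plan <- tibble::tibble(segment = c("a", "b"), gene = c("rA", "rB"),
                         ploidies = list(c(2L, 4L), c(6L)))
  ct <- chain_ct()
  expect_error(chained_normalization(ct, plan, "cal"), "disconnected")
})

test_that("encoded fold-change ladders are recovered on average", {
  plan <- chrysanthemum_reference_plan()$plan
  truth <- dplyr::filter(chrysanthemum_fold_changes(), gene == "DDM1")
  qs <- vapply(1:60, function(s) {
    sc <- ct_scenario_chrysanthemum(ct_noise_sd = 0.1, seed = s)
    fit <- chained_normalization(generate_ct(sc), plan, "C. nankingense")
    q <- dplyr::filter(tidy(fit), gene == "DDM1")
    q$quantity[match(truth$species, q$species)]
  }, numeric(5))
  expect_equal(rowMeans(qs), truth$fold_vs_diploid, tolerance = 0.05)
})
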