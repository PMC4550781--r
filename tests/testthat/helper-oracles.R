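# Independent oracles and small fixture builders shared by the tests.

# Direct arithmetic on the pooled two-proportion formulas, written
# independently of u_statistic() so the two can be cross-checked.
oracle_u <- function(y1, n1, y2, n2) {
  p <- (y1 + y2) / (n1 + n2)
  q <- 1 - p
  delta <- sqrt(p * q * (1 / n1 + 1 / n2))
  if (delta == 0) return(0)
  abs(y1 / n1 - y2 / n2) / delta
}

# A minimal collapsed fragment table with the requested state counts for
# one sample (states rendered as H/M band patterns).
fragment_table_for <- function(sample_id, n_non, n_full, n_hemi,
                               n_uninf = 0) {
  states <- rep(c("non", "full", "hemi", "uninf"),
                c(n_non, n_full, n_hemi, n_uninf))
  n <- length(states)
  tibble::tibble(
    sample = sample_id,
    primer_combo = "E2+HM5",
    size_bp = seq(120, length.out = n),
    H = as.integer(states %in% c("non", "hemi")),
    M = as.integer(states %in% c("non", "full"))
  ) |>
    tidyr::pivot_longer(c("H", "M"), names_to = "enzyme_lane",
                        values_to = "present")
}

# A hand-built profile row, bypassing classification.
profile_row <- function(sample, ploidy, n_sites, p_full, p_hemi) {
  n_full <- round(p_full * n_sites)
  n_hemi <- round(p_hemi * n_sites)
  n_non <- n_sites - n_full - n_hemi
  tibble::tibble(
    sample = sample, ploidy = as.integer(ploidy),
    n_sites = as.integer(n_sites), n_non = n_non, n_full = n_full,
    n_hemi = n_hemi, y_total = n_full + n_hemi,
    p_non = n_non / n_sites, p_full = n_full / n_sites,
    p_hemi = n_hemi / n_sites,
    p_total = (n_full + n_hemi) / n_sites
  )
}

# Reference-gene Ct table with per-gene sample-level noise SDs; one row
# per (species, bio_rep, gene), shared template shifts across genes.
sim_reference_ct <- function(seed, sds, n_species = 6, bio_reps = 3,
                             base_ct = 20) {
  withr::with_seed(seed, {
    genes <- paste0("g", seq_along(sds))
    sp <- tidyr::expand_grid(species = paste0("s", seq_len(n_species)),
                             bio_rep = seq_len(bio_reps))
    sp$ploidy <- rep(rep(c(2L, 4L, 6L), length.out = n_species),
                     each = bio_reps)
    sp$shift <- rnorm(nrow(sp), 0, 1)
    out <- tidyr::expand_grid(sp, gene = genes)
    out$role <- "reference"
    out$tech_rep <- 1L
    out$run_id <- "r1"
    out$ct <- base_ct + out$shift +
      rnorm(nrow(out), 0, sds[match(out$gene, genes)])
    out$shift <- NULL
    out
  })
}

# Single-segment chained normalization plan.
one_segment_plan <- function(gene, ploidies) {
  tibble::tibble(segment = "all", gene = gene, ploidies = list(ploidies))
}
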