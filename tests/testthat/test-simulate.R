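test_that("methylome simulation is deterministic and validates its config", {
  cfg <- methylome_config(seed = 7, n_chromosomes = 2,
                          probes_per_chromosome = 300,
                          n_spiked_regions = 4)
  s1 <- simulate_methylome(cfg)
  s2 <- simulate_methylome(cfg)
  expect_identical(s1$design, s2$design)
  expect_identical(tibble::as_tibble(s1$truth), tibble::as_tibble(s2$truth))
  expect_identical(purrr::map(s1$groups, "values"),
                   purrr::map(s2$groups, "values"))

  expect_error(methylome_config(probes_per_chromosome = 0),
               class = "methtrace_config_error")
  expect_error(methylome_config(probe_spacing_bp = -5),
               class = "methtrace_config_error")
  expect_error(methylome_config(n_replicates = 1),
               class = "methtrace_config_error")
  expect_error(methylome_config(probe_length_bp = 200, probe_spacing_bp = 100),
               class = "methtrace_config_error")
})

test_that("persistence scenario controls which treated groups carry the effect", {
  scenarios <- list(
    none = "G1R_MGC",
    g1_only = c("G1R_MGC", "G1R_sperm"),
    g1_and_sperm = c("G1R_MGC", "G1R_sperm", "G2R_MGC"),
    full_tgi = c("G1R_MGC", "G1R_sperm", "G2R_MGC", "G2R_sperm")
  )
  delta <- 0.5
  for (sc in names(scenarios)) {
    sim <- simulate_methylome(methylome_config(
      seed = 3, n_chromosomes = 2, probes_per_chromosome = 400,
      n_spiked_regions = 6, effect_log2_delta = delta, persistence = sc,
      baseline_log2_sd = 0.2, n_replicates = 3
    ))
    spike <- region_probe_mask(sim)
    n_spike_vals <- sum(spike) * 3
    se <- 0.2 / sqrt(n_spike_vals)
    for (label in c("G1R_MGC", "G1R_sperm", "G2R_MGC", "G2R_sperm")) {
      shift <- mean(sim$groups[[paste0(label, "_treated")]]$values[spike, ]) -
        mean(sim$groups[[paste0(label, "_oil")]]$values[spike, ])
      expected <- if (label %in% scenarios[[sc]]) delta else 0
      expect_lt(abs(shift - expected), 3 * sqrt(2) * se)
    }
  }
})

test_that("group means match the generative formula within 3 SE", {
  cfg <- methylome_config(seed = 5, n_chromosomes = 2,
                          probes_per_chromosome = 500,
                          baseline_log2_mean = 0.2, baseline_log2_sd = 0.3,
                          methylated_region_log2_mean = 1.5,
                          n_spiked_regions = 5)
  sim <- simulate_methylome(cfg)
  spike <- region_probe_mask(sim)
  g <- sim$groups$G1R_MGC_oil
  n_bg <- sum(!spike) * 3
  n_sp <- sum(spike) * 3
  expect_lt(abs(mean(g$values[!spike, ]) - 0.2), 3 * 0.3 / sqrt(n_bg))
  expect_lt(abs(mean(g$values[spike, ]) - 1.7), 3 * 0.3 / sqrt(n_sp))
  # spiked regions are disjoint from background probes by construction
  expect_identical(sum(spike), nrow(tibble::as_tibble(sim$truth)) *
                     cfg$probes_per_region)
})

test_that("allelotype generator follows the odds-scale skew model", {
  # identity skew, no noise: observed equals the true fraction
  cfg <- allelotype_config(seed = 1, snp_ids = "a",
                           true_maternal_fraction = 0.5,
                           skew_ratio = 1, noise_sd = 0)
  out <- simulate_allelotypes(cfg)
  expect_equal(unique(out$measurements$raw_maternal_pct), 50)

  # skew 2, f = 0.5 -> 2/3, cross-checked on the odds scale
  cfg2 <- allelotype_config(seed = 1, snp_ids = "a",
                            true_maternal_fraction = 0.5,
                            skew_ratio = 2, noise_sd = 0)
  out2 <- simulate_allelotypes(cfg2)
  expect_equal(unique(out2$measurements$raw_maternal_pct), 100 * 2 / 3)
  expect_equal(unique(out2$measurements$raw_maternal_pct) / 100,
               oracle_apply_skew(0.5, 2))

  # boundary: f = 0 stays 0 under any skew
  cfg0 <- allelotype_config(seed = 1, snp_ids = "a",
                            true_maternal_fraction = 0,
                            skew_ratio = 5, noise_sd = 0)
  expect_equal(unique(simulate_allelotypes(cfg0)$measurements$raw_maternal_pct), 0)

  # standards carry the mixing series and a het standard under the skew
  expect_setequal(
    out2$standards$true_maternal_pct[out2$standards$kind == "mixing_point"],
    c(0, 10, 30, 50, 70, 90, 100)
  )
  het <- out2$standards[out2$standards$kind == "het_dna", ]
  expect_equal(het$observed_maternal_pct, 100 * 2 / 3)

  # fractions are clipped to [0, 1] after noise
  cfgn <- allelotype_config(seed = 2, snp_ids = letters[1:5],
                            true_maternal_fraction = c(0, 0.01, 0.5, 0.99, 1),
                            noise_sd = 0.5, n_replicates = 20)
  outn <- simulate_allelotypes(cfgn)
  expect_true(all(outn$measurements$raw_maternal_pct >= 0 &
                    outn$measurements$raw_maternal_pct <= 100))

  expect_error(allelotype_config(skew_ratio = 0),
               class = "methtrace_config_error")
  expect_identical(simulate_allelotypes(cfgn), simulate_allelotypes(cfgn))
})

test_that("expression generator produces truth-labelled effects deterministically", {
  design <- tidyr::crossing(sex = c("F", "M"), generation = "G1R",
                            treatment = c("oil", "VZ"), rep = 1:3)
  design$sample_id <- sprintf("s%02d", seq_len(nrow(design)))
  sim <- simulate_expression(1000, design, sex_effect_log2 = 2,
                             n_sex_genes = 100, treatment_effect_log2 = 1,
                             n_treatment_genes = 50, noise_sd = 0.1,
                             seed = 9)
  expect_identical(sum(sim$truth$sex_gene), 100L)
  expect_identical(sum(sim$truth$treatment_gene), 50L)
  expect_identical(sum(sim$truth$sex_gene & sim$truth$treatment_gene), 0L)

  sim2 <- simulate_expression(1000, design, sex_effect_log2 = 2,
                              n_sex_genes = 100, treatment_effect_log2 = 1,
                              n_treatment_genes = 50, noise_sd = 0.1,
                              seed = 9)
  expect_identical(sim$expression, sim2$expression)

  expect_error(simulate_expression(10, design[0, ]),
               class = "methtrace_config_error")
  expect_error(simulate_expression(10, design, n_sex_genes = 8,
                                   n_treatment_genes = 8),
               class = "methtrace_config_error")
})
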