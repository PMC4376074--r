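make_expr_design <- function(n_rep = 3) {
  design <- tidyr::crossing(sex = c("F", "M"), generation = c("G1R", "G2R"),
                            treatment = c("oil", "DEHP"), rep = seq_len(n_rep))
  design$sample_id <- sprintf("s%02d", seq_len(nrow(design)))
  design
}

sample_ids <- function(design, ...) {
  dplyr::filter(design, ...)$sample_id
}

test_that("null simulations give ~0 strict hits and calibrated p-values", {
  design <- make_expr_design()
  sim <- simulate_expression(3000, design, noise_sd = 0.2, seed = 100)
  de <- differential_expression(
    sim$expression,
    sample_ids(design, treatment == "DEHP", sex == "M"),
    sample_ids(design, treatment == "oil", sex == "M"),
    profile = "strict"
  )
  expect_lte(sum(de$passed), 2)
  # raw p-values roughly uniform: ~5% below 0.05
  expect_lt(abs(mean(de$p_value < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / 3000))
})

test_that("a 2-fold treatment effect is recovered at the strict profile", {
  design <- make_expr_design()
  sim <- simulate_expression(2000, design, treatment_effect_log2 = 1,
                             n_treatment_genes = 100, noise_sd = 0.1,
                             seed = 101)
  de <- differential_expression(
    sim$expression,
    sample_ids(design, treatment == "DEHP"),
    sample_ids(design, treatment == "oil"),
    profile = "strict"
  )
  truth <- sim$truth$gene_id[sim$truth$treatment_gene]
  hits <- de$gene_id[de$passed]
  expect_gte(sum(truth %in% hits) / length(truth), 0.95)
  # and essentially nothing outside the truth set
  expect_lte(sum(!hits %in% truth), 5)
  expect_true(all(de$direction[de$gene_id %in% truth & de$passed] == "up"))
})

test_that("p-values match the pooled t oracle and q-values are BH-monotone", {
  design <- make_expr_design(n_rep = 3)
  sim <- simulate_expression(50, design, noise_sd = 0.3, seed = 102)
  a_ids <- sample_ids(design, treatment == "DEHP", sex == "F")
  b_ids <- sample_ids(design, treatment == "oil", sex == "F")
  de <- differential_expression(sim$expression, a_ids, b_ids,
                                profile = "relaxed1")
  mat <- as.matrix(sim$expression[, -1])
  rownames(mat) <- sim$expression$gene_id
  for (i in c(1, 17, 50)) {
    expect_equal(de$p_value[i],
                 oracle_student_t_p(mat[i, a_ids], mat[i, b_ids]),
                 tolerance = 1e-12)
  }
  ord <- order(de$p_value)
  expect_true(all(diff(de$fdr_q[ord]) >= -1e-12))
})

test_that("sex contrasts dwarf treatment contrasts when sex drives the data", {
  design <- make_expr_design()
  sim <- simulate_expression(2000, design, sex_effect_log2 = 2,
                             n_sex_genes = 500, treatment_effect_log2 = 0.3,
                             n_treatment_genes = 20, noise_sd = 0.1,
                             seed = 103)
  de_sex <- differential_expression(
    sim$expression,
    sample_ids(design, sex == "F"), sample_ids(design, sex == "M"),
    profile = "strict"
  )
  de_trt <- differential_expression(
    sim$expression,
    sample_ids(design, treatment == "DEHP"),
    sample_ids(design, treatment == "oil"),
    profile = "strict"
  )
  expect_gt(sum(de_sex$passed), 10 * max(1, sum(de_trt$passed)))
  truth_sex <- sim$truth$gene_id[sim$truth$sex_gene]
  expect_gte(mean(de_sex$gene_id[de_sex$passed] %in% truth_sex), 0.99)
})

test_that("overlap counting and direction concordance behave at the extremes", {
  design <- make_expr_design()
  sim <- simulate_expression(500, design, treatment_effect_log2 = 1,
                             n_treatment_genes = 60, noise_sd = 0.1,
                             seed = 104)
  de <- differential_expression(
    sim$expression,
    sample_ids(design, treatment == "DEHP"),
    sample_ids(design, treatment == "oil"),
    profile = "strict"
  )
  # identical lists: every common transcript is same-direction
  ov <- g1_g2_overlap(de, de)
  expect_identical(ov$n_common, sum(de$passed))
  expect_identical(ov$n_same_direction, ov$n_common)

  # inverted directions: none agree
  flipped <- de
  flipped$log2_fold_change <- -flipped$log2_fold_change
  flipped$direction <- ifelse(flipped$direction == "up", "down", "up")
  ov2 <- g1_g2_overlap(de, flipped)
  expect_identical(ov2$n_common, sum(de$passed))
  expect_identical(ov2$n_same_direction, 0L)

  # disjoint universes error
  renamed <- de
  renamed$gene_id <- paste0("other_", renamed$gene_id)
  expect_error(g1_g2_overlap(de, renamed), "disjoint")
})

test_that("probes collapse to unique transcripts by best p-value", {
  de1 <- tibble::tibble(
    gene_id = c("p1", "p2", "p3"),
    transcript_id = c("t1", "t1", "t2"),
    log2_fold_change = c(1, -1, 1),
    p_value = c(0.001, 0.04, 0.01),
    fdr_q = c(0.01, 0.2, 0.05),
    direction = c("up", "down", "up"),
    passed = c(TRUE, TRUE, TRUE)
  )
  de2 <- de1
  ov <- g1_g2_overlap(de1, de2)
  # t1 keeps its best-p (up) probe only: 2 unique common transcripts
  expect_identical(ov$n_common, 2L)
  expect_identical(ov$n_same_direction, 2L)
})

test_that("independent random hit lists agree in direction about half the time", {
  set.seed(77)
  n <- 10000
  mk <- function() {
    tibble::tibble(
      gene_id = sprintf("t%05d", seq_len(n)),
      log2_fold_change = sample(c(-1, 1), n, TRUE),
      p_value = runif(n), fdr_q = runif(n),
      direction = NA_character_,
      passed = runif(n) < 0.3
    ) |>
      dplyr::mutate(direction = ifelse(log2_fold_change > 0, "up", "down"))
  }
  ov <- g1_g2_overlap(mk(), mk())
  frac <- ov$n_same_direction / ov$n_common
  # binomial 99.7% band around 0.5
  expect_gt(ov$n_common, 500)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / ov$n_common))
  # and the enrichment machinery sees no signal
  expect_gt(ov$enrichment$binomial_p, 0.001)
})
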