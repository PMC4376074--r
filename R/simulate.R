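#' Configuration for the synthetic methylome generator
#'
#' Defines the study layout the generator emulates: uniformly spaced
#' tiling probes per chromosome, a Gaussian log2(MIRA/input) baseline,
#' spiked methylated regions (runs of consecutive probes elevated in all
#' sample groups), and a treatment effect added on top of the spiked
#' regions in the treated groups selected by the persistence scenario.
#'
#' The `persistence` scenario decides how far along the germline chain
#' G1R prospermatogonia -> G1R sperm -> G2R prospermatogonia -> G2R sperm
#' the induced change is maintained:
#' * `"none"`: immediate effect in G1R MGCs only;
#' * `"g1_only"`: maintained into G1R sperm but not transmitted;
#' * `"g1_and_sperm"`: transmitted into G2R prospermatogonia but lost
#'   before G2R sperm;
#' * `"full_tgi"`: maintained in all four germline samples — true
#'   transgenerational inheritance.
#'
#' @param seed Integer seed; identical configurations give identical
#'   output.
#' @param n_chromosomes,probes_per_chromosome Array layout counts.
#' @param probe_spacing_bp Distance between probe starts (default 100 bp;
#'   tiling density is not a fixed platform property here, so it is
#'   configurable).
#' @param probe_length_bp Probe length, must not exceed the spacing so
#'   probes stay non-overlapping.
#' @param baseline_log2_mean,baseline_log2_sd Gaussian background of the
#'   log2 ratio.
#' @param methylated_region_log2_mean Elevation of spiked regions in
#'   *all* groups (constitutively methylated regions). Set to 0 to model
#'   regions that are unmethylated in controls and gain methylation only
#'   under treatment.
#' @param n_spiked_regions,probes_per_region Number and width of spiked
#'   regions.
#' @param effect_log2_delta Log2 shift added at spiked regions in the
#'   treated groups selected by `persistence`.
#' @param persistence One of `"none"`, `"g1_only"`, `"g1_and_sperm"`,
#'   `"full_tgi"`.
#' @param n_replicates Replicates per sample group (>= 2).
#'
#' @return A `methylome_config` list.
#' @export
methylome_config <- function(seed = 1L,
                             n_chromosomes = 5L,
                             probes_per_chromosome = 2000L,
                             probe_spacing_bp = 100L,
                             probe_length_bp = 50L,
                             baseline_log2_mean = 0,
                             baseline_log2_sd = 0.3,
                             methylated_region_log2_mean = 1.5,
                             n_spiked_regions = 20L,
                             probes_per_region = 10L,
                             effect_log2_delta = 0.5,
                             persistence = c("none", "g1_only",
                                             "g1_and_sperm", "full_tgi"),
                             n_replicates = 3L) {
  persistence <- match.arg(persistence)
  seed <- check_count(seed, "seed", min = 0L)
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  probes_per_chromosome <- check_count(probes_per_chromosome,
                                       "probes_per_chromosome")
  probe_spacing_bp <- check_count(probe_spacing_bp, "probe_spacing_bp")
  probe_length_bp <- check_count(probe_length_bp, "probe_length_bp")
  n_spiked_regions <- check_count(n_spiked_regions, "n_spiked_regions",
                                  min = 0L)
  probes_per_region <- check_count(probes_per_region, "probes_per_region")
  n_replicates <- check_count(n_replicates, "n_replicates", min = 2L)
  check_number(baseline_log2_mean, "baseline_log2_mean")
  check_number(baseline_log2_sd, "baseline_log2_sd")
  check_number(methylated_region_log2_mean, "methylated_region_log2_mean")
  check_number(effect_log2_delta, "effect_log2_delta")
  if (probe_length_bp > probe_spacing_bp) {
    rlang::abort("`probe_length_bp` must not exceed `probe_spacing_bp` (probes would overlap).",
                 class = "methtrace_config_error")
  }
  cfg <- list(
    seed = seed, n_chromosomes = n_chromosomes,
    probes_per_chromosome = probes_per_chromosome,
    probe_spacing_bp = probe_spacing_bp,
    probe_length_bp = probe_length_bp,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    methylated_region_log2_mean = methylated_region_log2_mean,
    n_spiked_regions = n_spiked_regions,
    probes_per_region = probes_per_region,
    effect_log2_delta = effect_log2_delta,
    persistence = persistence,
    n_replicates = n_replicates
  )
  # candidate spike slots: disjoint, away from chromosome edges
  if (length(spike_candidates(cfg)) < n_spiked_regions) {
    rlang::abort("array too small for the requested number of spiked regions.",
                 class = "methtrace_config_error")
  }
  structure(cfg, class = "methylome_config")
}

spike_candidates <- function(cfg) {
  margin <- 5L
  sep <- 5L
  per_chrom_starts <- seq(
    from = margin + 1L,
    to = cfg$probes_per_chromosome - cfg$probes_per_region - margin + 1L,
    by = cfg$probes_per_region + sep
  )
  unlist(purrr::map(seq_len(cfg$n_chromosomes), function(c) {
    paste(c, per_chrom_starts, sep = ":")
  }))
}

persistence_groups <- function(persistence) {
  switch(persistence,
    none = "G1R_MGC",
    g1_only = c("G1R_MGC", "G1R_sperm"),
    g1_and_sperm = c("G1R_MGC", "G1R_sperm", "G2R_MGC"),
    full_tgi = c("G1R_MGC", "G1R_sperm", "G2R_MGC", "G2R_sperm")
  )
}

#' Simulate a replicated multigeneration methylome experiment
#'
#' Generates the full sample-group structure of a two-generation germline
#' screen: \{G1R, G2R\} x \{MGC (prospermatogonia), sperm\} x \{oil,
#' treated\}, each with `n_replicates` arrays on a shared probe design.
#' Spiked regions are elevated by `methylated_region_log2_mean` in every
#' group and additionally shifted by `effect_log2_delta` in the treated
#' groups implied by the `persistence` scenario (see
#' [methylome_config()]). Gaussian noise is added per probe and
#' replicate.
#'
#' @param cfg A [methylome_config()].
#'
#' @return List of class `methylome_sim` with elements `design` (probe
#'   tibble), `groups` (named list of [methyl_group()]s, names like
#'   `"G1R_MGC_treated"`), `truth` (a [region_set()] of the spiked
#'   regions), `affected_groups` (labels of the treated groups carrying
#'   the effect) and `config`.
#' @export
simulate_methylome <- function(cfg) {
  if (!inherits(cfg, "methylome_config")) cfg <- do.call(methylome_config, cfg)
  set.seed(cfg$seed)

  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  m <- cfg$probes_per_chromosome
  design <- dplyr::bind_rows(purrr::map(chroms, function(ch) {
    start <- (seq_len(m) - 1L) * cfg$probe_spacing_bp
    tibble::tibble(
      probe_id = sprintf("%s_p%06d", ch, seq_len(m)),
      chrom = ch, start = start, end = start + cfg$probe_length_bp
    )
  }))

  cand <- spike_candidates(cfg)
  picked <- sort(sample(cand, cfg$n_spiked_regions))
  spike_mask <- logical(nrow(design))
  truth_rows <- purrr::imap(picked, function(key, i) {
    parts <- as.integer(strsplit(key, ":", fixed = TRUE)[[1]])
    first <- (parts[1] - 1L) * m + parts[2]
    idx <- first:(first + cfg$probes_per_region - 1L)
    spike_mask[idx] <<- TRUE
    tibble::tibble(
      name = sprintf("spike_%03d", i),
      chrom = design$chrom[idx[1]],
      start = design$start[idx[1]],
      end = design$end[idx[length(idx)]]
    )
  })
  truth_tbl <- dplyr::bind_rows(truth_rows)
  truth <- if (nrow(truth_tbl)) {
    region_set(truth_tbl$name, truth_tbl$chrom, truth_tbl$start,
               truth_tbl$end, class = "spike")
  } else {
    region_set(character(0), character(0), integer(0), integer(0))
  }

  affected <- persistence_groups(cfg$persistence)
  combos <- expand.grid(treatment = c("oil", "treated"),
                        cell_type = c("MGC", "sperm"),
                        generation = c("G1R", "G2R"),
                        stringsAsFactors = FALSE)
  combos <- combos[order(combos$generation, combos$cell_type,
                         combos$treatment), ]
  groups <- purrr::pmap(combos, function(treatment, cell_type, generation) {
    label <- paste(generation, cell_type, sep = "_")
    mu <- cfg$baseline_log2_mean +
      spike_mask * cfg$methylated_region_log2_mean +
      spike_mask * cfg$effect_log2_delta *
        (treatment == "treated" && label %in% affected)
    vals <- matrix(
      rnorm(nrow(design) * cfg$n_replicates, mean = mu,
            sd = cfg$baseline_log2_sd),
      nrow = nrow(design), ncol = cfg$n_replicates
    )
    samples <- tibble::tibble(
      sample_id = sprintf("%s_%s_%s_rep%d", generation, cell_type,
                          treatment, seq_len(cfg$n_replicates)),
      generation = generation, cell_type = cell_type,
      treatment = treatment, platform = "CpG_tiling"
    )
    colnames(vals) <- samples$sample_id
    methyl_group(design, vals, samples)
  })
  names(groups) <- paste(combos$generation, combos$cell_type,
                         combos$treatment, sep = "_")

  structure(
    list(design = design, groups = groups, truth = truth,
         affected_groups = affected, config = cfg),
    class = "methylome_sim"
  )
}

#' Simulate an imprinted-DMR methylation panel
#'
#' Generates a one-chromosome array carrying paternally and maternally
#' methylated DMRs with the sign structure expected in the male germline:
#' PAT DMRs with positive and MAT DMRs with negative mean
#' log2(MIRA/input). An oil (control) and a treated group share the
#' design; optional class-specific shifts model treatment-induced
#' aberrations (e.g. a positive `treated_mat_shift` models gain of
#' methylation at maternally methylated DMRs).
#'
#' @param seed Integer seed.
#' @param n_pat,n_mat Number of PAT and MAT DMRs.
#' @param probes_per_region Probes per DMR.
#' @param pat_mean,mat_mean Class means of the log2 ratio (defaults +1
#'   and -1).
#' @param noise_sd Gaussian noise SD per probe and replicate.
#' @param n_replicates Replicates per group.
#' @param treated_pat_shift,treated_mat_shift Log2 shifts applied to the
#'   treated group at the respective DMR class (defaults 0: null
#'   generation).
#'
#' @return List with `regions` (a [region_set()]), `oil` and `treated`
#'   [methyl_group()]s.
#' @export
simulate_dmr_panel <- function(seed = 1L, n_pat = 10L, n_mat = 10L,
                               probes_per_region = 10L,
                               pat_mean = 1, mat_mean = -1,
                               noise_sd = 0.1, n_replicates = 3L,
                               treated_pat_shift = 0,
                               treated_mat_shift = 0) {
  check_count(n_pat, "n_pat")
  check_count(n_mat, "n_mat")
  check_count(probes_per_region, "probes_per_region")
  check_count(n_replicates, "n_replicates", min = 2L)
  set.seed(seed)

  n_regions <- n_pat + n_mat
  spacing <- 100L
  gap_probes <- 3L
  per_block <- probes_per_region + gap_probes
  n_probes <- n_regions * per_block
  start <- (seq_len(n_probes) - 1L) * spacing
  design <- tibble::tibble(
    probe_id = sprintf("chr1_p%05d", seq_len(n_probes)),
    chrom = "chr1", start = start, end = start + 50L
  )

  class_vec <- c(rep("PAT_DMR", n_pat), rep("MAT_DMR", n_mat))
  first_idx <- (seq_len(n_regions) - 1L) * per_block + 1L
  last_idx <- first_idx + probes_per_region - 1L
  regions <- region_set(
    name = sprintf("%s_%02d", tolower(class_vec),
                   c(seq_len(n_pat), seq_len(n_mat))),
    chrom = "chr1",
    start = design$start[first_idx],
    end = design$end[last_idx],
    class = class_vec
  )

  mu <- numeric(n_probes)
  for (r in seq_len(n_regions)) {
    mu[first_idx[r]:last_idx[r]] <- if (class_vec[r] == "PAT_DMR") pat_mean
                                    else mat_mean
  }
  shift <- numeric(n_probes)
  for (r in seq_len(n_regions)) {
    shift[first_idx[r]:last_idx[r]] <-
      if (class_vec[r] == "PAT_DMR") treated_pat_shift else treated_mat_shift
  }

  make_group <- function(label, mean_vec) {
    vals <- matrix(rnorm(n_probes * n_replicates, mean = mean_vec,
                         sd = noise_sd),
                   nrow = n_probes)
    samples <- tibble::tibble(
      sample_id = sprintf("%s_rep%d", label, seq_len(n_replicates)),
      generation = "G1R", cell_type = "MGC", treatment = label,
      platform = "imprinting_array"
    )
    colnames(vals) <- samples$sample_id
    methyl_group(design, vals, samples)
  }
  list(regions = regions,
       oil = make_group("oil", mu),
       treated = make_group("treated", mu + shift))
}

#' Configuration for the allelotype generator
#'
#' @param seed Integer seed.
#' @param snp_ids Character vector of SNP identifiers.
#' @param true_maternal_fraction Numeric vector in \[0, 1\], recycled to
#'   `snp_ids`; the true maternal share of signal at each SNP.
#' @param skew_ratio Instrument bias, acting multiplicatively on the
#'   maternal:paternal odds (must be > 0; 1 = unbiased).
#' @param noise_sd Gaussian noise SD on the fraction scale; fractions
#'   are clipped to \[0, 1\] after noise.
#' @param n_replicates Replicate measurements per SNP.
#' @param standard_ratios Maternal percentages of the mixing series;
#'   default `c(0, 10, 30, 50, 70, 90, 100)`.
#'
#' @return An `allelotype_config` list.
#' @export
allelotype_config <- function(seed = 1L,
                              snp_ids = paste0("snp", 1:6),
                              true_maternal_fraction = 0.5,
                              skew_ratio = 1,
                              noise_sd = 0.02,
                              n_replicates = 3L,
                              standard_ratios = c(0, 10, 30, 50, 70, 90, 100)) {
  seed <- check_count(seed, "seed", min = 0L)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1L)
  check_number(skew_ratio, "skew_ratio")
  if (skew_ratio <= 0) {
    rlang::abort("`skew_ratio` must be > 0.",
                 class = "methtrace_config_error")
  }
  check_number(noise_sd, "noise_sd")
  f <- rep_len(true_maternal_fraction, length(snp_ids))
  if (any(f < 0 | f > 1)) {
    rlang::abort("`true_maternal_fraction` must lie in [0, 1].",
                 class = "methtrace_config_error")
  }
  if (any(standard_ratios < 0 | standard_ratios > 100)) {
    rlang::abort("`standard_ratios` must lie in [0, 100].",
                 class = "methtrace_config_error")
  }
  structure(
    list(seed = seed, snp_ids = as.character(snp_ids),
         true_maternal_fraction = setNames(f, snp_ids),
         skew_ratio = skew_ratio, noise_sd = noise_sd,
         n_replicates = n_replicates, standard_ratios = standard_ratios),
    class = "allelotype_config"
  )
}

# Observed maternal fraction under odds-scale instrument skew.
apply_skew <- function(f, s) s * f / (s * f + (1 - f))

#' Simulate allelotype measurements and calibration standards
#'
#' The observed maternal fraction is `s*f / (s*f + (1 - f)) + noise`,
#' where `f` is the true fraction and `s` the skew ratio — the skew acts
#' multiplicatively on the maternal:paternal odds, mirroring preferential
#' incorporation of one extension product. Fractions are clipped to
#' \[0, 1\] after noise. The standards table contains the mixing series
#' and a heterozygote (f = 0.5) standard measured under the same skew.
#'
#' @param cfg An [allelotype_config()].
#'
#' @return List with `measurements` (tibble: `snp_id`, `replicate`,
#'   `true_maternal_pct`, `raw_maternal_pct`) and `standards` (tibble:
#'   `snp_id`, `kind` in `mixing_point`/`het_dna`, `true_maternal_pct`,
#'   `observed_maternal_pct`).
#' @export
simulate_allelotypes <- function(cfg) {
  if (!inherits(cfg, "allelotype_config")) cfg <- do.call(allelotype_config, cfg)
  set.seed(cfg$seed)
  s <- cfg$skew_ratio

  noisy_pct <- function(f, n) {
    obs <- apply_skew(f, s) + rnorm(n, 0, cfg$noise_sd)
    100 * pmin(1, pmax(0, obs))
  }

  measurements <- dplyr::bind_rows(purrr::map(cfg$snp_ids, function(id) {
    f <- cfg$true_maternal_fraction[[id]]
    tibble::tibble(
      snp_id = id,
      replicate = seq_len(cfg$n_replicates),
      true_maternal_pct = 100 * f,
      raw_maternal_pct = noisy_pct(f, cfg$n_replicates)
    )
  }))

  standards <- dplyr::bind_rows(
    tibble::tibble(
      snp_id = "mixing_series", kind = "mixing_point",
      true_maternal_pct = cfg$standard_ratios,
      observed_maternal_pct = vapply(cfg$standard_ratios / 100,
                                     function(f) noisy_pct(f, 1), numeric(1))
    ),
    tibble::tibble(
      snp_id = "het_standard", kind = "het_dna", true_maternal_pct = 50,
      observed_maternal_pct = noisy_pct(0.5, 1)
    )
  )
  list(measurements = measurements, standards = standards)
}

#' Simulate a gene-expression experiment with sex and treatment effects
#'
#' Log2-scale expression with per-gene Gaussian baselines, an additive
#' sex effect on a designated gene subset (sex is the dominant axis of
#' variation in germ-cell transcriptomes), treatment effects on a
#' disjoint truth subset, and Gaussian noise. Deterministic under a fixed
#' seed.
#'
#' @param n_genes Number of genes (>= 1).
#' @param design Tibble with one row per sample: `sample_id`, `sex`
#'   (`"F"`/`"M"`), `generation`, `treatment` (`"oil"` = control). Every
#'   sex x generation x treatment combination present needs >= 2
#'   replicates.
#' @param sex_effect_log2 Additive shift in females at sex genes.
#' @param n_sex_genes Size of the sex-affected subset.
#' @param treatment_effect_log2 Additive shift in non-control samples at
#'   treatment genes.
#' @param n_treatment_genes Size of the treatment truth subset (disjoint
#'   from the sex subset).
#' @param noise_sd Noise SD (log2 scale).
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline
#'   distribution.
#' @param seed Integer seed.
#'
#' @return List with `expression` (tibble: `gene_id` + one column per
#'   sample), `truth` (tibble: `gene_id`, `sex_gene`, `treatment_gene`)
#'   and `design`.
#' @export
simulate_expression <- function(n_genes, design,
                                sex_effect_log2 = 0, n_sex_genes = 0L,
                                treatment_effect_log2 = 0,
                                n_treatment_genes = 0L,
                                noise_sd = 0.1,
                                baseline_log2_mean = 6,
                                baseline_log2_sd = 1,
                                seed = 1L) {
  check_count(n_genes, "n_genes")
  design <- tibble::as_tibble(design)
  if (nrow(design) == 0) {
    rlang::abort("`design` must contain at least one sample.",
                 class = "methtrace_config_error")
  }
  needed <- c("sample_id", "sex", "generation", "treatment")
  missing <- setdiff(needed, names(design))
  if (length(missing)) {
    rlang::abort(sprintf("`design` is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  grp <- paste(design$sex, design$generation, design$treatment)
  if (any(table(grp) < 2)) {
    rlang::abort("every sex x generation x treatment group needs >= 2 replicates.",
                 class = "methtrace_config_error")
  }
  if (n_sex_genes + n_treatment_genes > n_genes) {
    rlang::abort("effect gene subsets exceed `n_genes`.",
                 class = "methtrace_config_error")
  }
  set.seed(seed)
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  base <- rnorm(n_genes, baseline_log2_mean, baseline_log2_sd)
  picked <- sample(n_genes, n_sex_genes + n_treatment_genes)
  sex_genes <- picked[seq_len(n_sex_genes)]
  trt_genes <- setdiff(picked, sex_genes)
  is_sex <- seq_len(n_genes) %in% sex_genes
  is_trt <- seq_len(n_genes) %in% trt_genes

  mat <- vapply(seq_len(nrow(design)), function(j) {
    mu <- base +
      sex_effect_log2 * is_sex * (design$sex[j] == "F") +
      treatment_effect_log2 * is_trt * (design$treatment[j] != "oil")
    rnorm(n_genes, mu, noise_sd)
  }, numeric(n_genes))
  colnames(mat) <- design$sample_id

  expression <- dplyr::bind_cols(tibble::tibble(gene_id = gene_id),
                                 tibble::as_tibble(mat))
  truth <- tibble::tibble(gene_id = gene_id, sex_gene = is_sex,
                          treatment_gene = is_trt)
  list(expression = expression, truth = truth, design = design)
}
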