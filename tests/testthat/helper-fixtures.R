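# Small in-code fixtures.

# Uniform one-or-more-chromosome design with unit-spaced probes.
make_design <- function(n, chrom = "chr1", spacing = 100L, len = 50L) {
  per <- rep(n, length.out = length(chrom))
  dplyr::bind_rows(purrr::map2(chrom, per, function(ch, m) {
    start <- (seq_len(m) - 1L) * spacing
    tibble::tibble(probe_id = sprintf("%s_p%04d", ch, seq_len(m)),
                   chrom = ch, start = start, end = start + len)
  }))
}

# methyl_group from a probes-by-replicates matrix.
make_group <- function(design, values, prefix = "s") {
  if (!is.matrix(values)) values <- matrix(values, ncol = 1)
  samples <- tibble::tibble(
    sample_id = sprintf("%s%d", prefix, seq_len(ncol(values))),
    generation = "G1R", cell_type = "MGC", treatment = prefix,
    platform = "test"
  )
  colnames(values) <- samples$sample_id
  methyl_group(design, values, samples)
}

# A values vector realising a given positivity pattern on a background of
# zeros: pattern probes get `high`, which exceeds the 95th percentile as
# long as the pattern covers < 5% of probes.
pattern_values <- function(pattern, n_background = 400, high = 10) {
  v <- c(ifelse(pattern, high, 0), numeric(n_background))
  v
}

# Hit-list tibble for intersection tests.
make_calls <- function(chrom, start, end, direction, test_id = "X") {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 direction = direction, passed = TRUE, test_id = test_id)
}

# Replicate values with an exact mean: mean +/- a fixed spread.
reps_with_mean <- function(mean, spread = 1.5, n = 3) {
  mean + spread * c(-1, 0, 1)[seq_len(n)]
}

# Logical mask of design probes lying inside a simulation's truth regions.
region_probe_mask <- function(sim) {
  tr <- tibble::as_tibble(sim$truth)
  mid <- (sim$design$start + sim$design$end) / 2
  mask <- logical(nrow(sim$design))
  for (i in seq_len(nrow(tr))) {
    mask <- mask | (sim$design$chrom == tr$chrom[i] &
                      mid >= tr$start[i] & mid < tr$end[i])
  }
  mask
}
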