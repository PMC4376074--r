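#' Bundle an array design with replicated methylation signal
#'
#' A `methyl_group` holds the three pieces every array-level operation
#' needs: the ordered probe layout, a probes-by-samples matrix of
#' log2(MIRA/input) values, and per-sample metadata. MIRA (methylated CpG
#' island recovery assay) signal is reported per probe as the log2 ratio of
#' the methylation-enriched fraction over input DNA.
#'
#' @param design Tibble of probe intervals with columns `probe_id`,
#'   `chrom`, `start`, `end` (0-based half-open, sorted by chromosome then
#'   start, non-overlapping within a chromosome).
#' @param values Numeric matrix, one row per probe and one column per
#'   sample; column names must match `samples$sample_id`.
#' @param samples Tibble of sample metadata with at least `sample_id`;
#'   conventional columns are `generation` (`"G1R"`/`"G2R"`), `cell_type`
#'   (`"MGC"`/`"sperm"`/`"FGC"`), `treatment` (`"oil"` or an endocrine
#'   disruptor) and `platform`.
#'
#' @return An object of class `methyl_group`.
#' @export
#' @examples
#' design <- tibble::tibble(
#'   probe_id = paste0("p", 1:4), chrom = "chr1",
#'   start = c(0, 100, 200, 300), end = c(50, 150, 250, 350)
#' )
#' vals <- matrix(rnorm(8), nrow = 4, dimnames = list(NULL, c("s1", "s2")))
#' methyl_group(design, vals, tibble::tibble(sample_id = c("s1", "s2")))
methyl_group <- function(design, values, samples) {
  design <- validate_array_design(design)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != nrow(design)) {
    rlang::abort(sprintf(
      "`values` has %d rows but the design has %d probes.",
      nrow(values), nrow(design)
    ))
  }
  samples <- tibble::as_tibble(samples)
  if (!"sample_id" %in% names(samples)) {
    rlang::abort("`samples` must contain a `sample_id` column.")
  }
  if (anyDuplicated(samples$sample_id)) {
    rlang::abort("duplicate `sample_id` in `samples`.")
  }
  if (ncol(values) != nrow(samples)) {
    rlang::abort("`values` must have one column per sample.")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- samples$sample_id
  } else if (!identical(colnames(values), samples$sample_id)) {
    rlang::abort("column names of `values` must equal `samples$sample_id`.")
  }
  structure(
    list(design = design, values = values, samples = samples),
    class = "methyl_group"
  )
}

#' @export
print.methyl_group <- function(x, ...) {
  cat(sprintf(
    "<methyl_group> %d probes on %d chromosome(s), %d sample(s)\n",
    nrow(x$design), length(unique(x$design$chrom)), nrow(x$samples)
  ))
  meta <- setdiff(names(x$samples), "sample_id")
  for (m in meta) {
    cat(sprintf("  %s: %s\n", m,
                paste(unique(x$samples[[m]]), collapse = ", ")))
  }
  invisible(x)
}

n_replicates <- function(group) nrow(group$samples)

validate_array_design <- function(design) {
  design <- tibble::as_tibble(design)
  needed <- c("probe_id", "chrom", "start", "end")
  missing <- setdiff(needed, names(design))
  if (length(missing)) {
    rlang::abort(sprintf("design is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(design$probe_id)) {
    rlang::abort("duplicate probe_ids in design.")
  }
  if (any(design$end <= design$start)) {
    rlang::abort("probe intervals must satisfy end > start.")
  }
  ord <- order(match(design$chrom, unique(design$chrom)), design$start)
  if (!identical(ord, seq_len(nrow(design)))) {
    rlang::abort("design probes must be sorted by (chrom, start).")
  }
  design
}

# Sanity checks shared by two-group comparisons.
check_same_design <- function(group_a, group_b) {
  if (!isTRUE(all.equal(group_a$design, group_b$design))) {
    rlang::abort("the two groups must share one array design.")
  }
  invisible(TRUE)
}

check_replicated <- function(group, min = 2L) {
  if (n_replicates(group) < min) {
    rlang::abort(sprintf("at least %d replicates are required (got %d).",
                         min, n_replicates(group)))
  }
  invisible(TRUE)
}
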