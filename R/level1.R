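#' Level-1 differential methylation test at consensus peaks
#'
#' Implements the first analysis level of the persistence framework:
#' consensus peaks are called in group A, and at each peak the
#' replicate-averaged signal of A is compared with that of B at the same
#' location. A region is called changed when the mean difference exceeds
#' the 5% fold-change cutoff (|delta log2| >= log2(1.05), i.e. a 1.05-fold
#' increase or 0.95-fold decrease) *and* a two-sided Fisher's exact test
#' on positive-probe counts gives P < 0.05.
#'
#' The Fisher 2x2 table counts probes inside the peak that are positive
#' versus non-positive, classifying each probe per replicate against that
#' replicate's own array-wide threshold and pooling counts over
#' replicates, for group A versus group B. This contingency construction
#' is isolated in one place so alternatives can be swapped.
#'
#' @param group_a,group_b [methyl_group()] objects sharing one array
#'   design, each with >= 2 replicates. Peaks are discovered in
#'   `group_a`.
#' @param test_id Label attached to every call (e.g. `"Test 3"`).
#' @param effect_cutoff Minimum |mean log2 difference|; default
#'   `log2(1.05)`.
#' @param alpha Significance level for the Fisher test; default 0.05.
#' @param min_probes Consensus peaks retaining fewer probes are skipped
#'   with a warning; default 4.
#'
#' @return A `level1_calls` tibble with one row per consensus peak:
#'   `chrom`, `start`, `end`, `n_probes`, `mean_a`, `mean_b`,
#'   `delta_log2` (= mean_a - mean_b), `direction` (`"up"`/`"down"`),
#'   `p_value`, `passed`, `test_id`. Downstream intersection levels use
#'   the `passed` rows.
#' @export
level1_test <- function(group_a, group_b, test_id = "Test",
                        effect_cutoff = log2(1.05), alpha = 0.05,
                        min_probes = 4L) {
  check_same_design(group_a, group_b)
  check_replicated(group_a)
  check_replicated(group_b)

  thr_a <- apply(group_a$values, 2, positivity_threshold)
  thr_b <- apply(group_b$values, 2, positivity_threshold)
  peaks <- consensus_peaks(group_a)

  skipped <- 0L
  rows <- purrr::pmap(peaks, function(chrom, start, end, n_probes,
                                      probe_indices) {
    if (length(probe_indices) < min_probes) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    va <- group_a$values[probe_indices, , drop = FALSE]
    vb <- group_b$values[probe_indices, , drop = FALSE]
    mean_a <- mean(va)
    mean_b <- mean(vb)
    delta <- mean_a - mean_b
    tab <- peak_positivity_table(va, vb, thr_a, thr_b)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    tibble::tibble(
      chrom = chrom, start = start, end = end,
      n_probes = length(probe_indices),
      mean_a = mean_a, mean_b = mean_b, delta_log2 = delta,
      direction = if (delta >= 0) "up" else "down",
      p_value = p,
      passed = abs(delta) >= effect_cutoff && p < alpha
    )
  })
  if (skipped > 0) {
    rlang::warn(sprintf(
      "%s: skipped %d consensus region(s) with fewer than %d probes.",
      test_id, skipped, min_probes
    ))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      n_probes = integer(), mean_a = double(), mean_b = double(),
      delta_log2 = double(), direction = character(), p_value = double(),
      passed = logical()
    )
  }
  out$test_id <- rep(test_id, nrow(out))
  new_level1_calls(out, test_id = test_id, effect_cutoff = effect_cutoff,
                   alpha = alpha)
}

# Pooled positive / non-positive probe counts inside one peak: the single
# place where the Fisher contingency table is constructed.
peak_positivity_table <- function(va, vb, thr_a, thr_b) {
  pos_a <- sum(sweep(va, 2, thr_a, `>`))
  pos_b <- sum(sweep(vb, 2, thr_b, `>`))
  tot_a <- length(va)
  tot_b <- length(vb)
  matrix(c(pos_a, tot_a - pos_a, pos_b, tot_b - pos_b),
         nrow = 2,
         dimnames = list(c("positive", "non_positive"), c("A", "B")))
}

new_level1_calls <- function(tbl, test_id, effect_cutoff, alpha) {
  structure(
    tbl,
    test_id = test_id,
    effect_cutoff = effect_cutoff,
    alpha = alpha,
    class = c("level1_calls", class(tibble::tibble()))
  )
}

#' Run a level-1 comparison in both directions
#'
#' The screening design compares treated versus vehicle control and also
#' control versus treated: peak discovery in A determines where the test
#' looks, so the two orientations are distinct tests and are reported as
#' a pair.
#'
#' @inheritParams level1_test
#' @param treated,control The two [methyl_group()]s.
#' @param labels Character vector of two test labels, first for
#'   treated-as-A.
#'
#' @return Named list of two `level1_calls` tibbles.
#' @export
bidirectional_level1 <- function(treated, control,
                                 labels = c("treated_vs_control",
                                            "control_vs_treated"),
                                 effect_cutoff = log2(1.05), alpha = 0.05,
                                 min_probes = 4L) {
  stopifnot(length(labels) == 2)
  out <- list(
    level1_test(treated, control, test_id = labels[1],
                effect_cutoff = effect_cutoff, alpha = alpha,
                min_probes = min_probes),
    level1_test(control, treated, test_id = labels[2],
                effect_cutoff = effect_cutoff, alpha = alpha,
                min_probes = min_probes)
  )
  names(out) <- labels
  out
}

#' @method glance level1_calls
#' @export
glance.level1_calls <- function(x, ...) {
  tibble::tibble(
    test_id = attr(x, "test_id"),
    n_regions = nrow(x),
    n_passed = sum(x$passed),
    n_up = sum(x$passed & x$direction == "up"),
    n_down = sum(x$passed & x$direction == "down")
  )
}

#' @method tidy level1_calls
#' @export
tidy.level1_calls <- function(x, ...) {
  tibble::as_tibble(x)
}
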