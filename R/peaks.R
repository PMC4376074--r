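#' Array-wide positivity threshold for MIRA signal
#'
#' A probe is scored "positive" when its normalized log2(MIRA/input) value
#' lies strictly above the 95th percentile of all probes on the same
#' array. The percentile uses the sorted-order linear-interpolation
#' convention (R quantile type 7), so on a constant array the threshold
#' equals that constant and no probe is positive.
#'
#' @param values Numeric vector of per-probe log2(MIRA/input) for one
#'   sample, covering the whole array.
#' @param probability Quantile defining positivity; default `0.95`.
#'
#' @return The threshold as a single number. Positivity is
#'   `values > positivity_threshold(values)`.
#' @export
#' @examples
#' positivity_threshold(1:100) # 95.05
positivity_threshold <- function(values, probability = 0.95) {
  if (!is.numeric(values) || length(values) == 0) {
    rlang::abort("`values` must be a non-empty numeric vector.")
  }
  bad <- which(!is.finite(values))
  if (length(bad)) {
    rlang::abort(sprintf(
      "non-finite log2 ratios at probe position(s): %s%s",
      paste(head(bad, 5), collapse = ", "),
      if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else ""
    ))
  }
  unname(stats::quantile(values, probs = probability, type = 7, names = FALSE))
}

#' Call gap-tolerant peaks on one sample
#'
#' Scans each chromosome for maximal runs of positive probes: a peak is
#' four or more positive probes in a row, allowing at most one interior
#' non-positive probe (the "gap"); the gap must be flanked by positive
#' probes and peak boundaries are always positive. Runs never cross
#' chromosome boundaries, and returned peaks are sorted and
#' non-overlapping.
#'
#' @param design Probe layout tibble (`probe_id`, `chrom`, `start`, `end`).
#' @param values Per-probe numeric vector aligned to `design`.
#' @param threshold Positivity threshold; defaults to
#'   [positivity_threshold()] of `values`.
#' @param min_positive Minimum positive probes per peak (default 4).
#' @param max_gaps Maximum interior non-positive probes per peak
#'   (default 1).
#'
#' @return Tibble with one row per peak: `chrom`, `start`, `end` (0-based
#'   half-open, spanning the first to last positive probe),
#'   `n_positive_probes`, and a `probe_indices` list-column of row indices
#'   into `design` spanned by the peak.
#' @export
call_peaks <- function(design, values, threshold = NULL,
                       min_positive = 4L, max_gaps = 1L) {
  design <- validate_array_design(design)
  if (length(values) != nrow(design)) {
    rlang::abort(sprintf(
      "`values` has length %d but the design has %d probes.",
      length(values), nrow(design)
    ))
  }
  threshold <- threshold %||% positivity_threshold(values)
  positive <- values > threshold

  chrom_levels <- unique(design$chrom)
  idx_by_chrom <- split(seq_len(nrow(design)),
                        factor(design$chrom, levels = chrom_levels))
  rows <- purrr::map(chrom_levels, function(ch) {
    ii <- idx_by_chrom[[ch]]
    runs <- scan_gap_runs(positive[ii], min_positive, max_gaps)
    if (!length(runs)) return(NULL)
    purrr::map(runs, function(r) {
      gi <- ii[r[1]:r[2]]
      tibble::tibble(
        chrom = ch,
        start = design$start[gi[1]],
        end = design$end[gi[length(gi)]],
        n_positive_probes = r[3],
        probe_indices = list(gi)
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_positive_probes = integer(),
                          probe_indices = list())
  }
  out
}

# Greedy left-to-right scan: from each positive start not yet consumed,
# extend to the furthest positive probe reachable with <= max_gaps single
# interior non-positives; emit when enough positives accumulate.
scan_gap_runs <- function(p, min_positive = 4L, max_gaps = 1L) {
  n <- length(p)
  out <- list()
  resume <- 1L
  for (s in which(p)) {
    if (s < resume) next
    j <- s
    gaps <- 0L
    k <- s + 1L
    while (k <= n) {
      if (p[k]) {
        j <- k
        k <- k + 1L
      } else if (gaps < max_gaps && k + 1L <= n && p[k + 1L]) {
        gaps <- gaps + 1L
        j <- k + 1L
        k <- k + 2L
      } else {
        break
      }
    }
    npos <- sum(p[s:j])
    if (npos >= min_positive) {
      out[[length(out) + 1L]] <- c(s, j, npos)
      resume <- j + 1L
    }
  }
  out
}

#' Consensus peaks across the replicates of a sample group
#'
#' Peaks are called separately in every replicate (each against its own
#' array-wide threshold); wherever per-replicate peaks mutually overlap by
#' at least 1 bp across *all* replicates, the intersection interval is
#' reported. Intersection (rather than union) is the conservative choice
#' for downstream testing.
#'
#' @param group A [methyl_group()] with at least two replicates.
#' @inheritParams call_peaks
#'
#' @return Tibble of consensus regions: `chrom`, `start`, `end`,
#'   `n_probes` (probes fully inside the intersection) and a
#'   `probe_indices` list-column.
#' @export
consensus_peaks <- function(group, min_positive = 4L, max_gaps = 1L) {
  check_replicated(group, min = 2L)
  design <- group$design
  per_rep <- purrr::map(seq_len(ncol(group$values)), function(r) {
    call_peaks(design, group$values[, r], min_positive = min_positive,
               max_gaps = max_gaps)
  })
  chrom_levels <- unique(design$chrom)
  out <- purrr::map(chrom_levels, function(ch) {
    ir <- purrr::map(per_rep, function(pk) {
      pk <- pk[pk$chrom == ch, , drop = FALSE]
      as_iranges0(pk$start, pk$end)
    })
    common <- Reduce(IRanges::intersect, ir)
    if (length(common) == 0) return(NULL)
    tbl <- iranges_to_tbl0(common, ch)
    in_chr <- which(design$chrom == ch)
    tbl$probe_indices <- purrr::map2(tbl$start, tbl$end, function(s, e) {
      in_chr[design$start[in_chr] >= s & design$end[in_chr] <= e]
    })
    tbl$n_probes <- lengths(tbl$probe_indices)
    tbl[, c("chrom", "start", "end", "n_probes", "probe_indices")]
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_probes = integer(),
                          probe_indices = list())
  }
  out
}
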