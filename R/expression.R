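#' Two-group differential expression contrast
#'
#' Per-gene two-sample, two-sided, equal-variance t-test between two
#' sample sets on log2-scale expression, with the fold change taken from
#' the group means and Benjamini-Hochberg FDR across genes. Cutoff
#' profiles reflect the tiers used when screening germ-cell
#' transcriptomes:
#' * `"strict"`: |fold change| >= 1.5 and FDR q < 0.05;
#' * `"relaxed1"`: |fold change| >= 1.5 and raw P < 0.05;
#' * `"relaxed2"`: |fold change| >= 1.05 and raw P < 0.05.
#'
#' @param expression Tibble with a `gene_id` column (and optionally
#'   `transcript_id`) plus one numeric column per sample.
#' @param samples_a,samples_b Character vectors of sample column names
#'   (>= 2 each).
#' @param profile Cutoff profile name.
#'
#' @return A `de_results` tibble: `gene_id`, `mean_a`, `mean_b`,
#'   `log2_fold_change`, `p_value`, `fdr_q`, `direction`, `passed`.
#' @export
differential_expression <- function(expression, samples_a, samples_b,
                                    profile = c("strict", "relaxed1",
                                                "relaxed2")) {
  profile <- match.arg(profile)
  expression <- tibble::as_tibble(expression)
  if (!"gene_id" %in% names(expression)) {
    rlang::abort("`expression` must contain a `gene_id` column.")
  }
  missing <- setdiff(c(samples_a, samples_b), names(expression))
  if (length(missing)) {
    rlang::abort(sprintf("sample column(s) not found: %s",
                         paste(missing, collapse = ", ")))
  }
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    rlang::abort("each group needs >= 2 samples.")
  }
  a <- as.matrix(expression[, samples_a])
  b <- as.matrix(expression[, samples_b])
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  p <- vapply(seq_len(nrow(a)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    } else {
      stats::t.test(x, y, var.equal = TRUE)$p.value
    }
  }, numeric(1))
  lfc <- mean_a - mean_b
  q <- stats::p.adjust(p, method = "BH")
  out <- tibble::tibble(
    gene_id = expression$gene_id,
    mean_a = mean_a, mean_b = mean_b,
    log2_fold_change = lfc, p_value = p, fdr_q = q,
    direction = ifelse(lfc >= 0, "up", "down"),
    passed = de_passed(lfc, p, q, profile)
  )
  if ("transcript_id" %in% names(expression)) {
    out <- dplyr::bind_cols(
      tibble::tibble(transcript_id = expression$transcript_id), out)
  }
  structure(out, profile = profile,
            class = c("de_results", class(tibble::tibble())))
}

de_passed <- function(lfc, p, q, profile) {
  switch(profile,
    strict = abs(lfc) >= log2(1.5) & q < 0.05,
    relaxed1 = abs(lfc) >= log2(1.5) & p < 0.05,
    relaxed2 = abs(lfc) >= log2(1.05) & p < 0.05,
    rlang::abort(sprintf("unknown cutoff profile '%s'.", profile))
  )
}

#' @method glance de_results
#' @export
glance.de_results <- function(x, ...) {
  tibble::tibble(profile = attr(x, "profile"), n_genes = nrow(x),
                 n_passed = sum(x$passed),
                 n_up = sum(x$passed & x$direction == "up"),
                 n_down = sum(x$passed & x$direction == "down"))
}

#' @method tidy de_results
#' @export
tidy.de_results <- function(x, ...) tibble::as_tibble(x)

#' Overlap and direction analysis of two differential-expression lists
#'
#' Counts the unique transcripts that pass the cutoff profile in both a
#' first-generation and a second-generation comparison, how many of them
#' changed in the same direction, and whether common changes are enriched
#' for concordant or discordant directions (via
#' [direction_enrichment()]). Multiple probes per transcript are
#' collapsed to the best (smallest) P value before overlap counting.
#'
#' @param de_x,de_y `de_results` from [differential_expression()] over
#'   the same transcript universe.
#' @param profile If supplied, `passed` is recomputed under this profile
#'   for both lists; otherwise each list's own flags are used.
#'
#' @return An `overlap_report` list: `n_common`, `n_same_direction`,
#'   `common` (tibble of shared transcripts with both directions),
#'   `enrichment` (a `direction_enrichment`), `profile`.
#' @export
g1_g2_overlap <- function(de_x, de_y, profile = NULL) {
  tx <- collapse_transcripts(de_x, profile)
  ty <- collapse_transcripts(de_y, profile)
  if (length(intersect(tx$transcript_id, ty$transcript_id)) == 0) {
    rlang::abort("the two lists share no transcripts (disjoint universes).")
  }
  common <- dplyr::inner_join(
    tx[tx$passed, c("transcript_id", "direction")],
    ty[ty$passed, c("transcript_id", "direction")],
    by = "transcript_id", suffix = c("_x", "_y")
  )
  common$same_direction <- common$direction_x == common$direction_y
  tab <- table(factor(common$direction_x, levels = c("down", "up")),
               factor(common$direction_y, levels = c("down", "up")))
  enr <- direction_enrichment(nrow(common), sum(common$same_direction),
                              as.matrix(tab))
  structure(
    list(n_common = nrow(common),
         n_same_direction = sum(common$same_direction),
         common = tibble::as_tibble(common),
         enrichment = enr,
         profile = profile %||% attr(de_x, "profile")),
    class = "overlap_report"
  )
}

collapse_transcripts <- function(de, profile = NULL) {
  de <- tibble::as_tibble(de)
  if (!"transcript_id" %in% names(de)) de$transcript_id <- de$gene_id
  if (!is.null(profile)) {
    de$passed <- de_passed(de$log2_fold_change, de$p_value, de$fdr_q,
                           profile)
  }
  de <- de[order(de$p_value), , drop = FALSE]
  de[!duplicated(de$transcript_id), , drop = FALSE]
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "<overlap_report> %d common transcript(s), %d (%.0f%%) in the same direction\n",
    x$n_common, x$n_same_direction,
    if (x$n_common > 0) 100 * x$n_same_direction / x$n_common else 0
  ))
  invisible(x)
}

#' @method tidy overlap_report
#' @export
tidy.overlap_report <- function(x, ...) x$common

#' @method glance overlap_report
#' @export
glance.overlap_report <- function(x, ...) {
  tibble::tibble(
    profile = x$profile %||% NA_character_,
    n_common = x$n_common,
    n_same_direction = x$n_same_direction,
    same_direction_fraction = if (x$n_common > 0) x$n_same_direction / x$n_common else NA_real_,
    binomial_p = x$enrichment$binomial_p
  )
}
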