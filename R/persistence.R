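#' Common changes between two differential-call lists (levels 2 and 3)
#'
#' Two passed calls are "common" when their regions overlap by at least
#' 1 bp; overlapping pairs are reported as the intersection interval
#' together with the direction of change in each input and whether the
#' directions agree. Level 2 pairs the same comparison across generations
#' (G1R vs G2R); level 3 pairs it across germ-cell stages (prospermatogonia
#' vs sperm); the arithmetic is identical.
#'
#' @param calls_x,calls_y `level1_calls` tibbles (or any tibble with
#'   `chrom`, `start`, `end`, `direction` and a logical `passed` column;
#'   rows with `passed == FALSE` are dropped first).
#' @param level Analysis level label, 2 or 3.
#'
#' @return A `persistence_report`: list with `level`, `input_test_ids`,
#'   `common` (tibble of intersection regions with per-input directions
#'   and `same_direction`), `n_common` and `n_same_direction`.
#' @export
intersect_calls <- function(calls_x, calls_y, level = 2) {
  hx <- passed_calls(calls_x)
  hy <- passed_calls(calls_y)
  ids <- c(call_label(calls_x), call_label(calls_y))
  common <- overlap_pairs(hx, hy)
  new_persistence_report(level = level, input_test_ids = ids,
                         common = common)
}

passed_calls <- function(calls) {
  tbl <- tibble::as_tibble(calls)
  if ("passed" %in% names(tbl)) tbl <- tbl[tbl$passed, , drop = FALSE]
  tbl
}

call_label <- function(calls) {
  attr(calls, "test_id") %||%
    (if ("test_id" %in% names(calls) && nrow(calls)) calls$test_id[1] else NA_character_)
}

# All-pairs >=1 bp overlaps between two hit lists, merged to the
# intersection interval.
overlap_pairs <- function(hx, hy) {
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), direction_x = character(),
                          direction_y = character(),
                          same_direction = logical())
  if (nrow(hx) == 0 || nrow(hy) == 0) return(empty)
  out <- purrr::map(intersect(unique(hx$chrom), unique(hy$chrom)), function(ch) {
    xs <- hx[hx$chrom == ch, , drop = FALSE]
    ys <- hy[hy$chrom == ch, , drop = FALSE]
    hits <- IRanges::findOverlaps(as_iranges0(xs$start, xs$end),
                                  as_iranges0(ys$start, ys$end))
    if (length(hits) == 0) return(NULL)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    tibble::tibble(
      chrom = ch,
      start = pmax(xs$start[qi], ys$start[si]),
      end = pmin(xs$end[qi], ys$end[si]),
      direction_x = xs$direction[qi],
      direction_y = ys$direction[si],
      same_direction = xs$direction[qi] == ys$direction[si]
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) empty else out
}

#' Level-4 test for true transgenerational inheritance
#'
#' A region qualifies only when it overlaps passed calls in all four
#' germline samples: an immediate effect in G1R prospermatogonia that is
#' maintained into G1R sperm, G2R prospermatogonia and G2R sperm, and so
#' could reach the third-generation soma. `same_direction` requires an
#' identical direction of change in all four lists.
#'
#' @param mgc_g1r,sperm_g1r,mgc_g2r,sperm_g2r `level1_calls` for the four
#'   germline samples, from the same platform.
#'
#' @return A `persistence_report` with level 4; `common` carries one
#'   direction column per input.
#' @export
tgi_level4 <- function(mgc_g1r, sperm_g1r, mgc_g2r, sperm_g2r) {
  inputs <- list(mgc_g1r = mgc_g1r, sperm_g1r = sperm_g1r,
                 mgc_g2r = mgc_g2r, sperm_g2r = sperm_g2r)
  if (any(vapply(inputs, is.null, logical(1)))) {
    rlang::abort("all four call lists are required for the level-4 test.")
  }
  ids <- vapply(inputs, call_label, character(1))
  hits <- purrr::map(inputs, passed_calls)

  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(),
                          direction_mgc_g1r = character(),
                          direction_sperm_g1r = character(),
                          direction_mgc_g2r = character(),
                          direction_sperm_g2r = character(),
                          same_direction = logical())
  if (any(vapply(hits, nrow, integer(1)) == 0)) {
    return(new_persistence_report(4, ids, empty))
  }

  chroms <- Reduce(intersect, purrr::map(hits, ~ unique(.x$chrom)))
  rows <- purrr::map(chroms, function(ch) {
    per <- purrr::map(hits, ~ .x[.x$chrom == ch, , drop = FALSE])
    ir <- purrr::map(per, ~ as_iranges0(.x$start, .x$end))
    common <- Reduce(IRanges::intersect, ir)
    if (length(common) == 0) return(NULL)
    tbl <- iranges_to_tbl0(common, ch)
    dirs <- purrr::map(per, function(h) {
      ov <- IRanges::findOverlaps(as_iranges0(tbl$start, tbl$end),
                                  as_iranges0(h$start, h$end),
                                  select = "first")
      h$direction[ov]
    })
    tbl$direction_mgc_g1r <- dirs$mgc_g1r
    tbl$direction_sperm_g1r <- dirs$sperm_g1r
    tbl$direction_mgc_g2r <- dirs$mgc_g2r
    tbl$direction_sperm_g2r <- dirs$sperm_g2r
    dm <- do.call(cbind, dirs)
    tbl$same_direction <- apply(dm, 1, function(d) length(unique(d)) == 1)
    tbl
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- empty
  new_persistence_report(4, ids, out)
}

new_persistence_report <- function(level, input_test_ids, common) {
  structure(
    list(
      level = level,
      input_test_ids = input_test_ids,
      common = common,
      n_common = nrow(common),
      n_same_direction = sum(common$same_direction)
    ),
    class = "persistence_report"
  )
}

#' @export
print.persistence_report <- function(x, ...) {
  cat(sprintf("<persistence_report> level %s: %d common hit(s), %d in the same direction\n",
              x$level, x$n_common, x$n_same_direction))
  cat("  inputs:", paste(x$input_test_ids, collapse = " / "), "\n")
  invisible(x)
}

#' @method tidy persistence_report
#' @export
tidy.persistence_report <- function(x, ...) x$common

#' @method glance persistence_report
#' @export
glance.persistence_report <- function(x, ...) {
  tibble::tibble(level = x$level, n_common = x$n_common,
                 n_same_direction = x$n_same_direction)
}

#' Direction enrichment among common changes
#'
#' Given the 2x2 table of up/down membership of common hits in two
#' comparisons, computes for every cell the fold enrichment
#' (observed / expected under row-column independence) with a two-sided
#' Fisher's exact P value, plus an exact binomial test of the
#' same-direction count against the chance rate of 0.5. Used to show, for
#' example, that common expression changes between generations occur
#' predominantly in *opposite* directions.
#'
#' @param n_common,n_same Total common hits and how many changed in the
#'   same direction.
#' @param table 2x2 matrix of counts; rows index the direction
#'   (down/up) in the first comparison, columns in the second.
#'
#' @return A `direction_enrichment` list: `cells` tibble (one row per
#'   cell with `observed`, `expected`, `fold_enrichment`, `fisher_p`),
#'   `binomial_p`, `n_common`, `n_same`.
#' @export
#' @examples
#' direction_enrichment(50, 40, matrix(c(20, 5, 5, 20), 2))
direction_enrichment <- function(n_common, n_same, table) {
  if (n_same > n_common) {
    rlang::abort("`n_same` cannot exceed `n_common`.")
  }
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0)) {
    rlang::abort("`table` must be a 2x2 matrix of non-negative counts.")
  }
  if (is.null(dimnames(table))) {
    dimnames(table) <- list(c("down", "up"), c("down", "up"))
  }
  total <- sum(table)
  expected <- if (total > 0) outer(rowSums(table), colSums(table)) / total
              else table * NA_real_
  fisher_p <- if (total > 0) stats::fisher.test(table)$p.value else NA_real_
  cells <- tibble::tibble(
    direction_1 = rep(rownames(table), times = 2),
    direction_2 = rep(colnames(table), each = 2),
    observed = as.vector(table),
    expected = as.vector(expected),
    fold_enrichment = as.vector(table / expected),
    fisher_p = fisher_p
  )
  binom_p <- if (n_common > 0) {
    stats::binom.test(n_same, n_common, p = 0.5)$p.value
  } else NA_real_
  structure(
    list(cells = cells, binomial_p = binom_p,
         n_common = n_common, n_same = n_same),
    class = "direction_enrichment"
  )
}

#' @export
print.direction_enrichment <- function(x, ...) {
  cat(sprintf("<direction_enrichment> %d/%d same direction (binomial P = %.3g)\n",
              x$n_same, x$n_common, x$binomial_p))
  print(x$cells)
  invisible(x)
}

#' @method tidy direction_enrichment
#' @export
tidy.direction_enrichment <- function(x, ...) x$cells

#' @method glance direction_enrichment
#' @export
glance.direction_enrichment <- function(x, ...) {
  tibble::tibble(n_common = x$n_common, n_same = x$n_same,
                 same_direction_fraction = if (x$n_common > 0) x$n_same / x$n_common else NA_real_,
                 binomial_p = x$binomial_p,
                 fisher_p = x$cells$fisher_p[1])
}
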