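#' Read and write probe-level methylation tables
#'
#' Tab-delimited layout: `probe_id`, `chrom`, `start`, `end`, then one
#' numeric column per sample. Values survive a write/read round trip to
#' within 1e-9 (integers bit-exactly).
#'
#' @param group A [methyl_group()].
#' @param path File path.
#' @param samples Optional sample-metadata tibble to attach on read; by
#'   default minimal metadata (just `sample_id`) is created from the
#'   column names.
#'
#' @return `write_probe_table()` returns `path` invisibly;
#'   `read_probe_table()` returns a [methyl_group()].
#' @export
write_probe_table <- function(group, path) {
  tbl <- dplyr::bind_cols(group$design,
                          tibble::as_tibble(group$values))
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_probe_table
#' @export
read_probe_table <- function(path, samples = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("probe_id", "chrom", "start", "end")
  missing <- setdiff(needed, names(tbl))
  if (length(missing)) {
    rlang::abort(sprintf("probe table %s is missing column(s): %s",
                         path, paste(missing, collapse = ", ")))
  }
  design <- tbl[, needed]
  design$start <- as.integer(design$start)
  design$end <- as.integer(design$end)
  value_cols <- setdiff(names(tbl), needed)
  values <- as.matrix(tbl[, value_cols])
  if (is.null(samples)) {
    samples <- tibble::tibble(sample_id = value_cols)
  }
  methyl_group(design, values, samples)
}

#' Read and write region sets as BED
#'
#' Regions are stored 0-based half-open in BED form: chrom, start, end,
#' name, score (0), strand (`.`), plus a seventh column carrying the
#' region class. Files with fewer columns read back with class
#' `"control"`.
#'
#' @param regions A [region_set()].
#' @param path File path.
#'
#' @return `write_region_bed()` returns `path` invisibly;
#'   `read_region_bed()` returns a [region_set()].
#' @export
write_region_bed <- function(regions, path) {
  tbl <- tibble::as_tibble(regions)
  out <- tibble::tibble(chrom = tbl$chrom, start = tbl$start,
                        end = tbl$end, name = tbl$name, score = 0L,
                        strand = ".", class = tbl$class)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_region_bed
#' @export
read_region_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(region_set(character(0), character(0), integer(0), integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  bad <- which(n < 4)
  if (length(bad)) {
    rlang::abort(sprintf("malformed BED line(s): %s",
                         paste(bad, collapse = ", ")),
                 class = "methtrace_format_error")
  }
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3)))
  name <- vapply(fields, `[`, character(1), 4)
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad)) {
    rlang::abort(sprintf("invalid coordinates on line(s): %s",
                         paste(bad, collapse = ", ")),
                 class = "methtrace_format_error")
  }
  cls <- vapply(fields, function(f) if (length(f) >= 7) f[7] else "control",
                character(1))
  region_set(name, chrom, start, end, cls)
}

#' Read and write differential calls as BED
#'
#' Differential-methylation calls travel as BED intervals with the test
#' label in the name column, `delta_log2` in the score column and the
#' direction encoded as the strand (`+` up, `-` down). An empty call list
#' writes a valid BED containing only a header comment.
#'
#' @param calls A `level1_calls` tibble (or compatible).
#' @param path File path.
#' @param passed_only Write only passed calls (default TRUE).
#'
#' @return `write_calls_bed()` returns `path` invisibly;
#'   `read_calls_bed()` returns a tibble with `chrom`, `start`, `end`,
#'   `test_id`, `delta_log2`, `direction`, `passed`.
#' @export
write_calls_bed <- function(calls, path, passed_only = TRUE) {
  tbl <- tibble::as_tibble(calls)
  if (passed_only && "passed" %in% names(tbl)) tbl <- tbl[tbl$passed, ]
  header <- "# methtrace differential calls: chrom start end test_id delta_log2 strand(direction)"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(tbl)) {
    out <- sprintf("%s\t%d\t%d\t%s\t%.10g\t%s", tbl$chrom,
                   as.integer(tbl$start), as.integer(tbl$end),
                   tbl$test_id, tbl$delta_log2,
                   ifelse(tbl$direction == "up", "+", "-"))
    writeLines(out, con)
  }
  invisible(path)
}

#' @rdname write_calls_bed
#' @export
read_calls_bed <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#")
  lines <- lines[keep]
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), test_id = character(),
                          delta_log2 = double(), direction = character(),
                          passed = logical())
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 6)
  if (length(bad)) {
    rlang::abort(sprintf("malformed call line(s): %s",
                         paste(which(keep)[bad], collapse = ", ")),
                 class = "methtrace_format_error")
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad)) {
    rlang::abort(sprintf("invalid coordinates on line(s): %s",
                         paste(which(keep)[bad], collapse = ", ")),
                 class = "methtrace_format_error")
  }
  tibble::tibble(
    chrom = vapply(fields, `[`, character(1), 1),
    start = start, end = end,
    test_id = vapply(fields, `[`, character(1), 4),
    delta_log2 = as.numeric(vapply(fields, `[`, character(1), 5)),
    direction = ifelse(vapply(fields, `[`, character(1), 6) == "+",
                       "up", "down"),
    passed = TRUE
  )
}

#' Read and write allelotype measurement tables
#'
#' Plain tab-delimited tables with a `maternal_pct`-style percentage
#' column validated to \[0, 100\] on read.
#'
#' @param measurements Tibble of measurements.
#' @param path File path.
#' @param pct_cols Columns to validate as percentages; defaults to every
#'   column ending in `_pct`.
#'
#' @return `write_allelotype_table()` returns `path` invisibly;
#'   `read_allelotype_table()` a tibble.
#' @export
write_allelotype_table <- function(measurements, path) {
  readr::write_tsv(tibble::as_tibble(measurements), path)
  invisible(path)
}

#' @rdname write_allelotype_table
#' @export
read_allelotype_table <- function(path, pct_cols = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  pct_cols <- pct_cols %||% grep("_pct$", names(tbl), value = TRUE)
  for (col in pct_cols) {
    bad <- which(!is.finite(tbl[[col]]) | tbl[[col]] < 0 | tbl[[col]] > 100)
    if (length(bad)) {
      rlang::abort(sprintf("column %s out of [0, 100] on data line(s): %s",
                           col, paste(bad, collapse = ", ")),
                   class = "methtrace_format_error")
    }
  }
  tbl
}

#' Simulation configuration round trip through YAML
#'
#' @param cfg A [methylome_config()] or [allelotype_config()].
#' @param path File path.
#'
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   the reconstructed config object (the stored `type` field selects
#'   the constructor).
#' @export
write_config <- function(cfg, path) {
  type <- class(cfg)[1]
  yaml::write_yaml(c(list(type = type),
                     lapply(unclass(cfg), function(x) {
                       if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
                     })),
                   path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  type <- raw$type %||% rlang::abort("config file lacks a `type` field.")
  raw$type <- NULL
  switch(type,
    methylome_config = do.call(methylome_config, raw),
    allelotype_config = {
      if (is.list(raw$true_maternal_fraction)) {
        raw$true_maternal_fraction <- unlist(raw$true_maternal_fraction)
        raw$snp_ids <- names(raw$true_maternal_fraction)
      }
      do.call(allelotype_config, raw)
    },
    rlang::abort(sprintf("unknown config type '%s'.", type))
  )
}

#' Write an analysis report as JSON
#'
#' Persistence and overlap reports serialise with their counts and
#' common-region tables; anything else is serialised as-is.
#'
#' @param report A `persistence_report`, `overlap_report`, or list.
#' @param path File path.
#'
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- if (inherits(report, "persistence_report")) {
    list(level = report$level, input_test_ids = report$input_test_ids,
         n_common = report$n_common,
         n_same_direction = report$n_same_direction,
         common = report$common)
  } else if (inherits(report, "overlap_report")) {
    list(profile = report$profile, n_common = report$n_common,
         n_same_direction = report$n_same_direction,
         common = report$common)
  } else {
    report
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Experimental design bookkeeping counts
#'
#' Derives the headline sizes of a multigeneration allelotyping screen
#' from its factor structure:
#' * `"conditions"` = organs x EDs x SNPs (e.g. 7 x 3 x 18 = 378);
#' * `"data_points"` = individuals_per_group x
#'   treatment_groups_including_vehicle x organs x snps
#'   (e.g. 3 x 4 x 7 x 56 = 4,704);
#' * `"level1_tests"` = platforms x sum over cell types of
#'   (generations x EDs tested in that cell type) x
#'   directions_per_comparison (e.g. 2 x (2x3 + 2x1) x 2 = 32).
#'
#' @param spec Named list of factor counts; see [design_spec()] for the
#'   defaults matching a two-generation, two-platform screen.
#' @param quantity One of `"conditions"`, `"data_points"`,
#'   `"level1_tests"`.
#'
#' @return A single integer count.
#' @export
#' @examples
#' design_counts(design_spec(organs = 7, eds = 3, snps = 18), "conditions")
design_counts <- function(spec, quantity = c("conditions", "data_points",
                                             "level1_tests")) {
  quantity <- match.arg(quantity)
  need <- switch(quantity,
    conditions = c("organs", "eds", "snps"),
    data_points = c("individuals_per_group",
                    "treatment_groups_including_vehicle", "organs", "snps"),
    level1_tests = c("platforms", "generations", "eds_per_cell_type",
                     "directions_per_comparison")
  )
  missing <- setdiff(need, names(spec))
  if (length(missing)) {
    rlang::abort(sprintf("design spec is missing field(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "methtrace_design_error")
  }
  for (f in setdiff(need, "eds_per_cell_type")) check_count(spec[[f]], f)
  switch(quantity,
    conditions = spec$organs * spec$eds * spec$snps,
    data_points = spec$individuals_per_group *
      spec$treatment_groups_including_vehicle * spec$organs * spec$snps,
    level1_tests = spec$platforms *
      sum(spec$generations * spec$eds_per_cell_type) *
      spec$directions_per_comparison
  )
}

#' @rdname design_counts
#' @param organs,eds,snps,individuals_per_group,treatment_groups_including_vehicle,platforms,generations,directions_per_comparison
#'   Factor level counts.
#' @param eds_per_cell_type Named numeric vector: EDs tested per cell
#'   type (default 3 for prospermatogonia, 1 for sperm).
#' @export
design_spec <- function(organs = 7L, eds = 3L, snps = 18L,
                        individuals_per_group = 3L,
                        treatment_groups_including_vehicle = 4L,
                        platforms = 2L, generations = 2L,
                        eds_per_cell_type = c(MGC = 3L, sperm = 1L),
                        directions_per_comparison = 2L) {
  list(organs = organs, eds = eds, snps = snps,
       individuals_per_group = individuals_per_group,
       treatment_groups_including_vehicle = treatment_groups_including_vehicle,
       platforms = platforms, generations = generations,
       eds_per_cell_type = eds_per_cell_type,
       directions_per_comparison = directions_per_comparison)
}
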