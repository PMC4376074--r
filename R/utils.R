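# Round half away from zero at `digits` decimals; base round() is
# round-half-even, which would turn 0.05/56 into 0.0008 instead of 0.0009.
round_half_up <- function(x, digits = 0) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

# 1-based closed IRanges from 0-based half-open genomic coordinates.
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

iranges_to_tbl0 <- function(ir, chrom) {
  tibble::tibble(
    chrom = chrom,
    start = IRanges::start(ir) - 1L,
    end = IRanges::end(ir)
  )
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    rlang::abort(
      sprintf("`%s` must be a single integer >= %d (got %s).", name, min,
              paste(format(x), collapse = ", ")),
      class = "methtrace_config_error"
    )
  }
  invisible(as.integer(x))
}

check_number <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name),
                 class = "methtrace_config_error")
  }
  invisible(as.numeric(x))
}
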