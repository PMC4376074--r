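#' Odds-scale skew correction of percent-maternal measurements
#'
#' Primer-extension allelotyping reads out the percentage of a SNP's
#' signal carried by the maternal allele, but the instrument incorporates
#' the two extended products with unequal efficiency. A known 50:50
#' standard (a true heterozygote for DNA, an equimolar RNA mix for
#' transcription) measured under the same skew calibrates the assay:
#' observed maternal:paternal odds are divided by the standard's odds and
#' mapped back to a percentage. This is the unique monotone correction
#' that fixes both endpoints (0 and 100 pass through unchanged) and maps
#' the standard itself to exactly 50.
#'
#' @param raw_maternal_pct Numeric vector of raw percent-maternal values
#'   in \[0, 100\].
#' @param standard_observed_pct Observed percent-maternal of the 50:50
#'   standard, strictly inside (0, 100).
#'
#' @return Corrected percent-maternal values.
#' @export
#' @examples
#' skew_correct(75, 200 / 3) # standard measured at 66.67 -> corrected 60
skew_correct <- function(raw_maternal_pct, standard_observed_pct) {
  check_number(standard_observed_pct, "standard_observed_pct")
  if (standard_observed_pct <= 0 || standard_observed_pct >= 100) {
    rlang::abort(
      "degenerate calibration standard: observed percent must be strictly between 0 and 100.",
      class = "methtrace_calibration_error"
    )
  }
  if (any(!is.finite(raw_maternal_pct)) ||
      any(raw_maternal_pct < 0 | raw_maternal_pct > 100)) {
    rlang::abort("`raw_maternal_pct` must lie in [0, 100].")
  }
  std_odds <- standard_observed_pct / (100 - standard_observed_pct)
  out <- raw_maternal_pct
  interior <- raw_maternal_pct > 0 & raw_maternal_pct < 100
  odds <- (raw_maternal_pct[interior] / (100 - raw_maternal_pct[interior])) /
    std_odds
  out[interior] <- 100 * odds / (1 + odds)
  out
}

#' Mixing-series linearity check
#'
#' Regresses corrected observations from an allele mixing series (default
#' design 0:100, 10:90, 30:70, 50:50, 70:30, 90:10, 100:0 maternal
#' percentages) on the true input percentages by ordinary least squares.
#' A well-calibrated assay gives slope 1, intercept 0, R-squared 1; QC
#' passes when R-squared meets the threshold.
#'
#' @param true_pct True maternal percentages of the mixing points (at
#'   least 3 distinct values).
#' @param observed_pct Corrected observed percentages, same length.
#' @param r2_threshold Minimum R-squared for QC pass; default 0.95.
#'
#' @return A `methtrace_linearity` object with `slope`, `intercept`,
#'   `r_squared` (NA when the observations are constant), `qc_pass`, and
#'   the underlying `lm` fit. Constant observations give an undefined
#'   R-squared and a QC failure.
#' @export
linearity_check <- function(true_pct, observed_pct, r2_threshold = 0.95) {
  if (length(true_pct) != length(observed_pct)) {
    rlang::abort("`true_pct` and `observed_pct` must have equal length.")
  }
  if (length(unique(true_pct)) < 3) {
    rlang::abort("at least 3 distinct mixing points are required.")
  }
  fit <- stats::lm(observed_pct ~ true_pct)
  if (stats::sd(observed_pct) == 0) {
    r2 <- NA_real_
    qc <- FALSE
  } else {
    ss_tot <- sum((observed_pct - mean(observed_pct))^2)
    r2 <- 1 - sum(stats::residuals(fit)^2) / ss_tot
    qc <- is.finite(r2) && r2 >= r2_threshold
  }
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, qc_pass = qc, fit = fit,
         r2_threshold = r2_threshold),
    class = "methtrace_linearity"
  )
}

#' @export
print.methtrace_linearity <- function(x, ...) {
  cat(sprintf(
    "<linearity check> slope %.4f, intercept %.4f, R^2 %s -> QC %s\n",
    x$slope, x$intercept,
    if (is.na(x$r_squared)) "undefined" else sprintf("%.4f", x$r_squared),
    if (x$qc_pass) "pass" else "FAIL"
  ))
  invisible(x)
}

#' @method tidy methtrace_linearity
#' @export
tidy.methtrace_linearity <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @method glance methtrace_linearity
#' @export
glance.methtrace_linearity <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, qc_pass = x$qc_pass)
}

#' Bonferroni-corrected significance threshold
#'
#' Divides the family-wise alpha by the number of tests in the declared
#' family and reports it rounded half-up to four decimals, the precision
#' used when quoting thresholds such as 0.05/28 = 0.0018. The unrounded
#' value is also returned and is what internal comparisons use.
#'
#' @param alpha Family-wise error rate, in (0, 1); default 0.05.
#' @param m Number of tests in the family (>= 1).
#'
#' @return List with `threshold` (rounded to 4 decimals, half-up) and
#'   `exact` (= alpha / m).
#' @export
#' @examples
#' bonferroni_alpha(0.05, 28)$threshold # 0.0018
bonferroni_alpha <- function(alpha = 0.05, m) {
  check_count(m, "m", min = 1L)
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) {
    rlang::abort("`alpha` must be strictly between 0 and 1.")
  }
  exact <- alpha / m
  list(threshold = round_half_up(exact, 4), exact = exact)
}

#' Classify baseline parental bias of a control measurement
#'
#' Applies the 80% cutoff to the vehicle-treated (control) mean: at least
#' 80% maternal signal is maternal-specific (`MAT`), at most 20% is
#' paternal-specific (`PAT`), anything between indicates no allele
#' specificity (`NO`, i.e. erased or biallelic). The boundaries are
#' inclusive.
#'
#' @param control_mean_maternal_pct Numeric vector in \[0, 100\].
#'
#' @return Character vector of `"MAT"`, `"PAT"`, `"NO"`.
#' @export
#' @examples
#' classify_baseline(c(100, 5, 73)) # "MAT" "PAT" "NO"
classify_baseline <- function(control_mean_maternal_pct) {
  x <- control_mean_maternal_pct
  if (any(!is.finite(x)) || any(x < 0 | x > 100)) {
    rlang::abort("`control_mean_maternal_pct` must lie in [0, 100].")
  }
  ifelse(x >= 80, "MAT", ifelse(x <= 20, "PAT", "NO"))
}

#' Group comparison of allele-specific measurements
#'
#' For every SNP x organ stratum, compares each treatment against the
#' vehicle control with a two-sample, two-sided, equal-variance Student's
#' t-test on the percent-maternal replicate values. Rows report the group
#' means, the difference (treated minus control), the treated-group SD,
#' the P value, a change flag (`gt5` when |difference| > 5 and P < 0.05,
#' `gt10` when additionally |difference| > 10, otherwise `none`), the
#' baseline parental-bias class of the control mean, and whether the P
#' value clears the Bonferroni threshold for the declared family size.
#'
#' @param measurements Tibble with columns `snp_id`, `organ`,
#'   `treatment`, `replicate`, `maternal_pct` (optionally `assay`, kept
#'   as a grouping key).
#' @param family_size Number of tests `m` in the Bonferroni family.
#' @param alpha Per-test significance level; default 0.05.
#' @param control Label of the vehicle-control treatment; default
#'   `"oil"`.
#'
#' @return Tibble with one row per SNP x organ x treatment comparison.
#' @export
compare_groups <- function(measurements, family_size, alpha = 0.05,
                           control = "oil") {
  measurements <- tibble::as_tibble(measurements)
  needed <- c("snp_id", "organ", "treatment", "maternal_pct")
  missing <- setdiff(needed, names(measurements))
  if (length(missing)) {
    rlang::abort(sprintf("`measurements` is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  bonf <- bonferroni_alpha(alpha, family_size)
  keys <- intersect(c("assay", "snp_id", "organ"), names(measurements))
  strata <- dplyr::group_split(dplyr::group_by(
    measurements, dplyr::across(dplyr::all_of(keys))
  ))
  rows <- purrr::map(strata, function(st) {
    ctrl <- st$maternal_pct[st$treatment == control]
    label <- paste(unlist(st[1, keys]), collapse = "/")
    if (length(ctrl) == 0) {
      rlang::abort(sprintf("stratum %s has no '%s' control group.",
                           label, control),
                   class = "methtrace_design_error")
    }
    if (length(ctrl) < 2) {
      rlang::abort(sprintf("stratum %s needs >= 2 control replicates.", label))
    }
    purrr::map(setdiff(unique(st$treatment), control), function(trt) {
      y <- st$maternal_pct[st$treatment == trt]
      if (length(y) < 2) {
        rlang::abort(sprintf("stratum %s/%s needs >= 2 replicates.",
                             label, trt))
      }
      if (stats::sd(y) == 0 && stats::sd(ctrl) == 0) {
        p <- if (isTRUE(all.equal(mean(y), mean(ctrl)))) 1 else 0
      } else {
        p <- stats::t.test(y, ctrl, var.equal = TRUE)$p.value
      }
      diff <- mean(y) - mean(ctrl)
      flag <- if (abs(diff) > 10 && p < alpha) "gt10"
              else if (abs(diff) > 5 && p < alpha) "gt5"
              else "none"
      out <- st[1, keys]
      out$treatment <- trt
      out$n_control <- length(ctrl)
      out$n_treated <- length(y)
      out$mean_control <- mean(ctrl)
      out$mean_treated <- mean(y)
      out$difference_pct <- diff
      out$sd_pct <- stats::sd(y)
      out$p_value <- p
      out$flag <- flag
      out$baseline <- classify_baseline(mean(ctrl))
      out$bonferroni_significant <- p < bonf$exact
      out
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}
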