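#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all reported percentages and
#' Z statistics so that displayed values match the usual convention of
#' summary tables (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Relative percentage decrease between paired endorsement rates
#'
#' The headline effect measure for clinical-check gating:
#' `100 * (pct_without - pct_with) / pct_without`, i.e. the decrease in the
#' endorsement rate relative to the ungated rate. Following the reporting
#' convention of the source tables, it is computed on the percentages as
#' printed (one decimal) and reported to one decimal, half-up; pass
#' `digits = NULL` for the unrounded value.
#'
#' @param pct_without endorsement percentage without clinical checks; must
#'   be non-zero.
#' @param pct_with endorsement percentage with clinical checks.
#' @param digits decimals for the reported value (default 1); `NULL` for no
#'   rounding.
#' @return Relative decrease in percent (negative if the rate increased).
#' @export
#' @examples
#' percentage_decrease(25.3, 15.0)  # 40.7
#' percentage_decrease(9.5, 4.9)    # 48.4
percentage_decrease <- function(pct_without, pct_with, digits = 1) {
  stopifnot(is.numeric(pct_without), is.numeric(pct_with))
  if (any(pct_without == 0, na.rm = TRUE)) {
    stop("percentage decrease undefined: baseline rate is zero")
  }
  out <- 100 * (pct_without - pct_with) / pct_without
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Discordant-pair counts for a paired binary predicate
#'
#' Cross-tabulates a binary predicate evaluated twice on the same
#' respondents (e.g. diagnosed without vs with clinical checks) into the
#' 2x2 paired counts that McNemar's test consumes: `b` respondents positive
#' before and negative after, `c` the reverse, `n11`/`n00` the concordant
#' cells.
#'
#' @param before,after logical vectors of equal length, same respondent
#'   order.
#' @return An object of class `paired_counts` with fields `b`, `c`, `n11`,
#'   `n00` and `n`.
#' @export
paired_counts <- function(before, after) {
  stopifnot(is.logical(before), is.logical(after))
  if (length(before) != length(after)) {
    stop("before and after must have the same length")
  }
  if (anyNA(before) || anyNA(after)) stop("paired flags must not be NA")
  structure(
    list(
      b = sum(before & !after),
      c = sum(!before & after),
      n11 = sum(before & after),
      n00 = sum(!before & !after),
      n = length(before)
    ),
    class = "paired_counts"
  )
}

#' @export
print.paired_counts <- function(x, ...) {
  cat(sprintf(
    "paired counts (n = %d): b = %d (pos -> neg), c = %d (neg -> pos), concordant %d/%d\n",
    x$n, x$b, x$c, x$n11, x$n00))
  invisible(x)
}

#' McNemar's Z-test for paired proportions
#'
#' The large-sample McNemar statistic on the discordant counts:
#' uncorrected `z = (b - c) / sqrt(b + c)`; continuity-corrected
#' `z = (|b - c| - 1) / sqrt(b + c)`, floored at zero. Two-sided p-value
#' from the standard normal. For a predicate that gating can only switch
#' off (`c = 0`) the uncorrected statistic reduces to `sqrt(b)`.
#'
#' @param b either a `paired_counts` object or the count of pairs positive
#'   before and negative after.
#' @param c count of pairs negative before and positive after (ignored when
#'   `b` is a `paired_counts` object).
#' @param corrected apply the continuity correction? No default policy is
#'   imposed: callers choose explicitly. (Summary tables in this package
#'   use the uncorrected form at the symptom and cluster levels and the
#'   corrected form at the disorder level; see [build_report()].)
#' @return A list of class `mcnemar_z` with `z`, `p` (two-sided), `b`, `c`
#'   and `corrected`.
#' @export
#' @examples
#' mcnemar_z(101, 0)$z                     # 10.05 (sqrt(101))
#' mcnemar_z(45, 0, corrected = TRUE)$z    # 6.56
mcnemar_z <- function(b, c = 0L, corrected = FALSE) {
  if (inherits(b, "paired_counts")) {
    c <- b$c
    b <- b$b
  }
  stopifnot(length(b) == 1L, length(c) == 1L, b >= 0, c >= 0)
  if (b + c == 0) {
    stop("no discordant pairs: McNemar's test is undefined (b + c = 0)")
  }
  z <- if (corrected) {
    max(0, abs(b - c) - 1) / sqrt(b + c)
  } else {
    (b - c) / sqrt(b + c)
  }
  structure(
    list(z = z, p = 2 * stats::pnorm(-abs(z)), b = b, c = c,
         corrected = corrected),
    class = "mcnemar_z"
  )
}

#' @export
print.mcnemar_z <- function(x, ...) {
  cat(sprintf("McNemar's Z = %.2f (%s), b = %d, c = %d, two-sided p = %.3g\n",
              x$z, if (x$corrected) "continuity-corrected" else "uncorrected",
              x$b, x$c, x$p))
  invisible(x)
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k - 1) * (1 - sum(item variances) / var(total score))` with
#' sample variances (denominator n - 1).
#'
#' @param scores numeric matrix or data.frame, respondents in rows, items
#'   in columns; at least 2 items, 2 respondents and non-zero total-score
#'   variance.
#' @return A list with `alpha`, `k` (items) and `n` (respondents).
#' @export
cronbach_alpha <- function(scores) {
  scores <- as.matrix(scores)
  if (!is.numeric(scores)) stop("scores must be numeric")
  if (anyNA(scores)) stop("scores must be complete (no NA)")
  k <- ncol(scores)
  n <- nrow(scores)
  if (k < 2L) stop("Cronbach's alpha needs at least 2 items")
  if (n < 2L) stop("Cronbach's alpha needs at least 2 respondents")
  total_var <- stats::var(rowSums(scores))
  if (total_var == 0) stop("total score has zero variance; alpha undefined")
  item_var <- sum(apply(scores, 2L, stats::var))
  list(alpha = k / (k - 1) * (1 - item_var / total_var), k = k, n = n)
}

#' Sample size to estimate a prevalence with given precision
#'
#' Normal-approximation sample size for estimating a population proportion
#' `p` to within a margin of error `E` at a given confidence level:
#' `n = ceiling(z^2 * p * (1 - p) / E^2)` with `z` the two-sided normal
#' quantile. This is the standard prevalence-survey planning formula; note
#' that published studies sometimes report slightly different values from
#' proprietary calculators.
#'
#' @param p anticipated prevalence, in (0, 1).
#' @param confidence confidence level, in (0, 1), e.g. 0.99.
#' @param margin margin of error (half-width), as a proportion in (0, 1).
#' @return A list with `p`, `confidence`, `margin`, `z` and `n_required`.
#' @export
#' @examples
#' required_sample_size(0.5, 0.95, 0.05)$n_required   # 385
#' required_sample_size(0.05, 0.99, 0.02)$n_required  # 788
required_sample_size <- function(p, confidence, margin) {
  stopifnot(length(p) == 1L, length(confidence) == 1L, length(margin) == 1L)
  if (!(p > 0 && p < 1)) stop("p must be in (0, 1)")
  if (!(confidence > 0 && confidence < 1)) {
    stop("confidence must be in (0, 1)")
  }
  if (!(margin > 0 && margin < 1)) stop("margin must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  list(p = p, confidence = confidence, margin = margin, z = z,
       n_required = as.integer(ceiling(z^2 * p * (1 - p) / margin^2)))
}
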