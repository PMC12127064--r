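#' Published ITQ-CC summary tables (reference inputs)
#'
#' The endorsement summary tables reported for the ITQ-CC evaluation in a
#' UK general-population sample (N = 975), shipped as plain CSVs under
#' `inst/extdata/`. These are the *printed* cells — counts, percentages,
#' decreases and Z statistics — used as inputs by the [itq_verify()]
#' harness, which recomputes every derived column from the primary counts
#' and percentages. The respondent-level data behind them were never
#' released, so derived-column recomputation is the strongest check the
#' published record supports.
#'
#' @param which `"symptom"`, `"cluster"`, `"disorder"` or `"all"` (a list
#'   of the three).
#' @param n the sample size the percentages refer to.
#' @return A data.frame (or list of three) with attribute `"N"`.
#' @export
#' @examples
#' itq_reference_tables("disorder")
itq_reference_tables <- function(which = c("all", "symptom", "cluster",
                                           "disorder"),
                                 n = 975L) {
  which <- match.arg(which)
  load1 <- function(name) {
    path <- system.file("extdata", paste0("reference_", name, "_table.csv"),
                        package = "itqcc", mustWork = TRUE)
    tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
    attr(tbl, "N") <- as.integer(n)
    tbl
  }
  if (which == "all") {
    list(symptom = load1("symptom"), cluster = load1("cluster"),
         disorder = load1("disorder"))
  } else {
    load1(which)
  }
}

#' Recompute the derived columns of a published summary table
#'
#' The verify harness: given a table of primary cells (counts with and
#' without clinical checks, and their percentages), recompute every derived
#' column and compare it with the printed one.
#'
#' * `decrease_n_calc = n_without - n_with` (valid when gating is monotone,
#'   which holds for items, clusters, CPTSD and either-disorder; for the
#'   non-monotone disorder-level PTSD row this is the *net* decrease
#'   `b - c`).
#' * `decrease_pct_calc = 100 (pct_without - pct_with) / pct_without`,
#'   computed from the printed 1-decimal percentages, reported to 1
#'   decimal.
#' * `z_calc`: symptom/cluster rows use the uncorrected McNemar statistic,
#'   which for a monotone predicate with `b = decrease_n` equals
#'   `sqrt(decrease_n)`; disorder rows use the continuity-corrected form
#'   `(b - 1)/sqrt(b)` with `b = n_without - n_with`, valid only for
#'   monotone rows (`monotone` column). For a non-monotone row (PTSD) the
#'   individual `b` and `c` cannot be reconstructed from marginal counts
#'   and `z_calc` is `NA`.
#' * `pct_without_calc`/`pct_with_calc`: counts over `N`, flagging printed
#'   rounding slips.
#'
#' Any printed derived cell differing from its recomputation beyond
#' printing precision (0.05 on percentages, 0.005 on Z, any count
#' difference) is flagged in `flags`.
#'
#' @param table data.frame with columns `n_without`, `pct_without`,
#'   `n_with`, `pct_with` and optionally printed `decrease_n`,
#'   `decrease_pct`, `z`, `monotone` and a label column.
#' @param level `"symptom"`, `"cluster"` or `"disorder"`; controls the
#'   continuity-correction policy.
#' @param n cohort size for percentage recomputation (default: the table's
#'   `"N"` attribute, else 975).
#' @return The table with appended `*_calc` columns and a `flags` character
#'   column describing discrepancies ("" when all printed derived cells
#'   check out).
#' @export
#' @examples
#' tab <- itq_verify(itq_reference_tables("cluster"), level = "cluster")
#' tab[, c("label", "decrease_pct", "decrease_pct_calc", "z", "z_calc")]
itq_verify <- function(table, level = c("symptom", "cluster", "disorder"),
                       n = NULL) {
  level <- match.arg(level)
  if (is.null(n)) n <- attr(table, "N")
  if (is.null(n)) n <- 975L
  req <- c("n_without", "pct_without", "n_with", "pct_with")
  miss <- setdiff(req, names(table))
  if (length(miss)) {
    stop("verify table is missing columns: ", paste(miss, collapse = ", "))
  }
  monotone <- if ("monotone" %in% names(table)) {
    table$monotone
  } else {
    rep(TRUE, nrow(table))
  }
  corrected <- level == "disorder"

  out <- table
  out$pct_without_calc <- round_half_up(100 * table$n_without / n, 1)
  out$pct_with_calc <- round_half_up(100 * table$n_with / n, 1)
  out$decrease_n_calc <- table$n_without - table$n_with
  out$decrease_pct_calc <- percentage_decrease(table$pct_without,
                                               table$pct_with)
  out$z_calc <- vapply(seq_len(nrow(table)), function(i) {
    if (!monotone[i]) return(NA_real_)
    b <- table$n_without[i] - table$n_with[i]
    if (b <= 0) return(NA_real_)
    round_half_up(mcnemar_z(b, 0L, corrected = corrected)$z, 2)
  }, numeric(1))

  flag1 <- function(i) {
    f <- character()
    if (abs(out$pct_without_calc[i] - table$pct_without[i]) > 0.05) {
      f <- c(f, sprintf("pct_without printed %.1f, recomputed %.1f",
                        table$pct_without[i], out$pct_without_calc[i]))
    }
    if (abs(out$pct_with_calc[i] - table$pct_with[i]) > 0.05) {
      f <- c(f, sprintf("pct_with printed %.1f, recomputed %.1f",
                        table$pct_with[i], out$pct_with_calc[i]))
    }
    if ("decrease_n" %in% names(table) &&
        !is.na(table$decrease_n[i]) &&
        table$decrease_n[i] != out$decrease_n_calc[i]) {
      f <- c(f, sprintf("decrease_n printed %d, recomputed %d",
                        table$decrease_n[i], out$decrease_n_calc[i]))
    }
    if ("decrease_pct" %in% names(table) &&
        !is.na(table$decrease_pct[i]) &&
        abs(table$decrease_pct[i] - out$decrease_pct_calc[i]) > 0.05) {
      f <- c(f, sprintf("decrease_pct printed %.1f, recomputed %.1f",
                        table$decrease_pct[i], out$decrease_pct_calc[i]))
    }
    if ("z" %in% names(table) && !is.na(out$z_calc[i]) &&
        !is.na(table$z[i]) && abs(table$z[i] - out$z_calc[i]) > 0.005) {
      f <- c(f, sprintf("z printed %.2f, recomputed %.2f",
                        table$z[i], out$z_calc[i]))
    }
    paste(f, collapse = "; ")
  }
  out$flags <- vapply(seq_len(nrow(table)), flag1, character(1))
  attr(out, "N") <- n
  attr(out, "level") <- level
  out
}
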