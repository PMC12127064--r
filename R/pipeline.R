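#' Read a respondent-level cohort CSV
#'
#' Reads and validates a cohort in the schema described at
#' [validate_cohort()]. Violations of the check-gating invariant (a check
#' answered for an unendorsed item, or missing for an endorsed one) are
#' reported with row numbers.
#'
#' @param path path to a CSV file.
#' @param checks require check columns (default `TRUE`).
#' @return A validated cohort data.frame.
#' @export
read_cohort <- function(path, checks = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  if (nrow(cohort) == 0L) stop("empty cohort file: ", path)
  validate_cohort(cohort, checks = checks)
  cohort
}

#' Write a cohort (or any table) to CSV
#'
#' Plain ASCII CSV with fixed column order and empty cells for `NA`, so
#' that fixed-seed simulations round-trip byte-identically.
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

# One summary row: counts with/without gating, percentages, decrease and
# McNemar Z. `before`/`after` are respondent-level logicals.
.rate_row <- function(before, after, corrected, basis = "percent") {
  n <- length(before)
  pc <- paired_counts(before, after)
  n_without <- sum(before)
  n_with <- sum(after)
  pct_without <- round_half_up(100 * n_without / n, 1)
  pct_with <- round_half_up(100 * n_with / n, 1)
  dec_pct <- if (n_without == 0) {
    NA_real_
  } else if (basis == "percent") {
    percentage_decrease(pct_without, pct_with)
  } else {
    round_half_up(100 * (n_without - n_with) / n_without, 1)
  }
  z <- if (pc$b + pc$c == 0) {
    NA_real_
  } else {
    round_half_up(mcnemar_z(pc, corrected = corrected)$z, 2)
  }
  data.frame(
    n_without = n_without, pct_without = pct_without,
    n_with = n_with, pct_with = pct_with,
    decrease_n = n_without - n_with, decrease_pct = dec_pct,
    z = z, b = pc$b, c = pc$c,
    stringsAsFactors = FALSE
  )
}

#' Build the full endorsement/diagnosis study report for a cohort
#'
#' Scores the cohort under the plain ITQ and the check-gated ITQ-CC and
#' assembles the standard summary tables:
#'
#' * `exposure_table`: per-event ITEM endorsement counts and percentages,
#'   plus the exposed fraction and mean event count (when exposure columns
#'   are present).
#' * `symptom_table`: one row per ITQ symptom item (the two dual-variant
#'   items appear once per trial check, with the retained one flagged) and
#'   one row per functional-impairment block.
#' * `cluster_table`: the six symptom clusters and the two impairment
#'   blocks.
#' * `disorder_table`: PTSD, CPTSD and either-disorder prevalence.
#'
#' Each row carries counts with/without checks, percentages (1 decimal,
#' half-up), the decrease in cases, the relative decrease computed from the
#' rounded percentages (or from counts with `basis = "count"`), and
#' McNemar's Z. The mixed correction policy of the original analysis is
#' applied: uncorrected Z at the symptom and cluster levels, continuity-
#' corrected Z at the disorder level. Note the disorder-level PTSD row is
#' the one place where gating can add cases (CPTSD -> PTSD migration), so
#' its discordant counts `b` and `c` are both reported.
#'
#' @param cohort validated cohort data.frame (with check columns).
#' @param variants check-variant choice for the gated mode (default: the
#'   retained final checks).
#' @param basis `"percent"` (decreases from rounded percentages, the
#'   reporting convention of the original tables) or `"count"`.
#' @return A list of class `itq_report` with the four tables and `n`.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_params(n = 300, seed = 7))
#' rep <- build_report(sim$cohort)
#' rep$disorder_table
build_report <- function(cohort, variants = c(dso_ad2 = 1L, dso_dr1 = 2L),
                         basis = c("percent", "count")) {
  basis <- match.arg(basis)
  validate_cohort(cohort)
  n <- nrow(cohort)
  reg <- itq_items()
  ungated <- itq_mode(gated = FALSE)
  gated <- itq_mode(gated = TRUE, variants = variants)

  # exposure table
  exposure_table <- NULL
  exp_cols <- itq_exposure_columns()
  if (all(exp_cols %in% names(cohort))) {
    counts <- colSums(cohort[, exp_cols])
    n_events <- rowSums(cohort[, exp_cols])
    exposure_table <- data.frame(
      event = exp_cols, n = as.integer(counts),
      pct = round_half_up(100 * counts / n, 1),
      stringsAsFactors = FALSE
    )
    attr(exposure_table, "exposed_pct") <-
      round_half_up(100 * mean(n_events > 0), 1)
    attr(exposure_table, "mean_events") <- round_half_up(mean(n_events), 2)
  }

  endo_un <- itq_endorsement(cohort, ungated)

  # symptom table: 12 symptom items (dual ones under both variants) and the
  # two impairment blocks
  sym_rows <- list()
  for (j in which(!reg$cluster %in% c("PTSD_FI", "DSO_FI"))) {
    it <- reg$item[j]
    for (v in if (reg$dual_variant[j]) 1:2 else 1L) {
      vv <- variants
      if (reg$dual_variant[j]) vv[it] <- v
      endo_g <- itq_endorsement(cohort, itq_mode(TRUE, variants = vv),
                                items = it)
      row <- .rate_row(endo_un[, it], endo_g[, 1L], corrected = FALSE,
                       basis = basis)
      sym_rows[[length(sym_rows) + 1L]] <- cbind(
        data.frame(item = it, label = reg$label[j], variant = v,
                   retained = !reg$dual_variant[j] || variants[[it]] == v,
                   stringsAsFactors = FALSE),
        row)
    }
  }
  for (sc in c("PTSD", "DSO")) {
    fi <- paste0(sc, "_FI")
    row <- .rate_row(itq_cluster_met(cohort, ungated, fi)[, 1L],
                     itq_cluster_met(cohort, gated, fi)[, 1L],
                     corrected = FALSE, basis = basis)
    sym_rows[[length(sym_rows) + 1L]] <- cbind(
      data.frame(item = fi, label = paste(sc, "functional impairment"),
                 variant = 1L, retained = TRUE, stringsAsFactors = FALSE),
      row)
  }
  symptom_table <- do.call(rbind, sym_rows)

  # cluster table
  cl_un <- itq_cluster_met(cohort, ungated)
  cl_g <- itq_cluster_met(cohort, gated)
  cluster_labels <- c(
    Re = "Re-experiencing in the here and now", Av = "Avoidance",
    Th = "Sense of threat", PTSD_FI = "PTSD functional impairment",
    AD = "Affective dysregulation", NSC = "Negative self-concept",
    DR = "Disturbed relationships", DSO_FI = "DSO functional impairment"
  )
  cluster_table <- do.call(rbind, lapply(names(cluster_labels), function(cl) {
    cbind(data.frame(cluster = cl, label = cluster_labels[[cl]],
                     stringsAsFactors = FALSE),
          .rate_row(cl_un[, cl], cl_g[, cl], corrected = FALSE,
                    basis = basis))
  }))

  # disorder table (continuity-corrected Z)
  dx_un <- itq_diagnose(cohort, ungated)$label
  dx_g <- itq_diagnose(cohort, gated)$label
  disorder_table <- do.call(rbind, list(
    cbind(data.frame(disorder = "PTSD", stringsAsFactors = FALSE),
          .rate_row(dx_un == "PTSD", dx_g == "PTSD", corrected = TRUE,
                    basis = basis)),
    cbind(data.frame(disorder = "CPTSD", stringsAsFactors = FALSE),
          .rate_row(dx_un == "CPTSD", dx_g == "CPTSD", corrected = TRUE,
                    basis = basis)),
    cbind(data.frame(disorder = "either", stringsAsFactors = FALSE),
          .rate_row(dx_un != "none", dx_g != "none", corrected = TRUE,
                    basis = basis))
  ))

  structure(
    list(n = n, basis = basis, variants = variants,
         exposure_table = exposure_table, symptom_table = symptom_table,
         cluster_table = cluster_table, disorder_table = disorder_table),
    class = "itq_report"
  )
}

#' @export
print.itq_report <- function(x, ...) {
  cat(sprintf("ITQ/ITQ-CC study report (N = %d)\n", x$n))
  if (!is.null(x$exposure_table)) {
    cat(sprintf("  exposed to >= 1 event: %.1f%%; mean events: %.2f\n",
                attr(x$exposure_table, "exposed_pct"),
                attr(x$exposure_table, "mean_events")))
  }
  cat("\nSymptom level:\n")
  print(x$symptom_table[, c("label", "variant", "n_without", "pct_without",
                            "n_with", "pct_with", "decrease_n",
                            "decrease_pct", "z")], row.names = FALSE)
  cat("\nCluster level:\n")
  print(x$cluster_table[, c("label", "n_without", "pct_without", "n_with",
                            "pct_with", "decrease_n", "decrease_pct", "z")],
        row.names = FALSE)
  cat("\nDisorder level (continuity-corrected Z):\n")
  print(x$disorder_table, row.names = FALSE)
  invisible(x)
}

#' Write every table of a report to CSV files
#'
#' @param report an `itq_report`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "itq_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$exposure_table)) {
    write_cohort(report$exposure_table, file.path(dir, "exposure_table.csv"))
  }
  write_cohort(report$symptom_table, file.path(dir, "symptom_table.csv"))
  write_cohort(report$cluster_table, file.path(dir, "cluster_table.csv"))
  write_cohort(report$disorder_table, file.path(dir, "disorder_table.csv"))
  invisible(dir)
}
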