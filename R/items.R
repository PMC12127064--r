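#' Item registry for the International Trauma Questionnaire (ITQ)
#'
#' The ITQ is an 18-item self-report measure of ICD-11 PTSD and Complex PTSD
#' (CPTSD). Six items measure the three PTSD symptom clusters
#' (re-experiencing in the here and now, avoidance, sense of threat; two
#' items each), six measure the three DSO clusters (affective dysregulation,
#' negative self-concept, disturbed relationships; two items each), and each
#' scale carries three functional-impairment items. Items are answered on a
#' five-point Likert scale (0 = "Not at all" ... 4 = "Extremely"); a score of
#' 2 ("Moderately") or higher marks the symptom as present.
#'
#' @return A data.frame with one row per item: `item` (column name used in
#'   cohort data), `scale` (`"PTSD"` or `"DSO"`), `cluster` (one of `Re`,
#'   `Av`, `Th`, `AD`, `NSC`, `DR`, `PTSD_FI`, `DSO_FI`), `label` (human
#'   readable), and `dual_variant` (`TRUE` for the two items that carry two
#'   trial clinical checks).
#' @export
#' @examples
#' itq_items()
itq_items <- function() {
  data.frame(
    item = c(
      "ptsd_re1", "ptsd_re2", "ptsd_av1", "ptsd_av2", "ptsd_th1", "ptsd_th2",
      "ptsd_fi1", "ptsd_fi2", "ptsd_fi3",
      "dso_ad1", "dso_ad2", "dso_nsc1", "dso_nsc2", "dso_dr1", "dso_dr2",
      "dso_fi1", "dso_fi2", "dso_fi3"
    ),
    scale = rep(c("PTSD", "DSO"), each = 9L),
    cluster = c(
      "Re", "Re", "Av", "Av", "Th", "Th", rep("PTSD_FI", 3L),
      "AD", "AD", "NSC", "NSC", "DR", "DR", rep("DSO_FI", 3L)
    ),
    label = c(
      "Nightmares", "Flashbacks", "Internal avoidance", "External avoidance",
      "Hyperalert", "Hyperarousal",
      paste("PTSD functional impairment", 1:3),
      "Difficulty calming down", "Numbing", "Feel like a failure",
      "Feel worthless", "Feel cut off from others",
      "Difficult to stay close to others",
      paste("DSO functional impairment", 1:3)
    ),
    dual_variant = FALSE,
    stringsAsFactors = FALSE
  ) -> reg
  # The numbing and feel-cut-off items each had two trial clinical checks.
  reg$dual_variant[reg$item %in% c("dso_ad2", "dso_dr1")] <- TRUE
  reg
}

#' Cluster and column-name helpers
#'
#' Small registry accessors for code that builds or consumes cohort data:
#' the six symptom clusters in diagnostic order, all eight blocks
#' (clusters plus the two functional-impairment blocks), the two items
#' carrying two trial checks, the 21 ITEM trauma-exposure column names,
#' and the full set of clinical-check column names.
#'
#' @return Character vectors of ids / column names.
#' @export
itq_symptom_clusters <- function() c("Re", "Av", "Th", "AD", "NSC", "DR")

#' @rdname itq_symptom_clusters
#' @export
itq_all_clusters <- function() {
  c("Re", "Av", "Th", "AD", "NSC", "DR", "PTSD_FI", "DSO_FI")
}

#' @rdname itq_symptom_clusters
#' @export
itq_dual_variant_items <- function() c("dso_ad2", "dso_dr1")

#' Name of the clinical-check column for an item
#'
#' @param item item identifier (e.g. `"ptsd_re1"`).
#' @param variant check variant, 1 or 2. Variant 2 exists only for the two
#'   dual-variant items (`dso_ad2`, numbing; `dso_dr1`, feeling cut off).
#' @return Column name, e.g. `"chk_ptsd_re1"` or `"chk_dso_ad2_v2"`.
#' @export
itq_check_column <- function(item, variant = 1L) {
  stopifnot(length(item) == length(variant) || length(variant) == 1L)
  variant <- rep_len(as.integer(variant), length(item))
  bad <- variant == 2L & !item %in% itq_dual_variant_items()
  if (any(bad)) {
    stop("variant 2 checks exist only for items ",
         paste(itq_dual_variant_items(), collapse = ", "),
         "; requested for: ", paste(item[bad], collapse = ", "))
  }
  if (any(!variant %in% 1:2)) stop("check variant must be 1 or 2")
  paste0("chk_", item, ifelse(variant == 2L, "_v2", ""))
}

#' @rdname itq_symptom_clusters
#' @export
itq_exposure_columns <- function() sprintf("item%02d", 1:21)

#' @rdname itq_symptom_clusters
#' @export
itq_check_columns <- function() {
  reg <- itq_items()
  c(itq_check_column(reg$item),
    itq_check_column(itq_dual_variant_items(), 2L))
}

#' Validate a cohort data frame against the ITQ-CC schema
#'
#' A cohort holds one row per respondent: a `respondent_id`, the 18 Likert
#' item columns (integers 0-4), one clinical-check column per check
#' (`chk_<item>`, plus `chk_dso_ad2_v2` and `chk_dso_dr1_v2` for the two
#' dual-variant items) with values `"yes"`, `"no"` or `NA`, and optionally
#' the 21 binary trauma-exposure columns `item01`..`item21` of the
#' International Trauma Exposure Measure (ITEM).
#'
#' The check-gating invariant is enforced: a check answer is present if and
#' only if the paired item score is 2 or higher (checks were only shown for
#' endorsed items, and an endorsed item always received one).
#'
#' @param cohort data.frame to validate.
#' @param checks require check columns and the gating invariant
#'   (default `TRUE`; set `FALSE` for plain-ITQ cohorts without checks).
#' @return `cohort`, invisibly, if valid; otherwise an error listing the
#'   offending columns and row numbers.
#' @export
validate_cohort <- function(cohort, checks = TRUE) {
  if (!is.data.frame(cohort)) stop("cohort must be a data.frame")
  if (nrow(cohort) == 0L) stop("empty cohort: no respondent rows")
  reg <- itq_items()
  problems <- character()

  missing_items <- setdiff(c("respondent_id", reg$item), names(cohort))
  if (length(missing_items)) {
    stop("cohort is missing required columns: ",
         paste(missing_items, collapse = ", "))
  }

  for (it in reg$item) {
    v <- cohort[[it]]
    ok <- is.na(v) | (is.numeric(v) & v %in% 0:4)
    if (!all(ok)) {
      problems <- c(problems, sprintf(
        "%s: scores outside 0-4 in rows %s", it,
        paste(utils::head(which(!ok), 5L), collapse = ", ")))
    }
  }

  if (checks) {
    chk_cols <- itq_check_columns()
    missing_chk <- setdiff(chk_cols, names(cohort))
    if (length(missing_chk)) {
      stop("cohort is missing check columns: ",
           paste(missing_chk, collapse = ", "))
    }
    chk_item <- sub("_v2$", "", sub("^chk_", "", chk_cols))
    for (i in seq_along(chk_cols)) {
      ans <- cohort[[chk_cols[i]]]
      bad_val <- !is.na(ans) & !ans %in% c("yes", "no")
      if (any(bad_val)) {
        problems <- c(problems, sprintf(
          "%s: values other than yes/no/NA in rows %s", chk_cols[i],
          paste(utils::head(which(bad_val), 5L), collapse = ", ")))
      }
      score <- cohort[[chk_item[i]]]
      endorsed <- !is.na(score) & score >= 2
      viol_missing <- endorsed & is.na(ans)
      viol_extra <- !endorsed & !is.na(ans)
      if (any(viol_missing)) {
        problems <- c(problems, sprintf(
          "%s: check missing for endorsed item (score >= 2) in rows %s",
          chk_cols[i],
          paste(utils::head(which(viol_missing), 5L), collapse = ", ")))
      }
      if (any(viol_extra)) {
        problems <- c(problems, sprintf(
          "%s: check answered although item score < 2 in rows %s",
          chk_cols[i],
          paste(utils::head(which(viol_extra), 5L), collapse = ", ")))
      }
    }
  }

  exp_cols <- intersect(itq_exposure_columns(), names(cohort))
  for (ec in exp_cols) {
    v <- cohort[[ec]]
    ok <- is.na(v) | v %in% 0:1
    if (!all(ok)) {
      problems <- c(problems, sprintf(
        "%s: exposure values outside {0,1} in rows %s", ec,
        paste(utils::head(which(!ok), 5L), collapse = ", ")))
    }
  }

  if (length(problems)) {
    stop("cohort schema violations:\n  ",
         paste(problems, collapse = "\n  "))
  }
  invisible(cohort)
}
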