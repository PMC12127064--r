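#' Is a symptom present at a given Likert score?
#'
#' The ITQ marks a symptom as present when the item is rated 2
#' ("Moderately") or higher on the 0-4 Likert scale.
#'
#' @param score integer vector of Likert scores in 0..4 (`NA` allowed and
#'   propagated).
#' @return Logical vector, `TRUE` where `score >= 2`.
#' @export
#' @examples
#' itq_symptom_present(c(0, 1, 2, 3, 4))
itq_symptom_present <- function(score) {
  if (!is.numeric(score)) stop("score must be numeric (integer 0-4)")
  chk <- score[!is.na(score)]
  if (any(chk != as.integer(chk)) || any(chk < 0 | chk > 4)) {
    stop("score must be an integer in 0-4")
  }
  score >= 2
}

# Resolve check answers for one item under a mode; returns character vector
# ("yes"/"no"/NA). Errors on gating violations (endorsed but no answer).
.check_answers <- function(cohort, item, score, variant) {
  col <- itq_check_column(item, variant)
  if (!col %in% names(cohort)) {
    stop("gated scoring requires check column '", col, "'")
  }
  ans <- cohort[[col]]
  endorsed <- !is.na(score) & score >= 2
  bad <- endorsed & is.na(ans)
  if (any(bad)) {
    stop("inconsistent record: item ", item, " endorsed (score >= 2) but ",
         col, " not answered in rows ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  ans
}

#' Per-item endorsement matrix for a cohort
#'
#' Applies the symptom-present rule (score >= 2), and, for a gated mode,
#' additionally requires a "yes" on the item's clinical check (using the
#' mode's chosen variant for the two dual-variant items). Gating is
#' one-directional: it can withdraw an endorsement but never create one.
#'
#' @param cohort a validated cohort data.frame (see [validate_cohort()]).
#' @param mode an [itq_mode()] object.
#' @param items character vector of item ids (default: all 18).
#' @return Logical matrix, `nrow(cohort)` x `length(items)`, with item ids
#'   as column names. If the mode is lenient and scores were imputed, the
#'   attribute `"imputed_zero"` counts imputations per item.
#' @export
itq_endorsement <- function(cohort, mode = itq_mode(),
                            items = itq_items()$item) {
  stopifnot(inherits(mode, "itq_mode"), is.data.frame(cohort))
  if (nrow(cohort) == 0L) stop("empty cohort: no respondent rows")
  out <- matrix(FALSE, nrow(cohort), length(items),
                dimnames = list(NULL, items))
  imputed <- integer(length(items))
  names(imputed) <- items
  for (it in items) {
    if (!it %in% names(cohort)) stop("cohort is missing item column ", it)
    s <- cohort[[it]]
    if (anyNA(s)) {
      if (mode$missing == "strict") {
        stop("missing score for item ", it, " in rows ",
             paste(utils::head(which(is.na(s)), 5L), collapse = ", "),
             " (strict mode; use missing = \"lenient\" to score as 0)")
      }
      imputed[it] <- sum(is.na(s))
      s[is.na(s)] <- 0L
    }
    present <- itq_symptom_present(s)
    if (mode$gated) {
      variant <- if (it %in% names(mode$variants)) mode$variants[[it]] else 1L
      ans <- .check_answers(cohort, it, s, variant)
      out[, it] <- present & !is.na(ans) & ans == "yes"
    } else {
      out[, it] <- present
    }
  }
  if (any(imputed > 0L)) attr(out, "imputed_zero") <- imputed[imputed > 0L]
  out
}

#' Cluster- and impairment-level requirement flags
#'
#' Each symptom cluster is measured by two items and is met when at least
#' one of them is endorsed; each scale's functional-impairment block holds
#' three items and is met when at least one is endorsed.
#'
#' @inheritParams itq_endorsement
#' @param clusters which blocks to evaluate; any of `Re`, `Av`, `Th`, `AD`,
#'   `NSC`, `DR`, `PTSD_FI`, `DSO_FI`.
#' @return Logical matrix, one column per requested block.
#' @export
itq_cluster_met <- function(cohort, mode = itq_mode(),
                            clusters = itq_all_clusters()) {
  unknown <- setdiff(clusters, itq_all_clusters())
  if (length(unknown)) {
    stop("unknown cluster id(s): ", paste(unknown, collapse = ", "))
  }
  reg <- itq_items()
  endo <- itq_endorsement(cohort, mode,
                          items = reg$item[reg$cluster %in% clusters])
  out <- vapply(clusters, function(cl) {
    its <- reg$item[reg$cluster == cl]
    rowSums(endo[, its, drop = FALSE]) >= 1L
  }, logical(nrow(cohort)))
  out <- matrix(out, nrow = nrow(cohort),
                dimnames = list(NULL, clusters))
  out
}

#' Functional-impairment requirement for one scale
#'
#' @inheritParams itq_endorsement
#' @param scale `"PTSD"` or `"DSO"`.
#' @return Logical vector: at least one of the scale's three impairment
#'   items endorsed under `mode`.
#' @export
itq_impairment_met <- function(cohort, scale = c("PTSD", "DSO"),
                               mode = itq_mode()) {
  scale <- match.arg(scale)
  cl <- if (scale == "PTSD") "PTSD_FI" else "DSO_FI"
  itq_cluster_met(cohort, mode, clusters = cl)[, 1L]
}

#' ICD-11 PTSD/CPTSD diagnostic algorithm
#'
#' Implements the ICD-11 diagnostic rules as operationalized by the ITQ:
#'
#' * PTSD criteria: at least one endorsed item in each of re-experiencing
#'   (`Re`), avoidance (`Av`) and sense of threat (`Th`), plus at least one
#'   PTSD functional-impairment item.
#' * DSO criteria: at least one endorsed item in each of affective
#'   dysregulation (`AD`), negative self-concept (`NSC`) and disturbed
#'   relationships (`DR`), plus at least one DSO impairment item.
#' * CPTSD requires both blocks; PTSD requires the PTSD block without the
#'   full DSO block; anything else (including DSO criteria alone, for which
#'   ICD-11 defines no diagnosis) is `none`. The labels are mutually
#'   exclusive by construction.
#'
#' Under check gating the PTSD label is not monotone: a respondent meeting
#' CPTSD ungated whose DSO endorsements fail their checks while the PTSD
#' endorsements survive migrates from CPTSD to PTSD, so gated PTSD counts
#' can exceed ungated ones even though every other level only loses cases.
#'
#' @inheritParams itq_endorsement
#' @return A data.frame with `respondent_id`, `label` (factor `none` /
#'   `PTSD` / `CPTSD`), the logical block flags `ptsd_part` and `dso_part`,
#'   the six cluster flags and the two impairment flags.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_params(n = 50, seed = 1))$cohort
#' table(itq_diagnose(cohort, itq_mode(gated = TRUE))$label)
itq_diagnose <- function(cohort, mode = itq_mode()) {
  cl <- itq_cluster_met(cohort, mode)
  ptsd_part <- cl[, "Re"] & cl[, "Av"] & cl[, "Th"] & cl[, "PTSD_FI"]
  dso_part <- cl[, "AD"] & cl[, "NSC"] & cl[, "DR"] & cl[, "DSO_FI"]
  label <- ifelse(ptsd_part & dso_part, "CPTSD",
                  ifelse(ptsd_part, "PTSD", "none"))
  if (mode$require_exposure) {
    exp_cols <- itq_exposure_columns()
    if (!all(exp_cols %in% names(cohort))) {
      stop("require_exposure = TRUE but exposure columns are absent")
    }
    n_events <- rowSums(cohort[, exp_cols])
    label[n_events == 0L] <- "none"
  }
  res <- data.frame(
    respondent_id = if ("respondent_id" %in% names(cohort)) {
      cohort$respondent_id
    } else {
      seq_len(nrow(cohort))
    },
    label = factor(label, levels = c("none", "PTSD", "CPTSD")),
    ptsd_part = ptsd_part,
    dso_part = dso_part,
    stringsAsFactors = FALSE
  )
  cbind(res, as.data.frame(cl))
}

#' Select the clinical-check variant to retain
#'
#' For the two items that trialled two clinical checks, the pre-set rule
#' keeps the check producing the largest decrease in item endorsement.
#' Ties break to the lowest variant id (the rule as stated never needed a
#' tie-break).
#'
#' @param decreases named numeric vector (or bare numeric whose positions
#'   are variant ids) of decrease counts or percentages per variant.
#' @return The selected variant id (integer).
#' @export
#' @examples
#' select_check_variant(c(`1` = 94, `2` = 76))  # numbing -> variant 1
#' select_check_variant(c(`1` = 53, `2` = 71))  # cut-off -> variant 2
select_check_variant <- function(decreases) {
  if (length(decreases) == 0L) stop("no variants supplied")
  if (any(is.na(decreases))) stop("decrease values must not be NA")
  ids <- if (is.null(names(decreases))) {
    seq_along(decreases)
  } else {
    as.integer(names(decreases))
  }
  best <- ids[decreases == max(decreases)]
  as.integer(min(best))
}
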