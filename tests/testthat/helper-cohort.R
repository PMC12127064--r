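# Hand-built cohort fixtures: a blank cohort (all scores 0, checks NA) and
# a setter that keeps the check-gating invariant satisfied.

blank_cohort <- function(n = 1L) {
  df <- data.frame(respondent_id = sprintf("T%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (it in itq_items()$item) df[[it]] <- 0L
  for (cc in itq_check_columns()) df[[cc]] <- NA_character_
  df
}

# Set one item's score and check answer(s) on one row. For dual-variant
# items, `check2` sets the variant-2 answer (defaults to `check`).
set_item <- function(cohort, row, item, score, check = "yes",
                     check2 = check) {
  cohort[row, item] <- as.integer(score)
  if (score >= 2) {
    cohort[row, itq_check_column(item)] <- check
    if (item %in% itq_dual_variant_items()) {
      cohort[row, itq_check_column(item, 2L)] <- check2
    }
  } else {
    cohort[row, itq_check_column(item)] <- NA_character_
    if (item %in% itq_dual_variant_items()) {
      cohort[row, itq_check_column(item, 2L)] <- NA_character_
    }
  }
  cohort
}

# Endorse one item per listed cluster at the given score, with the given
# check answer.
endorse_clusters <- function(cohort, row, clusters, score = 3L,
                             check = "yes") {
  reg <- itq_items()
  for (cl in clusters) {
    it <- reg$item[reg$cluster == cl][1L]
    cohort <- set_item(cohort, row, it, score, check)
  }
  cohort
}

# A respondent meeting full CPTSD requirements ungated, with per-block
# check answers (PTSD block: Re/Av/Th/PTSD_FI; DSO block: AD/NSC/DR/DSO_FI).
cptsd_record <- function(check_ptsd = "yes", check_dso = "yes") {
  co <- blank_cohort(1L)
  co <- endorse_clusters(co, 1L, c("Re", "Av", "Th", "PTSD_FI"),
                         check = check_ptsd)
  endorse_clusters(co, 1L, c("AD", "NSC", "DR", "DSO_FI"),
                   check = check_dso)
}
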