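test_that("symptom presence follows the score >= 2 rule and rejects bad input", {
  expect_equal(itq_symptom_present(0:4), c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_true(is.na(itq_symptom_present(NA_integer_)))
  expect_error(itq_symptom_present(5), "0-4")
  expect_error(itq_symptom_present(-1), "0-4")
  expect_error(itq_symptom_present(2.5), "integer")
  expect_error(itq_symptom_present("2"), "numeric")
})

test_that("the item registry has the ICD-11 ITQ structure", {
  reg <- itq_items()
  expect_equal(nrow(reg), 18L)
  counts <- table(reg$cluster)
  for (cl in itq_symptom_clusters()) expect_equal(unname(counts[cl]), 2L)
  expect_equal(unname(counts["PTSD_FI"]), 3L)
  expect_equal(unname(counts["DSO_FI"]), 3L)
  # scale consistency
  expect_true(all(reg$scale[reg$cluster %in% c("Re", "Av", "Th", "PTSD_FI")]
                  == "PTSD"))
  expect_true(all(reg$scale[reg$cluster %in% c("AD", "NSC", "DR", "DSO_FI")]
                  == "DSO"))
  expect_equal(reg$item[reg$dual_variant], c("dso_ad2", "dso_dr1"))
  expect_error(itq_check_column("ptsd_re1", 2), "variant 2")
})

test_that("gated endorsement requires both the score and a yes on the check", {
  co <- set_item(blank_cohort(3L), 1L, "ptsd_re1", 3L, "yes")
  co <- set_item(co, 2L, "ptsd_re1", 3L, "no")
  co <- set_item(co, 3L, "ptsd_re1", 1L)
  ungated <- itq_endorsement(co, itq_mode(FALSE), items = "ptsd_re1")
  gated <- itq_endorsement(co, itq_mode(TRUE), items = "ptsd_re1")
  expect_equal(unname(ungated[, 1]), c(TRUE, TRUE, FALSE))
  expect_equal(unname(gated[, 1]), c(TRUE, FALSE, FALSE))
})

test_that("an endorsed item without a check answer is an inconsistent record", {
  co <- blank_cohort(1L)
  co$ptsd_av1 <- 3L                    # score >= 2 but check left NA
  expect_error(itq_endorsement(co, itq_mode(TRUE)), "inconsistent record")
  expect_error(validate_cohort(co), "check missing for endorsed")
  # ungated scoring is unaffected
  expect_true(itq_endorsement(co, itq_mode(FALSE))[, "ptsd_av1"])
})

test_that("cluster rule matches brute-force enumeration over all score/check configurations", {
  # all 5^2 score pairs x all check-answer combinations for the Re cluster,
  # in both modes, against an independently coded at-least-one oracle
  grid <- expand.grid(s1 = 0:4, s2 = 0:4,
                      a1 = c("yes", "no"), a2 = c("yes", "no"),
                      stringsAsFactors = FALSE)
  co <- blank_cohort(nrow(grid))
  co$ptsd_re1 <- grid$s1
  co$ptsd_re2 <- grid$s2
  co$chk_ptsd_re1 <- ifelse(grid$s1 >= 2, grid$a1, NA_character_)
  co$chk_ptsd_re2 <- ifelse(grid$s2 >= 2, grid$a2, NA_character_)

  got_un <- itq_cluster_met(co, itq_mode(FALSE), "Re")[, 1]
  got_g <- itq_cluster_met(co, itq_mode(TRUE), "Re")[, 1]
  oracle_un <- oracle_g <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    e1_un <- grid$s1[i] >= 2
    e2_un <- grid$s2[i] >= 2
    oracle_un[i] <- e1_un || e2_un
    oracle_g[i] <- (e1_un && grid$a1[i] == "yes") ||
      (e2_un && grid$a2[i] == "yes")
  }
  expect_equal(unname(got_un), oracle_un)
  expect_equal(unname(got_g), oracle_g)
  # gating never adds cluster endorsements
  expect_true(all(!got_g | got_un))
  expect_error(itq_cluster_met(co, itq_mode(FALSE), "XX"), "unknown cluster")
})

test_that("impairment rule matches exhaustive enumeration of score triples and checks", {
  grid <- expand.grid(s1 = 0:4, s2 = 0:4, s3 = 0:4,
                      a1 = c("yes", "no"), a2 = c("yes", "no"),
                      a3 = c("yes", "no"), stringsAsFactors = FALSE)
  co <- blank_cohort(nrow(grid))
  its <- paste0("ptsd_fi", 1:3)
  for (k in 1:3) {
    co[[its[k]]] <- grid[[paste0("s", k)]]
    co[[itq_check_column(its[k])]] <-
      ifelse(grid[[paste0("s", k)]] >= 2, grid[[paste0("a", k)]],
             NA_character_)
  }
  got_un <- itq_impairment_met(co, "PTSD", itq_mode(FALSE))
  got_g <- itq_impairment_met(co, "PTSD", itq_mode(TRUE))
  sc <- as.matrix(grid[, 1:3])
  an <- as.matrix(grid[, 4:6]) == "yes"
  expect_equal(got_un, rowSums(sc >= 2) >= 1)
  expect_equal(got_g, rowSums(sc >= 2 & an) >= 1)
  # a single high-scoring item whose check fails does not rescue the block
  i <- which(grid$s1 == 4 & grid$s2 == 1 & grid$s3 == 0 & grid$a1 == "no")[1]
  expect_false(got_g[i])
  expect_true(got_un[i])
})

test_that("diagnostic algorithm yields the ICD-11 labels and their exclusivity", {
  # maximal case: everything endorsed and confirmed
  co <- blank_cohort(1L)
  for (it in itq_items()$item) co <- set_item(co, 1L, it, 4L, "yes")
  expect_equal(as.character(itq_diagnose(co, itq_mode(TRUE))$label), "CPTSD")
  expect_equal(as.character(itq_diagnose(co, itq_mode(FALSE))$label), "CPTSD")

  # PTSD block met, AD cluster absent -> PTSD
  co2 <- endorse_clusters(blank_cohort(1L), 1L,
                          c("Re", "Av", "Th", "PTSD_FI",
                            "NSC", "DR", "DSO_FI"))
  dx2 <- itq_diagnose(co2, itq_mode(FALSE))
  expect_equal(as.character(dx2$label), "PTSD")
  expect_true(dx2$ptsd_part)
  expect_false(dx2$dso_part)

  # DSO criteria alone carry no ICD-11 diagnosis
  co3 <- endorse_clusters(blank_cohort(1L), 1L,
                          c("AD", "NSC", "DR", "DSO_FI"))
  expect_equal(as.character(itq_diagnose(co3, itq_mode(FALSE))$label), "none")
})

test_that("failed DSO checks migrate a CPTSD case to PTSD under gating", {
  co <- cptsd_record(check_ptsd = "yes", check_dso = "no")
  expect_equal(as.character(itq_diagnose(co, itq_mode(FALSE))$label), "CPTSD")
  expect_equal(as.character(itq_diagnose(co, itq_mode(TRUE))$label), "PTSD")
  # so the PTSD label is not monotone under gating: it gained a case
  before <- itq_diagnose(co, itq_mode(FALSE))$label == "PTSD"
  after <- itq_diagnose(co, itq_mode(TRUE))$label == "PTSD"
  expect_gte(paired_counts(before, after)$c, 1L)
})

test_that("gating with every check answered yes reproduces plain ITQ scoring", {
  sim <- simulate_cohort(cohort_params(n = 400, seed = 11))
  co <- sim$cohort
  for (cc in itq_check_columns()) {
    co[[cc]][!is.na(co[[cc]])] <- "yes"
  }
  expect_equal(itq_endorsement(co, itq_mode(TRUE)),
               itq_endorsement(co, itq_mode(FALSE)))
  expect_equal(itq_diagnose(co, itq_mode(TRUE))$label,
               itq_diagnose(co, itq_mode(FALSE))$label)
})

test_that("check-variant selection keeps the largest decrease, ties to variant 1", {
  expect_equal(select_check_variant(c(`1` = 94, `2` = 76)), 1L)
  expect_equal(select_check_variant(c(`1` = 53, `2` = 71)), 2L)
  expect_equal(select_check_variant(c(`1` = 10, `2` = 10)), 1L)
  expect_error(select_check_variant(numeric(0)), "no variants")
})

test_that("strict mode refuses missing scores; lenient mode scores them as absent", {
  co <- set_item(blank_cohort(2L), 1L, "ptsd_re1", 3L, "yes")
  co$dso_ad1[2L] <- NA
  expect_error(itq_endorsement(co, itq_mode(FALSE)), "strict")
  endo <- itq_endorsement(co, itq_mode(FALSE, missing = "lenient"))
  expect_false(endo[2L, "dso_ad1"])
  expect_equal(attr(endo, "imputed_zero"), c(dso_ad1 = 1L))
})

test_that("exposure filter zeroes diagnoses for unexposed respondents only when requested", {
  co <- cptsd_record()
  for (ec in itq_exposure_columns()) co[[ec]] <- 0L
  expect_equal(as.character(itq_diagnose(co, itq_mode(FALSE))$label), "CPTSD")
  m <- itq_mode(FALSE, require_exposure = TRUE)
  expect_equal(as.character(itq_diagnose(co, m)$label), "none")
  co$item05 <- 1L
  expect_equal(as.character(itq_diagnose(co, m)$label), "CPTSD")
})
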