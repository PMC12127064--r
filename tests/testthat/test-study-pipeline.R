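test_that("cohort CSVs round-trip through write and read", {
  sim <- simulate_cohort(cohort_params(n = 150, seed = 4))
  path <- tempfile(fileext = ".csv")
  write_cohort(sim$cohort, path)
  back <- read_cohort(path)
  expect_equal(back, sim$cohort)
})

test_that("schema violations are reported with row numbers", {
  sim <- simulate_cohort(cohort_params(n = 20, seed = 4))
  co <- sim$cohort
  i <- which(co$ptsd_re1 >= 2)[1]
  co$chk_ptsd_re1[i] <- NA
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_error(read_cohort(path), paste0("rows.* ", i))

  co2 <- sim$cohort
  co2$dso_ad1[2] <- 7L
  write_cohort(co2, path)
  expect_error(read_cohort(path), "outside 0-4")

  writeLines(paste(names(sim$cohort), collapse = ","), path)
  expect_error(read_cohort(path), "empty cohort")
  expect_error(read_cohort(tempfile()), "not found")
})

test_that("an all-confirming cohort produces a null report (no discordance)", {
  sim <- simulate_cohort(cohort_params(n = 250, seed = 8))
  co <- sim$cohort
  for (cc in itq_check_columns()) co[[cc]][!is.na(co[[cc]])] <- "yes"
  rep <- build_report(co)
  expect_equal(rep$symptom_table$n_with, rep$symptom_table$n_without)
  expect_true(all(rep$symptom_table$decrease_n == 0L))
  expect_true(all(is.na(rep$symptom_table$z)))
  expect_true(all(is.na(rep$disorder_table$z)))
  expect_error(build_report(co[0, ]), "empty cohort")
})

test_that("report cells match a hand-enumerated six-record fixture", {
  # r1 CPTSD -> CPTSD; r2 CPTSD -> PTSD (DSO checks fail);
  # r3 PTSD -> PTSD; r4 none; r5 PTSD -> none (Re check fails);
  # r6 DSO-only -> none
  co <- blank_cohort(6L)
  for (cl in c("Re", "Av", "Th", "PTSD_FI", "AD", "NSC", "DR", "DSO_FI")) {
    co <- endorse_clusters(co, 1L, cl)
    co <- endorse_clusters(co, 2L, cl,
                           check = if (cl %in% c("AD", "NSC", "DR",
                                                 "DSO_FI")) "no" else "yes")
  }
  co <- endorse_clusters(co, 3L, c("Re", "Av", "Th", "PTSD_FI"))
  co <- endorse_clusters(co, 5L, c("Av", "Th", "PTSD_FI"))
  co <- set_item(co, 5L, "ptsd_re1", 3L, "no")
  co <- endorse_clusters(co, 6L, c("AD", "NSC", "DR", "DSO_FI"))

  rep <- build_report(co)
  dt <- rep$disorder_table
  expect_equal(dt$n_without[dt$disorder == "PTSD"], 2L)   # r3, r5
  expect_equal(dt$n_with[dt$disorder == "PTSD"], 2L)      # r2, r3
  expect_equal(dt$b[dt$disorder == "PTSD"], 1L)           # r5 lost
  expect_equal(dt$c[dt$disorder == "PTSD"], 1L)           # r2 gained
  expect_equal(dt$n_without[dt$disorder == "CPTSD"], 2L)  # r1, r2
  expect_equal(dt$n_with[dt$disorder == "CPTSD"], 1L)     # r1
  expect_equal(dt$c[dt$disorder == "CPTSD"], 0L)
  expect_equal(dt$n_without[dt$disorder == "either"], 4L)
  expect_equal(dt$n_with[dt$disorder == "either"], 3L)

  ct <- rep$cluster_table
  expect_equal(ct$n_without[ct$cluster == "Re"], 4L)  # r1 r2 r3 r5
  expect_equal(ct$n_with[ct$cluster == "Re"], 3L)     # r5's check failed
  expect_equal(ct$n_without[ct$cluster == "AD"], 3L)  # r1 r2 r6
  expect_equal(ct$n_with[ct$cluster == "AD"], 2L)     # r2's check failed

  st <- rep$symptom_table
  expect_equal(st$n_without[st$item == "ptsd_re1" & st$variant == 1], 4L)
  expect_equal(st$n_with[st$item == "ptsd_re1" & st$variant == 1], 3L)
})

test_that("either-disorder count equals PTSD plus CPTSD in both modes", {
  sim <- simulate_cohort(cohort_params(n = 2000, seed = 15))
  rep <- build_report(sim$cohort)
  dt <- rep$disorder_table
  for (col in c("n_without", "n_with")) {
    expect_equal(dt[[col]][dt$disorder == "either"],
                 dt[[col]][dt$disorder == "PTSD"] +
                   dt[[col]][dt$disorder == "CPTSD"])
  }
})

test_that("report decreases can be computed on a count basis as an alternative", {
  sim <- simulate_cohort(cohort_params(n = 2000, seed = 16))
  rp <- build_report(sim$cohort, basis = "percent")
  rc <- build_report(sim$cohort, basis = "count")
  i <- which(rp$symptom_table$n_without > 0)
  # same quantity up to percentage-rounding error
  expect_true(all(abs(rp$symptom_table$decrease_pct[i] -
                        rc$symptom_table$decrease_pct[i]) < 2.5))
  # count basis is exact against first principles
  st <- rc$symptom_table
  expect_equal(st$decrease_pct,
               round_half_up(100 * (st$n_without - st$n_with) /
                               st$n_without, 1))
})

test_that("mode configuration files round-trip through YAML and JSON", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c("gated: true", "missing: lenient",
               "variants:", "  dso_ad2: 2"), y)
  m <- read_mode_config(y)
  expect_true(m$gated)
  expect_equal(m$missing, "lenient")
  expect_equal(m$variants, c(dso_ad2 = 2L, dso_dr1 = 2L))

  j <- tempfile(fileext = ".json")
  writeLines('{"gated": false, "require_exposure": true}', j)
  m2 <- read_mode_config(j)
  expect_false(m2$gated)
  expect_true(m2$require_exposure)
  expect_error(read_mode_config(tempfile(fileext = ".txt")), "not found")
})

test_that("command-line interface simulates deterministically and verifies tables", {
  cli <- system.file("cli", "itqcc.R", package = "itqcc")
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  wd <- tempfile("cli")
  dir.create(wd)
  run <- function(...) {
    suppressWarnings(system2(
      rscript, c(cli, ...), stdout = TRUE, stderr = TRUE,
      env = paste0("R_LIBS=", libs)))
  }
  old <- setwd(wd); on.exit(setwd(old))

  out1 <- run("simulate", "--n", "60", "--seed", "7", "--out-prefix", "a")
  out2 <- run("simulate", "--n", "60", "--seed", "7", "--out-prefix", "b")
  expect_identical(readLines("a_cohort.csv"), readLines("b_cohort.csv"))

  run("score", "--cohort", "a_cohort.csv", "--out", "dx.csv")
  dx <- utils::read.csv("dx.csv")
  expect_equal(nrow(dx), 60L)
  expect_true(all(dx$label_ungated %in% c("none", "PTSD", "CPTSD")))

  ref <- system.file("extdata", "reference_cluster_table.csv",
                     package = "itqcc")
  out <- run("verify", "--table", ref, "--level", "cluster",
             "--out", "v.csv")
  v <- utils::read.csv("v.csv")
  expect_equal(v$z_calc, v$z)

  # report on an empty cohort exits non-zero
  writeLines(readLines("a_cohort.csv")[1], "empty.csv")
  res <- suppressWarnings(system2(
    rscript, c(cli, "report", "--cohort", "empty.csv"),
    stdout = FALSE, stderr = FALSE, env = paste0("R_LIBS=", libs)))
  expect_true(res != 0)
})
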