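#' Parameters of the synthetic ITQ-CC cohort generator
#'
#' The generator emulates the data structure the ITQ-CC analysis assumes:
#' correlated latent PTSD and DSO severities, graded ordinal item responses,
#' a mixture of clinically true and false-positive endorsements, and
#' clinical-check answers whose pass probability depends on that truth
#' status. The data-generating model, per respondent `i` and item `j`:
#'
#' * Trauma exposure: a count of lifetime traumatic events, zero with
#'   probability `exposure_zero_prob`, otherwise `1 +` a negative-binomial
#'   draw with mean `exposure_mean_pos - 1` and dispersion
#'   `exposure_dispersion`, spread uniformly over the 21 ITEM event slots.
#' * Latent traits: `(theta_PTSD, theta_DSO)` bivariate standard normal
#'   with correlation `rho`, each shifted by
#'   `trauma_loading * log(1 + n_events)`.
#' * Item propensity: `theta(scale_j) + item_shifts[j] + N(0, sigma_item)`;
#'   the Likert score is the number of global `cutpoints` below the
#'   propensity (graded-response style).
#' * Truth status: an endorsement (score >= 2, i.e. propensity above
#'   `cutpoints[2]`) is a *true symptom* when the propensity also clears
#'   `cutpoints[2] + fp_width`, otherwise a *false positive*. `fp_width`
#'   therefore controls the share of endorsements that are false positives.
#' * Clinical checks: answered "yes" with probability `pass_true` for true
#'   symptoms and `pass_false` for false positives, independently across
#'   items; emitted only when the item is endorsed. The two dual-variant
#'   items draw both trial checks, with per-variant false-positive pass
#'   probabilities from `dual_pass_false` (their stringencies differ).
#'
#' Default values reproduce the marginal structure of the UK
#' general-population survey the instrument was evaluated in: 72.5% exposed
#' with mean 3.69 lifetime events; ungated item endorsement rates of
#' 24-36%; ungated prevalence near 5.4% (PTSD) and 9.5% (CPTSD);
#' check-induced item-level decreases of roughly 18-44%.
#'
#' @param n cohort size.
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @param rho correlation of the latent PTSD and DSO traits, in (-1, 1).
#' @param exposure_zero_prob probability of zero lifetime events.
#' @param exposure_mean_pos mean event count among the exposed (>= 1).
#' @param exposure_dispersion negative-binomial size parameter of the
#'   positive part.
#' @param trauma_loading effect of `log(1 + events)` on both latent traits.
#' @param sigma_item sd of the item-specific propensity noise.
#' @param cutpoints four increasing cutpoints mapping propensity to the 0-4
#'   Likert score; `cutpoints[2]` is the endorsement (score-2) threshold.
#' @param item_shifts named length-18 vector of per-item propensity shifts
#'   (item severity/prevalence differences).
#' @param fp_width width of the false-positive band above the endorsement
#'   threshold (>= 0).
#' @param pass_true check pass probability for true symptoms.
#' @param pass_false check pass probability for false positives
#'   (single-check items).
#' @param dual_pass_false list with entries `dso_ad2` and `dso_dr1`, each a
#'   length-2 vector of false-positive pass probabilities for check
#'   variants 1 and 2.
#' @return An object of class `cohort_params`.
#' @seealso [simulate_cohort()], [simulate_exposures()]
#' @export
cohort_params <- function(n = 975,
                          seed = NULL,
                          rho = 0.84,
                          exposure_zero_prob = 0.275,
                          exposure_mean_pos = 5.09,
                          exposure_dispersion = 1.35,
                          trauma_loading = 0.35,
                          sigma_item = 0.66,
                          cutpoints = c(0.4, 1.15, 1.95, 2.75),
                          item_shifts = NULL,
                          fp_width = 0.35,
                          pass_true = 0.95,
                          pass_false = 0.15,
                          dual_pass_false = list(
                            dso_ad2 = c(0.02, 0.30),
                            dso_dr1 = c(0.45, 0.22)
                          )) {
  if (is.null(item_shifts)) item_shifts <- .default_item_shifts()
  p <- list(
    n = as.integer(n), seed = seed, rho = rho,
    exposure_zero_prob = exposure_zero_prob,
    exposure_mean_pos = exposure_mean_pos,
    exposure_dispersion = exposure_dispersion,
    trauma_loading = trauma_loading,
    sigma_item = sigma_item,
    cutpoints = cutpoints,
    item_shifts = item_shifts,
    fp_width = fp_width,
    pass_true = pass_true,
    pass_false = pass_false,
    dual_pass_false = dual_pass_false
  )
  .validate_params(p)
  structure(p, class = "cohort_params")
}

.validate_params <- function(p) {
  reg <- itq_items()
  if (p$n < 1L) stop("n must be positive")
  if (!(p$rho > -1 && p$rho < 1)) stop("rho must be in (-1, 1)")
  if (p$exposure_zero_prob < 0 || p$exposure_zero_prob > 1) {
    stop("exposure_zero_prob must be in [0, 1]")
  }
  if (p$exposure_mean_pos < 1) {
    stop("exposure_mean_pos must be >= 1 (the exposed have >= 1 event)")
  }
  if (p$exposure_dispersion <= 0) stop("exposure_dispersion must be > 0")
  if (length(p$cutpoints) != 4L || is.unsorted(p$cutpoints, strictly = TRUE)) {
    stop("cutpoints must be 4 strictly increasing values")
  }
  if (p$sigma_item <= 0) stop("sigma_item must be > 0")
  if (p$fp_width < 0) stop("fp_width must be >= 0")
  probs <- c(p$pass_true, p$pass_false, unlist(p$dual_pass_false))
  if (any(probs < 0 | probs > 1)) {
    stop("check pass probabilities must be in [0, 1]")
  }
  if (!setequal(names(p$item_shifts), reg$item)) {
    stop("item_shifts must be named by the 18 ITQ item ids")
  }
  dual <- itq_dual_variant_items()
  if (!setequal(names(p$dual_pass_false), dual) ||
      !all(lengths(p$dual_pass_false) == 2L)) {
    stop("dual_pass_false must hold length-2 vectors for ",
         paste(dual, collapse = ", "))
  }
  invisible(p)
}

# Per-item propensity shifts giving the observed spread of ungated
# endorsement rates (about 24-36%) across the 18 items; impairment items
# sit lower individually so the any-of-three blocks land near 27-29%.
.default_item_shifts <- function() {
  c(
    ptsd_re1 = -0.082, ptsd_re2 = -0.102, ptsd_av1 = 0.049,
    ptsd_av2 = 0.001, ptsd_th1 = 0.189, ptsd_th2 = -0.098,
    ptsd_fi1 = -0.393, ptsd_fi2 = -0.527, ptsd_fi3 = -0.677,
    dso_ad1 = 0.282, dso_ad2 = 0.062, dso_nsc1 = -0.074,
    dso_nsc2 = -0.138, dso_dr1 = 0.023, dso_dr2 = 0.012,
    dso_fi1 = -0.323, dso_fi2 = -0.461, dso_fi3 = -0.616
  )
}

#' Simulate lifetime trauma-exposure indicators (ITEM)
#'
#' Draws per-respondent lifetime event counts (zero-inflated shifted
#' negative binomial, see [cohort_params()]) and places each respondent's
#' events uniformly at random over the 21 ITEM event slots.
#'
#' @param params a [cohort_params()] object; its `seed`, if non-`NULL`, is
#'   set before drawing.
#' @param n number of respondents (default `params$n`).
#' @return Integer 0/1 matrix `n` x 21 with columns `item01`..`item21`.
#' @export
#' @examples
#' ex <- simulate_exposures(cohort_params(n = 1000, seed = 1))
#' mean(rowSums(ex) > 0)  # close to 0.725
simulate_exposures <- function(params = cohort_params(), n = params$n) {
  .validate_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  .sim_exposures(params, n)
}

.sim_exposures <- function(params, n) {
  counts <- ifelse(
    stats::runif(n) < params$exposure_zero_prob,
    0L,
    1L + stats::rnbinom(n, size = params$exposure_dispersion,
                        mu = params$exposure_mean_pos - 1)
  )
  counts <- pmin(counts, 21L)
  mat <- matrix(0L, n, 21L, dimnames = list(NULL, itq_exposure_columns()))
  for (i in which(counts > 0L)) {
    mat[i, sample.int(21L, counts[i])] <- 1L
  }
  mat
}

#' Simulate a synthetic ITQ-CC cohort with ground truth
#'
#' Draws a full respondent-level cohort (exposures, 18 Likert items, all
#' clinical-check answers) from the latent-trait model described in
#' [cohort_params()], together with the ground truth the model knows but a
#' real survey does not: the latent trait values and, for every
#' endorsement, whether it was a true symptom or a false positive.
#'
#' @param params a [cohort_params()] object.
#' @return A list with
#'   * `cohort`: data.frame in the cohort CSV schema
#'     ([validate_cohort()]): `respondent_id`, 18 item columns, 20 check
#'     columns, `item01`..`item21`;
#'   * `truth`: data.frame with `respondent_id`, `theta_ptsd`, `theta_dso`,
#'     `n_events`, and per item a `truth_<item>` factor
#'     (`absent` / `true` / `false_positive`).
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_params(n = 200, seed = 42))
#' table(sim$truth$truth_ptsd_re1)
simulate_cohort <- function(params = cohort_params()) {
  .validate_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n
  reg <- itq_items()

  exposures <- .sim_exposures(params, n)
  n_events <- rowSums(exposures)
  shift <- params$trauma_loading * log1p(n_events)

  z1 <- stats::rnorm(n)
  z2 <- params$rho * z1 + sqrt(1 - params$rho^2) * stats::rnorm(n)
  theta <- cbind(PTSD = z1 + shift, DSO = z2 + shift)

  cut2 <- params$cutpoints[2L]
  clin <- cut2 + params$fp_width

  cohort <- data.frame(respondent_id = sprintf("R%06d", seq_len(n)),
                       stringsAsFactors = FALSE)
  truth <- data.frame(respondent_id = cohort$respondent_id,
                      theta_ptsd = theta[, "PTSD"],
                      theta_dso = theta[, "DSO"],
                      n_events = n_events,
                      stringsAsFactors = FALSE)
  checks <- list()

  for (j in seq_len(nrow(reg))) {
    it <- reg$item[j]
    prop <- theta[, reg$scale[j]] + params$item_shifts[[it]] +
      stats::rnorm(n, 0, params$sigma_item)
    score <- findInterval(prop, params$cutpoints)
    cohort[[it]] <- as.integer(score)
    status <- ifelse(prop >= clin, "true",
                     ifelse(prop >= cut2, "false_positive", "absent"))
    truth[[paste0("truth_", it)]] <-
      factor(status, levels = c("absent", "true", "false_positive"))

    endorsed <- score >= 2L
    variants <- if (reg$dual_variant[j]) 1:2 else 1L
    for (v in variants) {
      pf <- if (reg$dual_variant[j]) {
        params$dual_pass_false[[it]][v]
      } else {
        params$pass_false
      }
      pass_p <- ifelse(status == "true", params$pass_true, pf)
      ans <- rep(NA_character_, n)
      idx <- which(endorsed)
      if (length(idx)) {
        ans[idx] <- ifelse(stats::runif(length(idx)) < pass_p[idx],
                           "yes", "no")
      }
      checks[[itq_check_column(it, v)]] <- ans
    }
  }

  # canonical column order: primary checks for all items, then v2 checks
  for (col in itq_check_columns()) cohort[[col]] <- checks[[col]]
  cohort <- cbind(cohort, as.data.frame(exposures))
  list(cohort = cohort, truth = truth)
}

#' Recover check pass probabilities from simulated ground truth
#'
#' Validation utility for the generator: among endorsements whose truth
#' status is known, the maximum-likelihood estimate of the check pass
#' probability is the observed proportion of "yes" answers in each truth
#' stratum. Only the 16 single-check items are pooled: the dual-variant
#' items carry their own per-variant pass probabilities.
#'
#' @param cohort,truth the two components returned by [simulate_cohort()].
#' @return A data.frame with one row per stratum (`true`,
#'   `false_positive`): `estimate`, `se` (binomial), `n_yes`, `n`.
#' @export
recover_check_params <- function(cohort, truth) {
  reg <- itq_items()
  single <- reg$item[!reg$dual_variant]
  yes <- list(true = integer(), false_positive = integer())
  for (it in single) {
    ans <- cohort[[itq_check_column(it)]]
    status <- truth[[paste0("truth_", it)]]
    for (st in names(yes)) {
      sel <- !is.na(ans) & status == st
      yes[[st]] <- c(yes[[st]], ans[sel] == "yes")
    }
  }
  out <- do.call(rbind, lapply(names(yes), function(st) {
    nn <- length(yes[[st]])
    if (nn == 0L) {
      stop("no endorsements in stratum '", st,
           "': pass probability not estimable")
    }
    ph <- mean(yes[[st]])
    data.frame(stratum = st, estimate = ph,
               se = sqrt(ph * (1 - ph) / nn),
               n_yes = sum(yes[[st]]), n = nn,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
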