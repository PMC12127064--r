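#' Scoring mode: plain ITQ or clinical-check gated ITQ-CC
#'
#' A scoring mode bundles everything that decides how raw Likert responses
#' become symptom endorsements:
#'
#' * `gated = FALSE` scores the plain ITQ: an item is endorsed when its
#'   Likert score is 2 ("Moderately") or higher.
#' * `gated = TRUE` scores the ITQ-CC: an endorsement additionally requires
#'   a "yes" on the item's clinical check. Checks were only presented for
#'   endorsed items, so gating can only remove endorsements, never add them.
#' * `variants` selects which trial check to use for the two items that
#'   carried two checks. The final instrument keeps, for each, the check
#'   with the larger observed decrease: variant 1 for numbing (`dso_ad2`)
#'   and variant 2 for feeling cut off from others (`dso_dr1`).
#' * `missing` controls incomplete item data: `"strict"` (default) refuses
#'   to score a cohort with missing item scores; `"lenient"` treats a
#'   missing score as 0 (symptom absent) and records that choice in an
#'   attribute of the scoring output.
#' * `require_exposure` optionally restricts diagnosis to respondents
#'   reporting at least one traumatic event on the ITEM checklist; off by
#'   default so that prevalence denominators are the full cohort.
#'
#' @param gated logical; apply clinical-check gating?
#' @param variants named integer vector choosing the check variant for the
#'   dual-variant items; names must be `dso_ad2` and `dso_dr1`.
#' @param missing `"strict"` or `"lenient"`.
#' @param require_exposure logical; require >= 1 ITEM exposure for a
#'   non-`none` diagnosis.
#' @return An object of class `itq_mode`.
#' @seealso [itq_diagnose()], [itq_endorsement()]
#' @export
#' @examples
#' itq_mode()                 # plain ITQ
#' itq_mode(gated = TRUE)     # ITQ-CC with the final retained checks
itq_mode <- function(gated = FALSE,
                     variants = c(dso_ad2 = 1L, dso_dr1 = 2L),
                     missing = c("strict", "lenient"),
                     require_exposure = FALSE) {
  stopifnot(is.logical(gated), length(gated) == 1L, !is.na(gated),
            is.logical(require_exposure), length(require_exposure) == 1L)
  missing <- match.arg(missing)
  dual <- itq_dual_variant_items()
  variants <- variants[dual]
  names(variants) <- dual            # keep canonical order
  if (anyNA(variants) || !all(variants %in% 1:2)) {
    stop("variants must name both of ", paste(dual, collapse = ", "),
         " with values in {1, 2}")
  }
  structure(
    list(gated = gated,
         variants = structure(as.integer(variants), names = dual),
         missing = missing, require_exposure = require_exposure),
    class = "itq_mode"
  )
}

#' @export
print.itq_mode <- function(x, ...) {
  cat(if (x$gated) "ITQ-CC scoring mode (clinical-check gated)"
      else "ITQ scoring mode (ungated)", "\n")
  cat("  check variants: ",
      paste(names(x$variants), x$variants, sep = "=", collapse = ", "), "\n",
      sep = "")
  cat("  missing data: ", x$missing,
      "; exposure required: ", x$require_exposure, "\n", sep = "")
  invisible(x)
}

#' Read a scoring-mode configuration file
#'
#' Accepts a YAML or JSON file with any of the fields `gated`, `variants`
#' (a mapping from `dso_ad2`/`dso_dr1` to 1 or 2), `missing` and
#' `require_exposure`; unspecified fields take the [itq_mode()] defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An `itq_mode` object.
#' @export
read_mode_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the 'jsonlite' package is required to read JSON configs")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be a .yaml/.yml or .json file: ", path)
  }
  defaults <- itq_mode()
  variants <- defaults$variants
  if (!is.null(cfg$variants)) {
    v <- unlist(cfg$variants)
    variants[names(v)] <- as.integer(v)
  }
  itq_mode(
    gated = if (is.null(cfg$gated)) defaults$gated else isTRUE(cfg$gated),
    variants = variants,
    missing = if (is.null(cfg$missing)) defaults$missing else cfg$missing,
    require_exposure = if (is.null(cfg$require_exposure)) {
      defaults$require_exposure
    } else {
      isTRUE(cfg$require_exposure)
    }
  )
}
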