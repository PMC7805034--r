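#' Single-lesion RECIST 1.1 response category
#'
#' Anatomic response classification for a single target lesion from its
#' longest diameter before and after treatment:
#' * `CR` — post-treatment diameter 0 (lesion disappeared);
#' * `PR` — diameter change <= -30%;
#' * `PD` — change >= +20% **and** absolute increase >= 5 mm;
#' * `SD` — otherwise.
#'
#' Every non-negative input pair maps to exactly one category, and for fixed
#' baseline a smaller post-treatment diameter never yields a worse category.
#'
#' @param diameter_pre baseline longest diameter (mm), > 0.
#' @param diameter_post follow-up longest diameter (mm), >= 0.
#' @return Factor with levels `CR`, `PR`, `SD`, `PD` (vectorised).
#' @examples
#' recist_category(30, 21)   # PR (-30% boundary)
#' recist_category(20, 24)   # SD (+20% but +4 mm < 5 mm)
#' @export
recist_category <- function(diameter_pre, diameter_post) {
  if (any(diameter_pre <= 0)) stop("baseline diameter must be positive")
  if (any(diameter_post < 0)) stop("diameters must be non-negative")
  change <- 100 * (diameter_post - diameter_pre) / diameter_pre
  out <- rep("SD", length(change))
  out[change >= 20 & (diameter_post - diameter_pre) >= 5] <- "PD"
  out[change <= -30] <- "PR"
  out[diameter_post == 0] <- "CR"
  factor(out, levels = c("CR", "PR", "SD", "PD"))
}

#' Single-lesion PERCIST 1.0 metabolic response category
#'
#' Metabolic response classification from the lesion uptake (the package
#' applies the standard thresholds to whichever uptake measure is supplied,
#' `SUVmax` by default):
#' * `CMR` — post-treatment uptake at or below the background reference
#'   (`background`; when no reference is supplied, CMR is unreachable);
#' * `PMR` — change <= -30% **and** absolute decrease >= `min_decrease`;
#' * `PMD` — change >= +30%;
#' * `SMD` — otherwise.
#'
#' @param suv_pre baseline uptake (g/mL), > 0.
#' @param suv_post follow-up uptake (g/mL), >= 0.
#' @param background per-lesion background-reference uptake (g/mL) below
#'   which residual activity counts as complete metabolic response; `NA`
#'   (default) disables CMR.
#' @param min_decrease minimum absolute SUV decrease for PMR (default 0.8).
#' @return Factor with levels `CMR`, `PMR`, `SMD`, `PMD` (vectorised).
#' @examples
#' percist_category(10, 6.9)         # PMR
#' percist_category(2.0, 1.35)       # SMD (-32.5% but decrease 0.65 < 0.8)
#' @export
percist_category <- function(suv_pre, suv_post, background = NA_real_,
                             min_decrease = 0.8) {
  if (any(suv_pre <= 0)) stop("baseline uptake must be positive")
  if (any(suv_post < 0)) stop("uptake values must be non-negative")
  n <- max(length(suv_pre), length(suv_post))
  suv_pre <- rep_len(suv_pre, n)
  suv_post <- rep_len(suv_post, n)
  background <- rep_len(background, n)
  change <- 100 * (suv_post - suv_pre) / suv_pre
  out <- rep("SMD", n)
  out[change >= 30] <- "PMD"
  out[change <= -30 & (suv_pre - suv_post) >= min_decrease] <- "PMR"
  cmr <- !is.na(background) & suv_post <= background
  out[cmr] <- "CMR"
  factor(out, levels = c("CMR", "PMR", "SMD", "PMD"))
}

#' Binarize a response category as a pCR prediction
#'
#' Collapses the four-level category into the responder/non-responder
#' dichotomy used for pCR prediction: RECIST `CR`/`PR` or PERCIST
#' `CMR`/`PMR` predict pathologic complete response.
#'
#' @param category factor or character vector of categories from
#'   [recist_category()] or [percist_category()].
#' @return Logical vector: `TRUE` for predicted pCR.
#' @export
is_responder <- function(category) {
  category <- as.character(category)
  bad <- setdiff(unique(category), c("CR", "PR", "SD", "PD",
                                     "CMR", "PMR", "SMD", "PMD"))
  if (length(bad)) stop("unknown response category: ", paste(bad, collapse = ", "))
  category %in% c("CR", "PR", "CMR", "PMR")
}

#' Ordinal score of a response category
#'
#' Maps categories to an ordinal scale increasing with depth of response
#' (PD/PMD = 1 < SD/SMD = 2 < PR/PMR = 3 < CR/CMR = 4), for use as an
#' ROC score in [auc_ordinal()].
#'
#' @inheritParams is_responder
#' @return Integer scores 1-4.
#' @export
ordinal_score <- function(category) {
  category <- as.character(category)
  map <- c(PD = 1L, PMD = 1L, SD = 2L, SMD = 2L, PR = 3L, PMR = 3L,
           CR = 4L, CMR = 4L)
  if (any(!category %in% names(map))) stop("unknown response category")
  unname(map[category])
}

#' Classify a patient table under RECIST and PERCIST
#'
#' Adds response-criteria columns to a per-patient biomarker table containing
#' `diameter_pre`, `diameter_post`, `suv_pre`, `suv_post` (and optionally
#' `suv_background`): the RECIST and PERCIST categories, their binarized pCR
#' predictions and their ordinal scores.
#'
#' @param records data frame of patient records.
#' @param min_decrease passed to [percist_category()].
#' @return The input with columns `recist`, `percist`,
#'   `recist_responder`, `percist_responder`, `recist_score`,
#'   `percist_score` appended.
#' @export
classify_response <- function(records, min_decrease = 0.8) {
  needed <- c("diameter_pre", "diameter_post", "suv_pre", "suv_post")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  background <- records$suv_background %||% NA_real_
  records$recist <- recist_category(records$diameter_pre,
                                    records$diameter_post)
  records$percist <- percist_category(records$suv_pre, records$suv_post,
                                      background = background,
                                      min_decrease = min_decrease)
  records$recist_responder <- is_responder(records$recist)
  records$percist_responder <- is_responder(records$percist)
  records$recist_score <- ordinal_score(records$recist)
  records$percist_score <- ordinal_score(records$percist)
  records
}
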