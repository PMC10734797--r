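# Mapping between the clinician-recorded EDSS (0.0-9.5 in half steps) and
# the 10-step proxy scale, and the classifier groupings used for validation.

#' Rescale clinician-recorded EDSS scores to the proxy step grid
#'
#' From 1.0 to 7.5 every half-point score is converted to the lower whole
#' step (2.5 -> 2); from 8.0 to 9.5 scores are grouped as one class, encoded
#' `8` ("8plus"), since these steps reflect the same construct of daily-living
#' activity without ambulation. A score of 0.0 is not expected in validation
#' cohorts (where 0-valued proxies are imputed to 1 instead); if encountered
#' it is mapped to 1 with a warning so that both sides of a comparison share
#' the same domain. Scores 0.5 and 10.0 are not part of the scale and are
#' rejected.
#'
#' @param score numeric vector of EDSS values on the half-point grid
#'   (0.0, 1.0, 1.5, ..., 9.5).
#' @return integer vector of class values in 1..8 (8 = "8plus").
#' @export
rescale_edss <- function(score) {
  if (length(score) == 0L) return(integer(0))
  bad <- is.na(score) | score < 0 | score > 9.5 | (score * 2) %% 1 != 0 |
    score == 0.5
  if (any(bad))
    stop("EDSS score(s) off the 0.0/1.0-9.5 half-point grid: ",
         paste(utils::head(score[bad], 5), collapse = ", "))
  out <- integer(length(score))
  zero <- score == 0
  if (any(zero)) {
    warning("EDSS 0.0 encountered; mapped to class 1 (mirrors the proxy imputation)")
    out[zero] <- 1L
  }
  out[!zero] <- pmin(as.integer(floor(score[!zero])), 8L)
  out
}

#' Impute proxy scores of 0 to 1 for validation comparisons
#'
#' Validation cohorts from specialist MS centers contain no EDSS of 0.0, so a
#' claims-derived step of 0 is compared as 1. This is a property of the
#' validation pathway only; the engine itself does produce step 0.
#'
#' @param pedss integer vector of steps 0-9.
#' @return integer vector with 0 replaced by 1, all other values unchanged.
#' @export
impute_pedss <- function(pedss) {
  stopifnot(all(pedss %in% 0:9))
  out <- as.integer(pedss)
  out[out == 0L] <- 1L
  out
}

#' Labels of a classifier scheme
#'
#' @param scheme `"eightfold"` (each step 1-7 plus the `"8plus"` aggregate),
#'   `"threefold"` (`"1-3"`, `"4-5"`, `"6plus"`) or `"binary"`
#'   (`"lt6"`, `"ge6"`).
#' @return character vector of class labels in scale order.
#' @export
scheme_labels <- function(scheme = c("eightfold", "threefold", "binary")) {
  switch(match.arg(scheme),
         eightfold = c(as.character(1:7), "8plus"),
         threefold = c("1-3", "4-5", "6plus"),
         binary = c("lt6", "ge6"))
}

#' Map step values to classifier classes
#'
#' Accepts integer class values 1..9 (rescaled EDSS is 1..8; an imputed proxy
#' step can be 9, which falls into the top group of every scheme). Eightfold:
#' identity for 1-7, 8 and 9 -> `"8plus"`; threefold: 1-3 -> `"1-3"`,
#' 4-5 -> `"4-5"`, >=6 -> `"6plus"`; binary: <6 -> `"lt6"`, >=6 -> `"ge6"`.
#'
#' @param value integer vector in 1..9.
#' @param scheme classifier scheme, see [scheme_labels()].
#' @return character vector of class labels.
#' @export
edss_class <- function(value, scheme = c("eightfold", "threefold", "binary")) {
  scheme <- match.arg(scheme)
  if (length(value) == 0L) return(character(0))
  if (any(is.na(value) | value < 1 | value > 9 | value %% 1 != 0))
    stop("class values must be integers in 1..9")
  switch(scheme,
         eightfold = ifelse(value >= 8, "8plus", as.character(value)),
         threefold = ifelse(value <= 3, "1-3", ifelse(value <= 5, "4-5", "6plus")),
         binary = ifelse(value < 6, "lt6", "ge6"))
}

#' Numeric encoding of eightfold class values
#'
#' Encodes class labels back to numbers for error summaries: `"1"`..`"7"` to
#' themselves and `"8plus"` to 8, its lower bound, consistent with the
#' flooring convention of [rescale_edss()].
#'
#' @param label character vector of eightfold class labels.
#' @return numeric vector.
#' @export
class_numeric <- function(label) {
  if (length(label) == 0L) return(numeric(0))
  out <- ifelse(label == "8plus", 8, suppressWarnings(as.numeric(label)))
  if (any(is.na(out) | out < 1 | out > 8))
    stop("not eightfold class labels: ",
         paste(utils::head(label[is.na(out) | out < 1 | out > 8], 5), collapse = ", "))
  out
}
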