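# Code systems and controlled vocabularies used throughout the package.
CODE_SYSTEMS <- c("ICD10GM", "ATC", "AID", "OPS")
FUNCTIONAL_SYSTEMS <- c("visual", "brainstem", "pyramidal", "cerebellar",
                        "sensory", "bowel_bladder", "cerebral", "ambulation")
SEVERITIES <- c("mild", "moderate", "severe")
EVIDENCE_KINDS <- c("diagnosis", "medication", "therapy")
MATCH_MODES <- c("exact", "prefix")
SETTINGS <- c("inpatient_dx", "outpatient_dx", "prescription", "aid", "procedure")
QUALIFIERS <- c("confirmed", "suspected", "excluded", "status_post", "none")

#' Normalize a raw claims code
#'
#' Uppercases and trims a code string and strips a trailing German outpatient
#' diagnosis qualifier letter (`G` gesichert/confirmed, `V` suspected,
#' `A` excluded, `Z` status post) when it is separated from the code by
#' whitespace. The dot is retained (`"G82.12"`), all internal whitespace is
#' removed.
#'
#' @param raw character vector of raw code strings.
#' @param code_system one of `"ICD10GM"`, `"ATC"`, `"AID"`, `"OPS"`. Qualifier
#'   suffixes are only stripped for ICD-10-GM codes.
#' @return character vector of normalized codes. The stripped qualifier (if
#'   any) is available via [code_qualifier()].
#' @examples
#' normalize_code("g82.12 G")   # "G82.12"
#' normalize_code("  r26.3")    # "R26.3"
#' @seealso [code_qualifier()]
#' @export
normalize_code <- function(raw, code_system = "ICD10GM") {
  code_system <- match.arg(code_system, CODE_SYSTEMS)
  if (length(raw) == 0L) return(character(0))
  stopifnot(is.character(raw))
  x <- toupper(trimws(raw))
  if (code_system == "ICD10GM") {
    x <- sub("[[:space:]]+[GVAZ]$", "", x)
  }
  x <- gsub("[[:space:]]+", "", x)
  if (any(!nzchar(x))) {
    stop("invalid code: empty after normalization at position(s) ",
         paste(which(!nzchar(x)), collapse = ", "))
  }
  x
}

#' Extract the outpatient diagnosis qualifier from a raw code string
#'
#' German outpatient diagnoses carry a one-letter confirmation qualifier
#' appended to the ICD code (`"G35.1 G"`). This returns the qualifier as the
#' vocabulary used in event tables: `G` -> `"confirmed"`, `V` -> `"suspected"`,
#' `A` -> `"excluded"`, `Z` -> `"status_post"`, otherwise `"none"`.
#'
#' @param raw character vector of raw code strings.
#' @return character vector of qualifiers.
#' @export
code_qualifier <- function(raw) {
  x <- toupper(trimws(raw))
  suffix <- ifelse(grepl("[[:space:]]+[GVAZ]$", x),
                   substring(x, nchar(x)), NA_character_)
  map <- c(G = "confirmed", V = "suspected", A = "excluded", Z = "status_post")
  out <- unname(map[suffix])
  out[is.na(out)] <- "none"
  out
}

# TRUE where `code` is matched by `set` under prefix semantics (a set member
# is either the full code or a stem of it). Used for the fixed special-role
# code sets, whose ICD and aid codes are stems at the granularity printed.
match_code_set <- function(code, set) {
  if (length(code) == 0L) return(logical(0))
  vapply(code, function(cc) any(startsWith(cc, set)), logical(1), USE.NAMES = FALSE)
}
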