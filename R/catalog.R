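# Symptom catalog: the configurable mapping from claims codes to MS-related
# symptoms with a functional system, a severity tier and an evidence kind,
# plus the fixed special-role code sets that parameterize the rule cascade
# (fampridine, gait disturbance, plegias, bed confinement, ambulation aids).

#' Default special-role code sets
#'
#' The fixed code sets that drive the ambulation-related steps of the cascade:
#' fampridine (ATC N07XX07), gait disturbance (ICD-10-GM R26.0/R26.1/R26.2/
#' R26.8), paraplegia (G82.12, G82.22, G82.63, M62.3), tetraplegia (G82.42,
#' G82.52), bed confinement (R26.3), and the German Hilfsmittel product-group
#' stems for walking stick (10.50.01), wheelchair (18.50, 18.51) and
#' chair/specialty bed (19.40.01). Aid and ICD stems match by prefix.
#'
#' @return named list of character vectors.
#' @export
special_code_defaults <- function() {
  list(
    fampridine_atc      = "N07XX07",
    gait_disturbance_icd = c("R26.0", "R26.1", "R26.2", "R26.8"),
    paraplegia_icd      = c("G82.12", "G82.22", "G82.63", "M62.3"),
    tetraplegia_icd     = c("G82.42", "G82.52"),
    bed_confinement_icd = "R26.3",
    walking_stick_aid   = "10.50.01",
    wheelchair_aid      = c("18.50", "18.51"),
    chair_bed_aid       = "19.40.01"
  )
}

SPECIAL_SET_NAMES <- names(special_code_defaults())

#' Construct a symptom catalog
#'
#' @param entries data.frame with columns `code`, `code_system`, `match_mode`,
#'   `symptom_id`, `functional_system`, `severity`, `evidence_kind`. May have
#'   zero rows (the cascade is then driven by the special code sets only).
#' @param special named list of special-role code sets, see
#'   [special_code_defaults()] for the required names and defaults.
#' @param name,version catalog identification strings.
#' @return validated object of class `symptom_catalog`.
#' @export
symptom_catalog <- function(entries = empty_catalog_entries(),
                            special = special_code_defaults(),
                            name = "catalog", version = "1") {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  special <- lapply(special, function(s) normalize_code_any(s))
  cat <- structure(
    list(entries = entries, special = special,
         name = as.character(name), version = as.character(version)),
    class = "symptom_catalog")
  validate_catalog(cat)
}

# normalize each code under its own system-agnostic rules (no qualifier
# stripping needed for stored catalog codes, but trims/uppercases)
normalize_code_any <- function(x) {
  if (length(x) == 0L) return(character(0))
  gsub("[[:space:]]+", "", toupper(trimws(as.character(x))))
}

#' @export
empty_catalog_entries <- function() {
  data.frame(code = character(0), code_system = character(0),
             match_mode = character(0), symptom_id = character(0),
             functional_system = character(0), severity = character(0),
             evidence_kind = character(0), stringsAsFactors = FALSE)
}

#' Validate a symptom catalog
#'
#' Checks every catalog invariant: required columns; non-empty, uppercase,
#' whitespace-free codes; valid vocabulary values for code system, match mode,
#' functional system, severity and evidence kind; uniqueness of
#' (code, code_system, evidence_kind); consistency of code system and evidence
#' kind (an aid code cannot be diagnosis evidence, an ICD-10-GM code cannot be
#' medication evidence); and a complete special code set.
#'
#' @param catalog a `symptom_catalog`.
#' @return the catalog, invisibly usable, or an error describing the first
#'   violated invariant (naming the offending row where applicable).
#' @export
validate_catalog <- function(catalog) {
  if (!inherits(catalog, "symptom_catalog"))
    stop("not a symptom_catalog object")
  e <- catalog$entries
  required <- names(empty_catalog_entries())
  missing_cols <- setdiff(required, names(e))
  if (length(missing_cols))
    stop("catalog entries missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(e)) {
    bad <- which(!nzchar(e$code) | grepl("[[:space:]]", e$code) |
                   e$code != toupper(e$code))
    if (length(bad))
      stop("invalid code at entry row ", bad[1], ": ",
           dQuote(e$code[bad[1]]), " (must be non-empty, uppercase, no whitespace)")
    check_vocab(e$code_system, CODE_SYSTEMS, "code_system")
    check_vocab(e$match_mode, MATCH_MODES, "match_mode")
    check_vocab(e$functional_system, FUNCTIONAL_SYSTEMS, "functional_system")
    check_vocab(e$severity, SEVERITIES, "severity")
    check_vocab(e$evidence_kind, EVIDENCE_KINDS, "evidence_kind")
    key <- paste(e$code, e$code_system, e$evidence_kind, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate catalog entry at row ", which(duplicated(key))[1],
           ": (code, code_system, evidence_kind) must be unique, got (",
           e$code[which(duplicated(key))[1]], ", ",
           e$code_system[which(duplicated(key))[1]], ", ",
           e$evidence_kind[which(duplicated(key))[1]], ")")
    bad <- which(e$code_system == "AID" & e$evidence_kind == "diagnosis")
    if (length(bad))
      stop("entry row ", bad[1], ": AID codes cannot carry diagnosis evidence")
    bad <- which(e$code_system == "ICD10GM" & e$evidence_kind == "medication")
    if (length(bad))
      stop("entry row ", bad[1], ": ICD-10-GM codes cannot carry medication evidence")
  }
  s <- catalog$special
  missing_sets <- setdiff(SPECIAL_SET_NAMES, names(s))
  if (length(missing_sets))
    stop("special code set(s) missing: ", paste(missing_sets, collapse = ", "))
  for (nm in SPECIAL_SET_NAMES) {
    if (length(s[[nm]]) == 0L || any(!nzchar(s[[nm]])))
      stop("special code set ", nm, " is empty or contains empty codes")
  }
  catalog
}

check_vocab <- function(x, vocab, what) {
  bad <- which(!(x %in% vocab))
  if (length(bad))
    stop("unknown ", what, " at entry row ", bad[1], ": ", dQuote(x[bad[1]]),
         " (expected one of ", paste(vocab, collapse = ", "), ")")
  invisible(TRUE)
}

#' The shipped default symptom catalog
#'
#' Contains every code with a fixed, published role in the cascade (the
#' special code sets of [special_code_defaults()]) plus a demonstration set of
#' symptom entries across all severity tiers. The visual/brainstem exemplars
#' H49 (paralytic strabismus), H51 (other binocular movement disorder),
#' H53.278 (diplopia) and H55 (nystagmus) are included at the mild tier.
#' Severity tiers of entries outside the fixed sets are plausible placeholders
#' for demonstration and testing: the full symptom-to-code dictionary with
#' clinically adjudicated tiers is site-specific and should be supplied via
#' [read_catalog()] for production use. The spasticity rows illustrate
#' severity escalation by treatment: the clinical descriptor alone is mild,
#' the associated drug (baclofen, ATC M03BX01) is a moderate-tier medication,
#' and the interventional therapy (intrathecal pump, OPS 8-910) is severe.
#'
#' @return a validated `symptom_catalog`.
#' @export
default_catalog <- function() {
  entries <- rbind(
    catalog_entry("H49",     "ICD10GM", "prefix", "paralytic_strabismus",       "visual",       "mild",     "diagnosis"),
    catalog_entry("H51",     "ICD10GM", "prefix", "binocular_movement_disorder", "visual",      "mild",     "diagnosis"),
    catalog_entry("H53.278", "ICD10GM", "prefix", "diplopia",                   "visual",       "mild",     "diagnosis"),
    catalog_entry("H55",     "ICD10GM", "prefix", "nystagmus",                  "brainstem",    "mild",     "diagnosis"),
    catalog_entry("R20.2",   "ICD10GM", "prefix", "paraesthesia",               "sensory",      "mild",     "diagnosis"),
    catalog_entry("R25.2",   "ICD10GM", "prefix", "spasticity",                 "pyramidal",    "mild",     "diagnosis"),
    catalog_entry("N04BB01", "ATC",     "exact",  "fatigue",                    "cerebral",     "mild",     "medication"),
    catalog_entry("R27.0",   "ICD10GM", "prefix", "ataxia",                     "cerebellar",   "moderate", "diagnosis"),
    catalog_entry("N31.9",   "ICD10GM", "prefix", "neurogenic_bladder",         "bowel_bladder","moderate", "diagnosis"),
    catalog_entry("F06.7",   "ICD10GM", "prefix", "cognitive_impairment",       "cerebral",     "moderate", "diagnosis"),
    catalog_entry("R47.0",   "ICD10GM", "prefix", "aphasia",                    "cerebral",     "moderate", "diagnosis"),
    catalog_entry("M03BX01", "ATC",     "exact",  "spasticity",                 "pyramidal",    "moderate", "medication"),
    catalog_entry("G04BD04", "ATC",     "exact",  "neurogenic_bladder",         "bowel_bladder","moderate", "medication"),
    catalog_entry("G04BD07", "ATC",     "exact",  "neurogenic_bladder",         "bowel_bladder","moderate", "medication"),
    catalog_entry("R13.9",   "ICD10GM", "prefix", "dysphagia",                  "brainstem",    "severe",   "diagnosis"),
    catalog_entry("8-910",   "OPS",     "prefix", "spasticity",                 "pyramidal",    "severe",   "therapy")
  )
  symptom_catalog(entries, special_code_defaults(),
                  name = "pedss-default", version = "1")
}

#' Build a single catalog entry row
#'
#' Convenience constructor for assembling catalogs programmatically with
#' `rbind()`; fields as documented in [symptom_catalog()].
#'
#' @param code,code_system,match_mode,symptom_id,functional_system,severity,evidence_kind
#'   scalar character values.
#' @return one-row data.frame.
#' @export
catalog_entry <- function(code, code_system, match_mode, symptom_id,
                          functional_system, severity, evidence_kind) {
  data.frame(code = code, code_system = code_system, match_mode = match_mode,
             symptom_id = symptom_id, functional_system = functional_system,
             severity = severity, evidence_kind = evidence_kind,
             stringsAsFactors = FALSE)
}

#' Look up catalog entries matching a code
#'
#' Returns all entries of the given code system whose stored code equals the
#' query (exact mode) or is a prefix of the query (prefix mode, e.g. the entry
#' `H55` matches the query `H55.0`). Results are ordered by stored code length
#' descending, then lexicographically, so the most specific entry comes first.
#'
#' @param catalog a validated `symptom_catalog`.
#' @param code a single normalized code.
#' @param code_system the code system of the query.
#' @return data.frame of matching entries (zero rows when nothing matches).
#' @export
match_codes <- function(catalog, code, code_system) {
  stopifnot(inherits(catalog, "symptom_catalog"), length(code) == 1L)
  code_system <- match.arg(code_system, CODE_SYSTEMS)
  e <- catalog$entries
  if (!nrow(e)) return(e)
  hit <- e$code_system == code_system &
    ifelse(e$match_mode == "exact", e$code == code, startsWith(code, e$code))
  out <- e[hit, , drop = FALSE]
  out[order(-nchar(out$code), out$code), , drop = FALSE]
}

#' Read a symptom catalog from a YAML file
#'
#' The file holds the entries as a list of records (fields as in
#' [symptom_catalog()]) and the special code sets in a named `special`
#' section. [write_catalog()] produces this format; the two round-trip.
#'
#' @param path path to a YAML catalog file.
#' @return validated `symptom_catalog`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$special)) stop("catalog file lacks a 'special' section: ", path)
  entries <- empty_catalog_entries()
  if (length(doc$entries)) {
    rows <- lapply(seq_along(doc$entries), function(i) {
      r <- doc$entries[[i]]
      need <- names(empty_catalog_entries())
      miss <- setdiff(need, names(r))
      if (length(miss))
        stop("catalog entry ", i, " missing field(s): ", paste(miss, collapse = ", "))
      as.data.frame(r[need], stringsAsFactors = FALSE)
    })
    entries <- do.call(rbind, rows)
  }
  symptom_catalog(entries, special = doc$special,
                  name = doc$name %||% "catalog",
                  version = as.character(doc$version %||% "1"))
}

#' Write a symptom catalog to a YAML file
#'
#' @param catalog a validated `symptom_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  e <- catalog$entries
  entries <- if (nrow(e)) lapply(seq_len(nrow(e)), function(i) as.list(e[i, ])) else list()
  doc <- list(name = catalog$name, version = catalog$version,
              entries = entries, special = catalog$special)
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.symptom_catalog <- function(x, ...) {
  cat("Symptom catalog:", x$name, "version", x$version, "\n")
  e <- x$entries
  cat(sprintf("  %d code entries (%d diagnosis, %d medication, %d therapy)\n",
              nrow(e), sum(e$evidence_kind == "diagnosis"),
              sum(e$evidence_kind == "medication"),
              sum(e$evidence_kind == "therapy")))
  if (nrow(e)) {
    tab <- table(factor(e$severity, levels = SEVERITIES))
    cat("  severity tiers:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  cat("  special code sets:",
      paste(sprintf("%s[%d]", names(x$special), lengths(x$special)),
            collapse = ", "), "\n")
  invisible(x)
}
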