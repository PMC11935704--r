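#' Concept dictionaries: mapping raw clinical codes to named concepts
#'
#' Registry extracts carry raw diagnosis and procedure codes (in practice a
#' licensed hierarchical coding schema). The package abstracts the code lists
#' to a *concept dictionary*: raw codes map to named concepts, and concepts
#' carry pathway roles per sentinel diagnosis plus diagnosis/subgroup markers.
#' Real code lists plug in through the same file format.
#'
#' @param code_to_concept named character vector: raw code -> concept id.
#' @param concept_roles named list: diagnosis -> named character vector of
#'   concept id -> role (one of prepathway, stage1, stage2, stage3, repair,
#'   transplant, other).
#' @param diagnosis_markers named character vector: concept id -> sentinel
#'   diagnosis (or "not_sentinel" for recognized non-sentinel cardiac
#'   diagnoses).
#' @param comorbidity_concepts,prematurity_concepts character vectors of
#'   concept ids marking congenital noncardiac comorbidity and prematurity.
#' @param version version string captured for provenance.
#' @return An object of class `concept_dictionary`.
#' @export
concept_dictionary <- function(code_to_concept, concept_roles,
                               diagnosis_markers,
                               comorbidity_concepts = character(0),
                               prematurity_concepts = character(0),
                               version = "unversioned") {
  dict <- structure(
    list(code_to_concept = code_to_concept,
         concept_roles = concept_roles,
         diagnosis_markers = diagnosis_markers,
         comorbidity_concepts = comorbidity_concepts,
         prematurity_concepts = prematurity_concepts,
         version = version),
    class = "concept_dictionary")
  validate_concept_dictionary(dict)
  dict
}

VALID_ROLES <- c("prepathway", "stage1", "stage2", "stage3", "repair",
                 "transplant", "other")

validate_concept_dictionary <- function(dict) {
  codes <- names(dict$code_to_concept)
  if (anyDuplicated(codes)) {
    dup <- unique(codes[duplicated(codes)])
    conflict <- vapply(dup, function(cd) {
      length(unique(dict$code_to_concept[codes == cd])) > 1L
    }, logical(1))
    if (any(conflict)) {
      stopf("concept dictionary: duplicate code(s) with conflicting concepts: %s",
            paste(dup[conflict], collapse = ", "))
    }
  }
  for (dx in names(dict$concept_roles)) {
    roles <- dict$concept_roles[[dx]]
    bad <- setdiff(unique(roles), VALID_ROLES)
    if (length(bad)) {
      stopf("concept dictionary: unknown role(s) %s for diagnosis %s",
            paste(bad, collapse = ", "), dx)
    }
    if (anyDuplicated(names(roles))) {
      stopf("concept dictionary: concept mapped to more than one role for %s", dx)
    }
  }
  # Completeness: staged palliation roles must exist for diagnoses that can be
  # managed on a single-ventricle pathway; a reparative role for the rest.
  sv_capable <- intersect(c("HLHS", "FUH", "TGA", "PA", "AVSD"),
                          names(dict$concept_roles))
  for (dx in sv_capable) {
    need <- c("stage1", "stage2", "stage3")
    have <- unique(dict$concept_roles[[dx]])
    if (!all(need %in% have)) {
      stopf("concept dictionary: diagnosis %s is missing role(s) %s",
            dx, paste(setdiff(need, have), collapse = ", "))
    }
  }
  bv_capable <- intersect(c("TGA", "PA", "AVSD", "TOF", "AS", "COARCT", "VSD"),
                          names(dict$concept_roles))
  for (dx in bv_capable) {
    if (!"repair" %in% dict$concept_roles[[dx]]) {
      stopf("concept dictionary: diagnosis %s has no reparative role", dx)
    }
  }
  missing_markers <- setdiff(SENTINEL_DIAGNOSES, unname(dict$diagnosis_markers))
  if (length(missing_markers)) {
    stopf("concept dictionary: no marker concept for diagnosis group(s): %s",
          paste(missing_markers, collapse = ", "))
  }
  invisible(dict)
}

#' Load a concept dictionary from a YAML document
#'
#' The document stores codes as a sequence of `{code, concept}` pairs so that
#' duplicate codes (a load error when the concepts conflict) can be detected.
#'
#' @param path path to the YAML dictionary.
#' @return A [concept_dictionary()].
#' @export
load_concept_dictionary <- function(path) {
  if (!file.exists(path)) stopf("concept dictionary not found: %s", path)
  doc <- yaml::read_yaml(path)
  codes <- vapply(doc$codes, function(x) as.character(x$code), character(1))
  concepts <- vapply(doc$codes, function(x) as.character(x$concept), character(1))
  code_to_concept <- stats::setNames(concepts, codes)
  roles <- lapply(doc$roles, function(r) unlist(r))
  markers <- unlist(doc$diagnosis_markers)
  concept_dictionary(
    code_to_concept = code_to_concept,
    concept_roles = roles,
    diagnosis_markers = markers,
    comorbidity_concepts = as.character(doc$comorbidity_concepts %||% character(0)),
    prematurity_concepts = as.character(doc$prematurity_concepts %||% character(0)),
    version = as.character(doc$version %||% "unversioned"))
}

#' Bundled default concept dictionary
#'
#' A shippable synthetic stand-in for the licensed national code lists, with
#' the structure (diagnosis markers, subgroup modifiers, pathway roles per
#' diagnosis) the phenotyping and pathway rules require.
#' @return A [concept_dictionary()].
#' @export
default_concept_dictionary <- function() {
  load_concept_dictionary(
    system.file("extdata", "concepts.yaml", package = "sentinelchd",
                mustWork = TRUE))
}

# Translate raw semicolon-joined code cells to concept cells.
# Returns list(concepts = character vector of joined concepts,
#              untranslated = named integer counts of unknown codes).
translate_code_column <- function(cells, dict) {
  if (!length(cells)) {
    return(list(concepts = character(0), untranslated = table(character(0))))
  }
  cells <- as.character(cells)
  raw <- strsplit(ifelse(is.na(cells), "", cells), ";", fixed = TRUE)
  lens <- lengths(raw)
  flat <- unlist(raw, use.names = FALSE)
  keep <- nzchar(flat)
  idx <- rep.int(seq_along(raw), lens)[keep]
  flat <- flat[keep]
  mapped <- unname(dict$code_to_concept[flat])
  unknown <- flat[is.na(mapped)]
  known_idx <- idx[!is.na(mapped)]
  known <- mapped[!is.na(mapped)]
  out <- character(length(cells))
  if (length(known)) {
    joined <- vapply(split(known, factor(known_idx, levels = seq_along(cells))),
                     join_codes, character(1))
    out <- unname(joined)
  }
  list(concepts = out,
       untranslated = if (length(unknown)) table(unknown) else
         table(character(0)))
}

#' Role of a concept for a diagnosis
#' @param concept concept id (scalar or vector).
#' @param diagnosis sentinel diagnosis.
#' @param dictionary a [concept_dictionary()].
#' @return character vector of roles; concepts with no role for this
#'   diagnosis map to `"other"`.
#' @export
concept_role <- function(concept, diagnosis, dictionary) {
  roles <- dictionary$concept_roles[[diagnosis]]
  out <- unname(roles[concept])
  out[is.na(out)] <- "other"
  out
}

#' @export
print.concept_dictionary <- function(x, ...) {
  cat("<concept_dictionary> version", x$version, "\n")
  cat("  codes:", length(x$code_to_concept),
      " concepts:", length(unique(x$code_to_concept)), "\n")
  cat("  diagnoses with roles:", paste(names(x$concept_roles), collapse = ", "), "\n")
  invisible(x)
}

#' Load the classification ruleset
#'
#' The ruleset carries the diagnosis precedence order (decreasing clinical
#' complexity), per-diagnosis subgroup rules, the data-quality rules q1-q5,
#' and the modality grouping used to split reinterventions into surgical and
#' interventional-cardiology categories.
#'
#' @param path path to the ruleset YAML; defaults to the bundled ruleset.
#' @return An object of class `chd_ruleset`.
#' @export
load_ruleset <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ruleset.yaml", package = "sentinelchd",
                        mustWork = TRUE)
  }
  doc <- yaml::read_yaml(path)
  rs <- structure(
    list(version = as.character(doc$version %||% "unversioned"),
         precedence = as.character(doc$precedence),
         subgroup_rules = doc$subgroup_rules,
         quality_rules = doc$quality_rules,
         modality_groups = lapply(doc$modality_groups, unlist)),
    class = "chd_ruleset")
  validate_ruleset(rs)
  rs
}

KNOWN_QUALITY_RULES <- c("q1", "q2", "q3", "q4", "q5")

validate_ruleset <- function(rs) {
  if (!length(rs$precedence)) stopf("ruleset: empty diagnosis precedence")
  unknown <- setdiff(names(rs$quality_rules), KNOWN_QUALITY_RULES)
  if (length(unknown)) {
    stopf("ruleset: unknown quality rule id(s): %s",
          paste(unknown, collapse = ", "))
  }
  for (dx in names(rs$subgroup_rules)) {
    rules <- rs$subgroup_rules[[dx]]
    last <- rules[[length(rules)]]
    if (length(last$any_of %||% character(0)) ||
        length(last$all_of %||% character(0))) {
      stopf("ruleset: diagnosis %s has no residual (unconditional) subgroup", dx)
    }
  }
  invisible(rs)
}
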