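#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# CURIE handling shared by several validity methods

.curieRegex <- "^[A-Za-z][A-Za-z0-9.-]*:[^[:space:]]+$"

.isCurie <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && grepl(.curieRegex, x)
}

.curiePrefix <- function(id) sub(":.*$", "", id)

# ---------------------------------------------------------------------------
# OntologyTerm

#' OntologyTerm: an identifier + label couple from a named vocabulary
#'
#' The atomic annotation unit: a human-readable label coupled with a unique
#' CURIE identifier (`PREFIX:LOCAL`), plus the name of the source vocabulary
#' and an optional free-text description.
#'
#' @slot id CURIE string, e.g. `"MI:2235"`.
#' @slot label Non-empty human-readable text, e.g. `"up-regulates"`.
#' @slot vocabulary Name of the source vocabulary, e.g. `"PSI-MI"`.
#' @slot description Free text; may be empty.
#'
#' @examples
#' OntologyTerm("MI:2235", "up-regulates", "PSI-MI")
#' @export
setClass("OntologyTerm",
  representation(id = "character", label = "character",
                 vocabulary = "character", description = "character"),
  prototype(description = ""))

setValidity("OntologyTerm", function(object) {
  msg <- character()
  if (!.isCurie(object@id))
    msg <- c(msg, sprintf("id '%s' is not a CURIE (PREFIX:LOCAL)", object@id))
  if (length(object@label) != 1L || is.na(object@label) || !nzchar(object@label))
    msg <- c(msg, "label must be a non-empty string")
  if (length(object@vocabulary) != 1L || !nzchar(object@vocabulary))
    msg <- c(msg, "vocabulary name must be a non-empty string")
  if (length(msg)) msg else TRUE
})

#' @rdname OntologyTerm-class
#' @param id,label,vocabulary,description See slots.
#' @export
OntologyTerm <- function(id, label, vocabulary, description = "") {
  new("OntologyTerm", id = as.character(id), label = as.character(label),
      vocabulary = as.character(vocabulary),
      description = as.character(description))
}

setClassUnion("OntologyTermOrNULL", c("OntologyTerm", "NULL"))

#' @describeIn OntologyTerm-class CURIE identifier accessor.
#' @param object,x An `OntologyTerm`.
#' @export
termId <- function(x) x@id

#' @describeIn OntologyTerm-class Label accessor.
#' @export
termLabel <- function(x) x@label

#' @describeIn OntologyTerm-class Source vocabulary accessor.
#' @export
termVocabulary <- function(x) x@vocabulary

setMethod("show", "OntologyTerm", function(object) {
  cat(sprintf("OntologyTerm: %s (%s) [%s]\n",
              object@label, object@id, object@vocabulary))
})

# ---------------------------------------------------------------------------
# Vocabulary

#' Vocabulary: a named controlled vocabulary over one CURIE namespace
#'
#' @slot name Vocabulary name, e.g. `"PSI-MI"`.
#' @slot namespace CURIE prefix, e.g. `"MI"`; every contained term id must
#'   begin with this prefix.
#' @slot terms List of [OntologyTerm] with unique ids.
#'
#' @examples
#' Vocabulary("PSI-MI", "MI", list(OntologyTerm("MI:2235", "up-regulates", "PSI-MI")))
#' @export
setClass("Vocabulary",
  representation(name = "character", namespace = "character", terms = "list"))

setValidity("Vocabulary", function(object) {
  msg <- character()
  if (!nzchar(object@name)) msg <- c(msg, "name must be non-empty")
  if (!grepl("^[A-Za-z][A-Za-z0-9.-]*$", object@namespace))
    msg <- c(msg, "namespace must be a valid CURIE prefix")
  ok <- vapply(object@terms, is, logical(1), class2 = "OntologyTerm")
  if (!all(ok)) msg <- c(msg, "terms must all be OntologyTerm objects")
  else {
    ids <- vapply(object@terms, termId, character(1))
    bad <- !startsWith(ids, paste0(object@namespace, ":"))
    if (any(bad))
      msg <- c(msg, sprintf("term id '%s' does not start with namespace '%s:'",
                            ids[bad][1], object@namespace))
    if (anyDuplicated(ids))
      msg <- c(msg, "term ids must be unique within a vocabulary")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname Vocabulary-class
#' @param name,namespace,terms See slots.
#' @export
Vocabulary <- function(name, namespace, terms = list()) {
  new("Vocabulary", name = name, namespace = namespace, terms = terms)
}

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary '%s' (namespace %s): %d term(s)\n",
              object@name, object@namespace, length(object@terms)))
})

# ---------------------------------------------------------------------------
# VocabRegistry

#' VocabRegistry: offline registry of controlled vocabularies
#'
#' Unified access layer over registered vocabularies: identifier resolution
#' ([resolveTerm()]) and role-restricted prefix autocomplete
#' ([lookupTerms()]). "Virtual" namespaces (PubMed references, numeric
#' sequence positions) resolve open-ended local ids without enumerated
#' fixture terms. This is the offline default implementation of the
#' pluggable dictionary-lookup interface; a live client can implement the
#' same generics.
#'
#' @slot terms data.frame with columns id, label, vocabulary, description.
#' @slot vocabularies data.frame with columns name, namespace, virtual.
#' @slot roleMap Named list mapping each field role to the character vector
#'   of allowed vocabulary names.
#'
#' @seealso [fixtureRegistry()], [registerVocabulary()], [allowedVocabularies()]
#' @export
setClass("VocabRegistry",
  representation(terms = "data.frame", vocabularies = "data.frame",
                 roleMap = "list"))

setValidity("VocabRegistry", function(object) {
  msg <- character()
  if (!all(c("id", "label", "vocabulary", "description") %in%
           names(object@terms)))
    msg <- c(msg, "terms must have columns id, label, vocabulary, description")
  if (!all(c("name", "namespace", "virtual") %in% names(object@vocabularies)))
    msg <- c(msg, "vocabularies must have columns name, namespace, virtual")
  if (anyDuplicated(object@vocabularies$namespace))
    msg <- c(msg, "vocabulary namespaces must be unique")
  if (anyDuplicated(object@terms$id))
    msg <- c(msg, "term ids must be unique across the registry")
  if (length(msg)) msg else TRUE
})

setMethod("show", "VocabRegistry", function(object) {
  cat(sprintf("VocabRegistry: %d vocabularies, %d terms, %d roles\n",
              nrow(object@vocabularies), nrow(object@terms),
              length(object@roleMap)))
})

# ---------------------------------------------------------------------------
# Modification

#' Modification: a protein modification with optional subfeatures
#'
#' Residue and position exist only attached to a modification; they are
#' never free-standing annotation slots.
#'
#' @slot term Modification type, e.g. a phosphorylation [OntologyTerm].
#' @slot residue Modified residue term, or `NULL`.
#' @slot position 1-based sequence position (integer), or `NA` when absent.
#' @export
setClass("Modification",
  representation(term = "OntologyTerm", residue = "OntologyTermOrNULL",
                 position = "integer"),
  prototype(residue = NULL, position = NA_integer_))

setValidity("Modification", function(object) {
  if (length(object@position) != 1L)
    return("position must be a single integer (NA when absent)")
  if (!is.na(object@position) && object@position < 1L)
    return("position must be >= 1")
  TRUE
})

#' @rdname Modification-class
#' @param term,residue,position See slots.
#' @export
Modification <- function(term, residue = NULL, position = NA_integer_) {
  new("Modification", term = term, residue = residue,
      position = as.integer(position))
}

setMethod("show", "Modification", function(object) {
  sub <- c(if (!is.null(object@residue)) sprintf("residue=%s", object@residue@label),
           if (!is.na(object@position)) sprintf("position=%d", object@position))
  cat(sprintf("Modification: %s%s\n", object@term@label,
              if (length(sub)) paste0(" (", paste(sub, collapse = ", "), ")") else ""))
})

# ---------------------------------------------------------------------------
# BioEntity

#' BioEntity: a biological entity participating in a causal statement
#'
#' @slot id CURIE identifier (e.g. a UniProt accession CURIE).
#' @slot label Non-empty display label, e.g. `"AKT1_MOUSE"`.
#' @slot biologicalType Entity type term (e.g. protein), or `NULL`.
#' @slot modifications Ordered list of [Modification] (possibly empty).
#' @slot compartment Subcellular location term, or `NULL`.
#' @export
setClass("BioEntity",
  representation(id = "character", label = "character",
                 biologicalType = "OntologyTermOrNULL",
                 modifications = "list",
                 compartment = "OntologyTermOrNULL"),
  prototype(biologicalType = NULL, modifications = list(), compartment = NULL))

setValidity("BioEntity", function(object) {
  msg <- character()
  if (!.isCurie(object@id)) msg <- c(msg, "entity id must be a CURIE")
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "entity label must be non-empty")
  if (!all(vapply(object@modifications, is, logical(1), class2 = "Modification")))
    msg <- c(msg, "modifications must all be Modification objects")
  if (length(msg)) msg else TRUE
})

#' @rdname BioEntity-class
#' @param id,label,biologicalType,modifications,compartment See slots.
#' @export
BioEntity <- function(id, label, biologicalType = NULL,
                      modifications = list(), compartment = NULL) {
  new("BioEntity", id = id, label = label, biologicalType = biologicalType,
      modifications = modifications, compartment = compartment)
}

setClassUnion("BioEntityOrNULL", c("BioEntity", "NULL"))

setMethod("show", "BioEntity", function(object) {
  cat(sprintf("BioEntity: %s (%s), %d modification(s)\n",
              object@label, object@id, length(object@modifications)))
})

# ---------------------------------------------------------------------------
# CausalStatement

#' CausalStatement: a directed, contextualized molecular causal interaction
#'
#' A regulatory assertion that a source entity up- or down-regulates a
#' target entity, with its MI2CAST annotation: the mandatory core (source,
#' target, causal relation, at least one reference and one evidence term)
#' plus optional context. Slots for mandatory elements admit `NULL`/empty
#' so that incomplete statements can be represented and *reported on* by
#' [validateStatement()] rather than being unconstructible.
#'
#' @slot source,target The interacting [BioEntity] objects (`NULL` when
#'   missing).
#' @slot relation Causal relation [OntologyTerm] (PSI-MI or Relation
#'   Ontology), or `NULL`.
#' @slot references Character vector of publication CURIEs
#'   (e.g. `"pubmed:12345"`), curation order preserved.
#' @slot evidence Ordered list of evidence [OntologyTerm] (ECO).
#' @slot mechanism,compartment,cellLine,cellType,tissue,taxon Optional
#'   single-valued context terms, or `NULL`.
#' @export
setClass("CausalStatement",
  representation(source = "BioEntityOrNULL", target = "BioEntityOrNULL",
                 relation = "OntologyTermOrNULL",
                 references = "character", evidence = "list",
                 mechanism = "OntologyTermOrNULL",
                 compartment = "OntologyTermOrNULL",
                 cellLine = "OntologyTermOrNULL",
                 cellType = "OntologyTermOrNULL",
                 tissue = "OntologyTermOrNULL",
                 taxon = "OntologyTermOrNULL"),
  prototype(source = NULL, target = NULL, relation = NULL,
            references = character(), evidence = list(),
            mechanism = NULL, compartment = NULL, cellLine = NULL,
            cellType = NULL, tissue = NULL, taxon = NULL))

setValidity("CausalStatement", function(object) {
  msg <- character()
  bad <- !vapply(object@references, .isCurie, logical(1))
  if (length(object@references) && any(bad))
    msg <- c(msg, sprintf("reference '%s' is not a CURIE", object@references[bad][1]))
  if (!all(vapply(object@evidence, is, logical(1), class2 = "OntologyTerm")))
    msg <- c(msg, "evidence must be a list of OntologyTerm objects")
  if (length(msg)) msg else TRUE
})

#' @rdname CausalStatement-class
#' @param source,target,relation,references,evidence,mechanism,compartment
#'   See slots.
#' @param cellLine,cellType,tissue,taxon See slots.
#' @export
CausalStatement <- function(source = NULL, target = NULL, relation = NULL,
                            references = character(), evidence = list(),
                            mechanism = NULL, compartment = NULL,
                            cellLine = NULL, cellType = NULL,
                            tissue = NULL, taxon = NULL) {
  new("CausalStatement", source = source, target = target, relation = relation,
      references = as.character(references), evidence = evidence,
      mechanism = mechanism, compartment = compartment, cellLine = cellLine,
      cellType = cellType, tissue = tissue, taxon = taxon)
}

setMethod("show", "CausalStatement", function(object) {
  cat("CausalStatement\n  ", statementSummary(object), "\n", sep = "")
})

# ---------------------------------------------------------------------------
# ValidationReport

#' ValidationReport: outcome of MI2CAST compliance validation
#'
#' Wraps a data.frame of violations with columns `code`, `severity`
#' (`"ERROR"` or `"WARNING"`), `message` and `path` (field locator),
#' ordered by field path in the canonical field order. A statement
#' satisfies all mandatory MI2CAST rules iff the report carries zero
#' ERROR-severity rows.
#'
#' @slot violations The violations data.frame.
#' @seealso [validateStatement()], [violationCodes()]
#' @export
setClass("ValidationReport", representation(violations = "data.frame"))

setValidity("ValidationReport", function(object) {
  v <- object@violations
  if (!all(c("code", "severity", "message", "path") %in% names(v)))
    return("violations must have columns code, severity, message, path")
  if (nrow(v) && !all(v$severity %in% c("ERROR", "WARNING")))
    return("severity must be ERROR or WARNING")
  TRUE
})

#' @describeIn ValidationReport-class Extract the violations data.frame.
#' @param x,object A `ValidationReport`.
#' @export
violations <- function(x) x@violations

#' @describeIn ValidationReport-class Number of ERROR-severity violations.
#' @export
nErrors <- function(x) sum(x@violations$severity == "ERROR")

setMethod("show", "ValidationReport", function(object) {
  v <- object@violations
  if (!nrow(v)) {
    cat("ValidationReport: compliant (no violations)\n")
  } else {
    cat(sprintf("ValidationReport: %d ERROR(s), %d WARNING(s)\n",
                sum(v$severity == "ERROR"), sum(v$severity == "WARNING")))
    for (i in seq_len(nrow(v)))
      cat(sprintf("  [%s] %s at %s: %s\n", v$severity[i], v$code[i],
                  v$path[i], v$message[i]))
  }
})

# ---------------------------------------------------------------------------
# FeatureSelection

#' FeatureSelection: the selection-panel state that drives template generation
#'
#' Mirrors the configuration panel: per-side modification counters with a
#' subfeature subset (`"residue"`, `"position"`) for each modification,
#' per-side entity feature flags, statement-level (relation) feature flags,
#' and the reference/evidence multiplicity counters (always at least 1 —
#' these are mandatory).
#'
#' @slot sourceModifications,targetModifications List with one character
#'   vector per selected modification, each a subset of
#'   `c("residue", "position")`.
#' @slot sourceFlags,targetFlags Subset of `c("biological_type", "compartment")`.
#' @slot relationFlags Subset of `c("mechanism", "compartment", "cell_line",
#'   "cell_type", "tissue", "taxon")`.
#' @slot referenceCount,evidenceCount Integer counters, both `>= 1`.
#' @export
setClass("FeatureSelection",
  representation(sourceModifications = "list", targetModifications = "list",
                 sourceFlags = "character", targetFlags = "character",
                 relationFlags = "character",
                 referenceCount = "integer", evidenceCount = "integer"),
  prototype(sourceModifications = list(), targetModifications = list(),
            sourceFlags = character(), targetFlags = character(),
            relationFlags = character(),
            referenceCount = 1L, evidenceCount = 1L))

.entityFlagSet <- c("biological_type", "compartment")
.relationFlagSet <- c("mechanism", "compartment", "cell_line", "cell_type",
                      "tissue", "taxon")
.subfeatureSet <- c("residue", "position")

setValidity("FeatureSelection", function(object) {
  msg <- character()
  checkMods <- function(mods, side) {
    ok <- vapply(mods, function(m)
      is.character(m) && all(m %in% .subfeatureSet) && !anyDuplicated(m),
      logical(1))
    if (!all(ok))
      sprintf("%s modification subfeatures must be subsets of {residue, position}", side)
    else character()
  }
  msg <- c(msg, checkMods(object@sourceModifications, "source"),
           checkMods(object@targetModifications, "target"))
  if (!all(object@sourceFlags %in% .entityFlagSet) ||
      anyDuplicated(object@sourceFlags))
    msg <- c(msg, "sourceFlags must be a subset of {biological_type, compartment}")
  if (!all(object@targetFlags %in% .entityFlagSet) ||
      anyDuplicated(object@targetFlags))
    msg <- c(msg, "targetFlags must be a subset of {biological_type, compartment}")
  if (!all(object@relationFlags %in% .relationFlagSet) ||
      anyDuplicated(object@relationFlags))
    msg <- c(msg, "relationFlags must be a subset of the statement-context flags")
  if (length(object@referenceCount) != 1L || is.na(object@referenceCount) ||
      object@referenceCount < 1L)
    msg <- c(msg, "referenceCount must be >= 1 (references are mandatory)")
  if (length(object@evidenceCount) != 1L || is.na(object@evidenceCount) ||
      object@evidenceCount < 1L)
    msg <- c(msg, "evidenceCount must be >= 1 (evidence is mandatory)")
  if (length(msg)) msg else TRUE
})

#' @rdname FeatureSelection-class
#' @param sourceModifications,targetModifications,sourceFlags,targetFlags
#'   See slots.
#' @param relationFlags,referenceCount,evidenceCount See slots.
#' @export
FeatureSelection <- function(sourceModifications = list(),
                             targetModifications = list(),
                             sourceFlags = character(),
                             targetFlags = character(),
                             relationFlags = character(),
                             referenceCount = 1L, evidenceCount = 1L) {
  new("FeatureSelection",
      sourceModifications = lapply(sourceModifications, as.character),
      targetModifications = lapply(targetModifications, as.character),
      sourceFlags = as.character(sourceFlags),
      targetFlags = as.character(targetFlags),
      relationFlags = as.character(relationFlags),
      referenceCount = as.integer(referenceCount),
      evidenceCount = as.integer(evidenceCount))
}

setMethod("show", "FeatureSelection", function(object) {
  cat(sprintf(paste0("FeatureSelection: %d source / %d target modification(s), ",
                     "source flags {%s}, target flags {%s}, relation flags {%s}, ",
                     "%d reference(s), %d evidence\n"),
              length(object@sourceModifications),
              length(object@targetModifications),
              paste(object@sourceFlags, collapse = ","),
              paste(object@targetFlags, collapse = ","),
              paste(object@relationFlags, collapse = ","),
              object@referenceCount, object@evidenceCount))
})

# ---------------------------------------------------------------------------
# VsmSentence

#' VsmSentence: ordered VSM terms joined by trident connectors
#'
#' One unit of information in the Visual Syntax Method: an ordered list of
#' terms (filled annotation terms, prefilled relation terms, or empty
#' template fields awaiting input) plus trident connectors, each assigning
#' a (bearer, relation, argument) triple of term positions to one semantic
#' subunit. A VSM *template* is simply a sentence that still contains at
#' least one empty field.
#'
#' Terms are held as a data.frame with one row per term, in sentence order;
#' term positions are the 0-based row indices. Columns:
#' \describe{
#'   \item{variant}{`"filled"`, `"prefilled"` (relation term) or `"empty"`.}
#'   \item{label}{Readable text (`NA` for empty fields).}
#'   \item{id}{CURIE (`NA` for empty fields and prefilled relation terms).}
#'   \item{fieldId}{Stable opaque field token (`NA` for prefilled terms).}
#'   \item{role}{Field role driving placeholder and autocomplete
#'     restriction (`NA` for prefilled terms).}
#'   \item{placeholder}{Hint text shown while the field is empty.}
#' }
#'
#' @slot terms The term data.frame described above.
#' @slot connectors List of integer triples `c(bearer, relation, argument)`
#'   of 0-based term positions; endpoints are pairwise distinct and always
#'   attach to terms, never to other connectors.
#' @seealso [generateTemplate()], [fillField()], [toVsmJson()]
#' @export
setClass("VsmSentence",
  representation(terms = "data.frame", connectors = "list"))

setValidity("VsmSentence", function(object) {
  t <- object@terms
  need <- c("variant", "label", "id", "fieldId", "role", "placeholder")
  if (!all(need %in% names(t)))
    return(paste("terms must have columns", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(t)) {
    if (!all(t$variant %in% c("filled", "prefilled", "empty")))
      msg <- c(msg, "variant must be filled, prefilled or empty")
    filled <- t$variant == "filled"
    if (any(filled & (is.na(t$label) | is.na(t$id))))
      msg <- c(msg, "filled terms must carry both label and id")
    empty <- t$variant == "empty"
    if (any(empty & (is.na(t$placeholder) | !nzchar(t$placeholder))))
      msg <- c(msg, "empty fields must carry a non-empty placeholder")
    fids <- t$fieldId[!is.na(t$fieldId)]
    if (anyDuplicated(fids)) msg <- c(msg, "fieldId tokens must be unique")
  }
  n <- nrow(t)
  for (cn in object@connectors) {
    if (length(cn) != 3L) { msg <- c(msg, "connectors must be tridents of 3 endpoints"); break }
    if (any(cn < 0L) || any(cn >= n)) { msg <- c(msg, "connector endpoint out of term range"); break }
    if (anyDuplicated(cn)) { msg <- c(msg, "connector endpoints must be pairwise distinct"); break }
  }
  if (length(msg)) msg else TRUE
})

.emptyTermFrame <- function() {
  data.frame(variant = character(), label = character(), id = character(),
             fieldId = character(), role = character(),
             placeholder = character(), stringsAsFactors = FALSE)
}

#' @rdname VsmSentence-class
#' @param terms,connectors See slots.
#' @export
VsmSentence <- function(terms = .emptyTermFrame(), connectors = list()) {
  rownames(terms) <- NULL
  new("VsmSentence", terms = terms,
      connectors = lapply(connectors, as.integer))
}

#' @describeIn VsmSentence-class Term data.frame accessor.
#' @param x A `VsmSentence`.
#' @export
vsmTerms <- function(x) x@terms

#' @describeIn VsmSentence-class Connector list accessor.
#' @export
vsmConnectors <- function(x) x@connectors

#' @describeIn VsmSentence-class Annotatable fields (empty or filled terms,
#'   excluding prefilled relation terms), as a data.frame.
#' @export
annotatableFields <- function(x) {
  t <- x@terms
  t[t$variant != "prefilled", , drop = FALSE]
}

setMethod("show", "VsmSentence", function(object) {
  t <- object@terms
  nEmpty <- sum(t$variant == "empty")
  cat(sprintf("VsmSentence: %d term(s) (%d empty field(s)), %d connector(s)%s\n",
              nrow(t), nEmpty, length(object@connectors),
              if (nEmpty) " [template]" else ""))
  if (nrow(t)) {
    disp <- ifelse(t$variant == "empty", paste0("<", t$placeholder, ">"), t$label)
    cat("  ", paste(disp, collapse = " | "), "\n", sep = "")
  }
})
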