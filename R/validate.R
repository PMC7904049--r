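#' @include vocab.R
NULL

#' Violation codes emitted by the validator
#'
#' The enumeration is part of the public interface so downstream curation
#' platforms can map codes onto their own quality control: the five
#' missing-mandatory-element codes, `VOCAB_VIOLATION` (an ERROR: relation or
#' evidence term outside its allowed vocabularies) and
#' `UNEXPECTED_NAMESPACE` (a WARNING: optional context term outside the
#' vocabulary recommended for its slot).
#'
#' @return Character vector of the frozen code enumeration.
#' @export
violationCodes <- function() {
  c("MISSING_SOURCE", "MISSING_TARGET", "MISSING_RELATION",
    "MISSING_REFERENCE", "MISSING_EVIDENCE", "VOCAB_VIOLATION",
    "UNEXPECTED_NAMESPACE")
}

.termNamespaceOk <- function(registry, term, role) {
  voc <- .vocabForPrefix(registry, .curiePrefix(term@id))
  !is.null(voc) && voc$name %in% allowedVocabularies(role, registry)
}

.violation <- function(code, severity, message, path) {
  data.frame(code = code, severity = severity, message = message,
             path = path, stringsAsFactors = FALSE)
}

# Mandatory core: source, target, relation, >=1 reference, >=1 evidence.
# Namespace checks: ERROR on relation/evidence (the MI2CAST-restricted
# roles), WARNING on optional context. Rows are emitted in canonical field
# order so reports are deterministic.
#' @rdname validateStatement
setMethod("validateStatement", signature("CausalStatement", "VocabRegistry"),
  function(statement, registry) {
    v <- list()
    add <- function(x) v[[length(v) + 1L]] <<- x

    checkEntity <- function(entity, path) {
      if (!is.null(entity@biologicalType) &&
          !.termNamespaceOk(registry, entity@biologicalType, "biological_type"))
        add(.violation("UNEXPECTED_NAMESPACE", "WARNING",
          sprintf("biological type '%s' is outside the recommended vocabularies",
                  entity@biologicalType@id),
          paste0(path, ".biological_type")))
      for (i in seq_along(entity@modifications)) {
        m <- entity@modifications[[i]]
        mpath <- sprintf("%s.modifications[%d]", path, i)
        if (!.termNamespaceOk(registry, m@term, "biological_modification"))
          add(.violation("UNEXPECTED_NAMESPACE", "WARNING",
            sprintf("modification '%s' is outside the recommended vocabularies",
                    m@term@id), mpath))
        if (!is.null(m@residue) &&
            !.termNamespaceOk(registry, m@residue, "residue"))
          add(.violation("UNEXPECTED_NAMESPACE", "WARNING",
            sprintf("residue '%s' is outside the recommended vocabularies",
                    m@residue@id), paste0(mpath, ".residue")))
      }
      if (!is.null(entity@compartment) &&
          !.termNamespaceOk(registry, entity@compartment, "compartment"))
        add(.violation("UNEXPECTED_NAMESPACE", "WARNING",
          sprintf("compartment '%s' is outside the recommended vocabularies",
                  entity@compartment@id), paste0(path, ".compartment")))
    }

    if (is.null(statement@source))
      add(.violation("MISSING_SOURCE", "ERROR",
                     "a source entity is mandatory", "source"))
    else checkEntity(statement@source, "source")

    if (is.null(statement@target))
      add(.violation("MISSING_TARGET", "ERROR",
                     "a target entity is mandatory", "target"))
    else checkEntity(statement@target, "target")

    if (is.null(statement@relation))
      add(.violation("MISSING_RELATION", "ERROR",
                     "a causal relation is mandatory", "relation"))
    else if (!.termNamespaceOk(registry, statement@relation, "causal_relation"))
      add(.violation("VOCAB_VIOLATION", "ERROR",
        sprintf("relation '%s' is outside the allowed vocabularies (%s)",
                statement@relation@id,
                paste(allowedVocabularies("causal_relation", registry),
                      collapse = ", ")), "relation"))

    if (length(statement@references) == 0L)
      add(.violation("MISSING_REFERENCE", "ERROR",
                     "at least one reference must be provided", "references"))
    else for (i in seq_along(statement@references)) {
      if (.curiePrefix(statement@references[i]) != "pubmed")
        add(.violation("UNEXPECTED_NAMESPACE", "WARNING",
          sprintf("reference '%s' is not a pubmed CURIE",
                  statement@references[i]),
          sprintf("references[%d]", i)))
    }

    if (length(statement@evidence) == 0L)
      add(.violation("MISSING_EVIDENCE", "ERROR",
                     "at least one evidence type must be provided", "evidence"))
    else for (i in seq_along(statement@evidence)) {
      ev <- statement@evidence[[i]]
      if (!.termNamespaceOk(registry, ev, "evidence"))
        add(.violation("VOCAB_VIOLATION", "ERROR",
          sprintf("evidence '%s' is outside the allowed vocabularies (%s)",
                  ev@id,
                  paste(allowedVocabularies("evidence", registry),
                        collapse = ", ")),
          sprintf("evidence[%d]", i)))
    }

    ctx <- c(mechanism = "mechanism", compartment = "compartment",
             cellLine = "cell_line", cellType = "cell_type",
             tissue = "tissue", taxon = "taxon")
    for (slotName in names(ctx)) {
      term <- slot(statement, slotName)
      if (!is.null(term) && !.termNamespaceOk(registry, term, ctx[[slotName]]))
        add(.violation("UNEXPECTED_NAMESPACE", "WARNING",
          sprintf("%s '%s' is outside the recommended vocabularies",
                  ctx[[slotName]], term@id), ctx[[slotName]]))
    }

    df <- if (length(v)) do.call(rbind, v) else
      .violation(character(), character(), character(), character())
    new("ValidationReport", violations = df)
  })

#' @rdname validateStatement
setMethod("validateStatement", signature("CausalStatement", "missing"),
  function(statement, registry) validateStatement(statement, fixtureRegistry()))

#' @rdname isValid
setMethod("isValid", signature("CausalStatement", "VocabRegistry"),
  function(statement, registry) nErrors(validateStatement(statement, registry)) == 0L)

#' @rdname isValid
setMethod("isValid", signature("CausalStatement", "missing"),
  function(statement, registry) isValid(statement, fixtureRegistry()))

#' @rdname statementSummary
setMethod("statementSummary", "CausalStatement", function(statement) {
  srcLab <- if (is.null(statement@source)) "<missing source>" else
    statement@source@label
  tgtLab <- if (is.null(statement@target)) "<missing target>" else
    statement@target@label
  relLab <- if (is.null(statement@relation)) "<missing relation>" else
    statement@relation@label
  nCtx <- length(statement@evidence) +
    sum(!vapply(list(statement@mechanism, statement@compartment,
                     statement@cellLine, statement@cellType,
                     statement@tissue, statement@taxon), is.null, logical(1)))
  sprintf("%s —%s→ %s [%d context/evidence item(s)]",
          srcLab, relLab, tgtLab, nCtx)
})
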