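#' @include AllGenerics.R
NULL

#' Register a vocabulary with a registry
#'
#' Adds a [Vocabulary] to a [VocabRegistry] so that its terms become
#' resolvable and available to autocomplete lookup.
#'
#' @param registry A `VocabRegistry`.
#' @param vocab A `Vocabulary`.
#' @return The updated `VocabRegistry`.
#' @export
setGeneric("registerVocabulary", function(registry, vocab)
  standardGeneric("registerVocabulary"))

#' Autocomplete term lookup restricted to a field role
#'
#' @param registry A `VocabRegistry`.
#' @param query Character query string; the empty query matches nothing.
#' @param role A field role name (see [fieldRoles()]).
#' @param limit Maximum number of results (default 10).
#' @return A list of [OntologyTerm] objects, ranked: case-insensitive exact
#'   label matches first, then label-prefix matches, then substring matches,
#'   each tier ordered lexicographically by label (ties by id).
#' @export
setGeneric("lookupTerms", function(registry, query, role, limit = 10L)
  standardGeneric("lookupTerms"))

#' Resolve a canonical CURIE to its term
#'
#' @param registry A `VocabRegistry`.
#' @param id A CURIE in canonical `PREFIX:LOCAL` form (see [normalizeId()]).
#' @return The unique [OntologyTerm] with that id.
#' @export
setGeneric("resolveTerm", function(registry, id)
  standardGeneric("resolveTerm"))

#' Validate a causal statement against the MI2CAST mandatory rules
#'
#' @param statement A [CausalStatement].
#' @param registry A `VocabRegistry` used for namespace checks.
#' @return A [ValidationReport].
#' @export
setGeneric("validateStatement", function(statement, registry)
  standardGeneric("validateStatement"))

#' Does a statement satisfy all mandatory MI2CAST rules?
#'
#' @inheritParams validateStatement
#' @return `TRUE` iff [validateStatement()] reports zero ERROR-severity
#'   violations (warnings do not invalidate).
#' @export
setGeneric("isValid", function(statement, registry)
  standardGeneric("isValid"))

#' One-line human-readable rendering of a statement
#'
#' @param statement A [CausalStatement].
#' @return A character scalar `"SOURCE —relation→ TARGET [k context/evidence item(s)]"`.
#'   Purely presentational; carries no information-preservation guarantee.
#' @export
setGeneric("statementSummary", function(statement)
  standardGeneric("statementSummary"))

#' Generate a VSM template from a feature selection
#'
#' @param selection A [FeatureSelection].
#' @return A [VsmSentence] containing the five mandatory fields (multiplied
#'   by the reference/evidence counters) plus one empty field per selected
#'   optional feature or subfeature, with prefilled relation terms and
#'   trident connectors. Deterministic for a given selection.
#' @export
setGeneric("generateTemplate", function(selection)
  standardGeneric("generateTemplate"))

#' Add an optional feature field to a template
#'
#' @param template A [VsmSentence].
#' @param feature Role name of the feature to add.
#' @param anchor `fieldId` of the field the feature attaches to (an entity
#'   field for modifications/type/compartment, a modification field for
#'   residue/position, the causal-relation field for statement context,
#'   references and evidence).
#' @return The mutated template; all previously filled values are preserved.
#' @export
setGeneric("addFeature", function(template, feature, anchor)
  standardGeneric("addFeature"))

#' Remove an optional field (and its dependents) from a template
#'
#' @param template A [VsmSentence].
#' @param fieldId The field to remove. Removing a modification cascades to
#'   its residue/position subfeatures. Mandatory fields cannot be removed
#'   below their minimum multiplicity.
#' @return The mutated template.
#' @export
setGeneric("removeFeature", function(template, fieldId)
  standardGeneric("removeFeature"))

#' Fill an empty template field with a vocabulary term
#'
#' @param sentence A [VsmSentence].
#' @param fieldId Field to fill.
#' @param term An [OntologyTerm]; its vocabulary must be allowed for the
#'   field's role, otherwise the fill is rejected.
#' @param registry A `VocabRegistry` (vocabulary restriction source).
#' @return The sentence with the field filled (label + id).
#' @export
setGeneric("fillField", function(sentence, fieldId, term, registry)
  standardGeneric("fillField"))

#' Are all fields of a sentence filled?
#'
#' @param sentence A [VsmSentence].
#' @return `TRUE` iff no empty field remains.
#' @export
setGeneric("isComplete", function(sentence)
  standardGeneric("isComplete"))

#' Serialize a sentence to VSM-JSON
#'
#' @param sentence A [VsmSentence].
#' @param pretty Pretty-print the JSON?
#' @return JSON text (see `inst/schema/vsm-json.schema.json`).
#' @export
setGeneric("toVsmJson", function(sentence, pretty = FALSE)
  standardGeneric("toVsmJson"))

#' Serialize a sentence to VSM-JSON-light
#'
#' The light form is a projection of the full form: it keeps every id/label
#' couple and every connector but drops template-related data (placeholders,
#' autocomplete lookup configuration, field tokens). It is write-only.
#'
#' @inheritParams toVsmJson
#' @return JSON text.
#' @export
setGeneric("toVsmJsonLight", function(sentence, pretty = FALSE)
  standardGeneric("toVsmJsonLight"))

#' Interpret a completely filled sentence as a causal statement
#'
#' @param sentence A complete [VsmSentence] (see [isComplete()]).
#' @param registry A `VocabRegistry` used to recover vocabulary names and
#'   descriptions for filled ids (defaults to the bundled fixture registry).
#' @return A [CausalStatement] that passes [isValid()].
#' @export
setGeneric("sentenceToStatement", function(sentence, registry = fixtureRegistry())
  standardGeneric("sentenceToStatement"))

#' Render a valid statement as a filled VSM sentence
#'
#' Generates the template implied by the statement's populated slots and
#' fills it with the statement's terms; [sentenceToStatement()] inverts it.
#'
#' @param statement A valid [CausalStatement].
#' @return A filled [VsmSentence].
#' @export
setGeneric("statementToSentence", function(statement)
  standardGeneric("statementToSentence"))
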