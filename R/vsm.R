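#' @include template.R
NULL

#' @rdname fillField
setMethod("fillField",
  signature("VsmSentence", "character", "OntologyTerm", "VocabRegistry"),
  function(sentence, fieldId, term, registry) {
    t <- sentence@terms
    i <- match(fieldId, t$fieldId)
    if (is.na(i))
      stop("no field with id '", fieldId, "' in this sentence", call. = FALSE)
    role <- t$role[i]
    resolved <- resolveTerm(registry, term@id)  # term must be resolvable
    allowed <- allowedVocabularies(role, registry)
    if (!resolved@vocabulary %in% allowed)
      stop(sprintf(
        "term '%s' (%s) is not allowed for role '%s'; allowed vocabularies: %s",
        term@label, term@id, role, paste(allowed, collapse = ", ")),
        call. = FALSE)
    t$variant[i] <- "filled"
    t$label[i] <- term@label
    t$id[i] <- term@id
    sentence@terms <- t
    validObject(sentence)
    sentence
  })

#' @rdname isComplete
setMethod("isComplete", "VsmSentence", function(sentence) {
  !any(sentence@terms$variant == "empty")
})

# ---------------------------------------------------------------------------
# Interpretation: sentence -> statement

# Recover a full OntologyTerm for a filled (label, id) couple, preferring the
# registry's record (which restores vocabulary name and description); fall
# back to a prefix-named vocabulary for ids outside the registry.
.termFromFill <- function(registry, fill) {
  t <- tryCatch(resolveTerm(registry, fill$id), error = function(e) NULL)
  if (!is.null(t) && t@label == fill$label) return(t)
  voc <- .vocabForPrefix(registry, .curiePrefix(fill$id))
  OntologyTerm(fill$id, fill$label,
               if (!is.null(voc)) voc$name else .curiePrefix(fill$id))
}

.requireFill <- function(node, what) {
  if (is.null(node$fill))
    stop("sentence is not complete: empty ", what, " field (",
         node$fieldId, ")", call. = FALSE)
  node$fill
}

.bpEntity <- function(registry, node, what) {
  fill <- .requireFill(node, what)
  mods <- lapply(node$modifications, function(m) {
    mfill <- .requireFill(m, "modification")
    Modification(
      term = .termFromFill(registry, mfill),
      residue = if (is.null(m$residue)) NULL else
        .termFromFill(registry, .requireFill(m$residue, "residue")),
      position = if (is.null(m$position)) NA_integer_ else
        as.integer(.requireFill(m$position, "position")$label))
  })
  BioEntity(
    id = fill$id, label = fill$label,
    biologicalType = if (is.null(node$type)) NULL else
      .termFromFill(registry, .requireFill(node$type, "biological type")),
    modifications = mods,
    compartment = if (is.null(node$compartment)) NULL else
      .termFromFill(registry, .requireFill(node$compartment, "compartment")))
}

#' @rdname sentenceToStatement
setMethod("sentenceToStatement", "VsmSentence",
  function(sentence, registry = fixtureRegistry()) {
    if (!isComplete(sentence))
      stop("sentence still has empty fields; fill the template before ",
           "interpreting it as a causal statement", call. = FALSE)
    bp <- .sentenceToBlueprint(sentence)
    ctxTerm <- function(node)
      if (is.null(node)) NULL else
        .termFromFill(registry, .requireFill(node, "context"))
    CausalStatement(
      source = .bpEntity(registry, bp$source, "source entity"),
      target = .bpEntity(registry, bp$target, "target entity"),
      relation = .termFromFill(registry, .requireFill(bp$relation, "relation")),
      references = vapply(bp$references, function(r)
        .requireFill(r, "reference")$id, character(1)),
      evidence = lapply(bp$evidence, function(e)
        .termFromFill(registry, .requireFill(e, "evidence"))),
      mechanism = ctxTerm(bp$relctx$mechanism),
      compartment = ctxTerm(bp$relctx$compartment),
      cellLine = ctxTerm(bp$relctx$cell_line),
      cellType = ctxTerm(bp$relctx$cell_type),
      tissue = ctxTerm(bp$relctx$tissue),
      taxon = ctxTerm(bp$relctx$taxon))
  })

# ---------------------------------------------------------------------------
# Statement -> sentence

#' Infer the feature selection implied by a statement's populated slots
#'
#' @param statement A [CausalStatement].
#' @return The [FeatureSelection] whose generated template has exactly one
#'   field per populated slot of the statement.
#' @export
selectionFromStatement <- function(statement) {
  entityBits <- function(entity) {
    if (is.null(entity))
      return(list(flags = character(), mods = list()))
    flags <- c(if (!is.null(entity@biologicalType)) "biological_type",
               if (!is.null(entity@compartment)) "compartment")
    mods <- lapply(entity@modifications, function(m)
      c(if (!is.null(m@residue)) "residue",
        if (!is.na(m@position)) "position"))
    list(flags = as.character(flags), mods = mods)
  }
  src <- entityBits(statement@source)
  tgt <- entityBits(statement@target)
  relFlags <- c(
    if (!is.null(statement@mechanism)) "mechanism",
    if (!is.null(statement@compartment)) "compartment",
    if (!is.null(statement@cellLine)) "cell_line",
    if (!is.null(statement@cellType)) "cell_type",
    if (!is.null(statement@tissue)) "tissue",
    if (!is.null(statement@taxon)) "taxon")
  FeatureSelection(
    sourceModifications = src$mods, targetModifications = tgt$mods,
    sourceFlags = src$flags, targetFlags = tgt$flags,
    relationFlags = as.character(relFlags),
    referenceCount = max(1L, length(statement@references)),
    evidenceCount = max(1L, length(statement@evidence)))
}

.fillNode <- function(label, id) list(label = label, id = id)
.termFill <- function(term) .fillNode(term@label, term@id)

#' @rdname statementToSentence
setMethod("statementToSentence", "CausalStatement", function(statement) {
  if (!isValid(statement))
    stop("statement does not satisfy the mandatory MI2CAST rules; ",
         "see validateStatement()", call. = FALSE)
  bp <- .selectionToBlueprint(selectionFromStatement(statement))
  fillEntity <- function(node, entity) {
    node$fill <- .fillNode(entity@label, entity@id)
    if (!is.null(node$type)) node$type$fill <- .termFill(entity@biologicalType)
    if (!is.null(node$compartment))
      node$compartment$fill <- .termFill(entity@compartment)
    for (i in seq_along(entity@modifications)) {
      m <- entity@modifications[[i]]
      node$modifications[[i]]$fill <- .termFill(m@term)
      if (!is.null(node$modifications[[i]]$residue))
        node$modifications[[i]]$residue$fill <- .termFill(m@residue)
      if (!is.null(node$modifications[[i]]$position))
        node$modifications[[i]]$position$fill <-
          .fillNode(as.character(m@position), paste0("num:", m@position))
    }
    node
  }
  bp$source <- fillEntity(bp$source, statement@source)
  bp$target <- fillEntity(bp$target, statement@target)
  bp$relation$fill <- .termFill(statement@relation)
  ctx <- list(mechanism = statement@mechanism,
              compartment = statement@compartment,
              cell_line = statement@cellLine, cell_type = statement@cellType,
              tissue = statement@tissue, taxon = statement@taxon)
  for (f in names(ctx))
    if (!is.null(bp$relctx[[f]])) bp$relctx[[f]]$fill <- .termFill(ctx[[f]])
  for (i in seq_along(statement@references)) {
    ref <- statement@references[i]
    bp$references[[i]]$fill <- .fillNode(sub("^[^:]+:", "", ref), ref)
  }
  for (i in seq_along(statement@evidence))
    bp$evidence[[i]]$fill <- .termFill(statement@evidence[[i]])
  .bpToSentence(bp)
})
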