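#' @include validate.R
NULL

# ---------------------------------------------------------------------------
# Frozen prefilled relation-term labels. Each optional/mandatory feature
# hangs off its anchor through a trident whose relation endpoint is one of
# these constant terms; "has modif." is the label shown in the selection
# panel mock-up, the others are chosen for readability.

.relLabels <- c(
  biological_modification = "has modif.",
  residue                 = "has residue",
  position                = "at position",
  biological_type         = "is a",
  compartment             = "has compartment",
  mechanism               = "has mechanism",
  cell_line               = "in cell line",
  cell_type               = "in cell type",
  tissue                  = "in tissue",
  taxon                   = "in taxon",
  reference               = "reported in",
  evidence                = "has evidence")

.placeholders <- c(
  source_entity = "source entity", target_entity = "target entity",
  causal_relation = "causal relation", reference = "reference",
  evidence = "evidence", biological_modification = "modification",
  residue = "residue", position = "position",
  biological_type = "biological type", compartment = "compartment",
  mechanism = "mechanism", cell_line = "cell line",
  cell_type = "cell type", tissue = "tissue", taxon = "taxon")

# statement-context features in canonical (reading) order
.relctxOrder <- c("mechanism", "compartment", "cell_line", "cell_type",
                  "tissue", "taxon")

#' Subfeatures available under a feature role
#'
#' Modifications are the only parent feature: they can carry a modified
#' residue and a 1-based sequence position. All other roles have no
#' subfeatures.
#'
#' @param feature A role name from [fieldRoles()].
#' @return Character vector of subfeature role names (possibly empty).
#' @examples subfeaturesFor("biological_modification")
#' @export
subfeaturesFor <- function(feature) {
  if (!feature %in% fieldRoles())
    stop("unknown field role: '", feature, "'", call. = FALSE)
  if (feature == "biological_modification") c("residue", "position")
  else character()
}

# ---------------------------------------------------------------------------
# Blueprint: the internal structured form of a template sentence.
# A fieldNode is list(fieldId, fill) with fill NULL or list(label, id).

.newFieldCounter <- function(start = 1L) {
  env <- new.env(parent = emptyenv())
  env$n <- as.integer(start)
  env
}

.nextFieldId <- function(counter) {
  id <- paste0("f", counter$n)
  counter$n <- counter$n + 1L
  id
}

.fieldNode <- function(counter) list(fieldId = .nextFieldId(counter), fill = NULL)

.modNode <- function(counter, subfeatures) {
  node <- list(fieldId = .nextFieldId(counter), fill = NULL,
               residue = NULL, position = NULL)
  # canonical subfeature order: residue before position
  if ("residue" %in% subfeatures) node$residue <- .fieldNode(counter)
  if ("position" %in% subfeatures) node$position <- .fieldNode(counter)
  node
}

.entityNode <- function(counter, flags, modifications) {
  node <- list(fieldId = .nextFieldId(counter), fill = NULL,
               type = NULL, compartment = NULL, modifications = list())
  if ("biological_type" %in% flags) node$type <- .fieldNode(counter)
  if ("compartment" %in% flags) node$compartment <- .fieldNode(counter)
  node$modifications <- lapply(modifications, function(sf)
    .modNode(counter, sf))
  node
}

# Field ids are assigned in reading order: source block, relation, target
# block, statement context, references, evidence.
.selectionToBlueprint <- function(selection) {
  counter <- .newFieldCounter()
  bp <- list()
  bp$source <- .entityNode(counter, selection@sourceFlags,
                           selection@sourceModifications)
  bp$relation <- .fieldNode(counter)
  bp$target <- .entityNode(counter, selection@targetFlags,
                           selection@targetModifications)
  bp$relctx <- stats::setNames(vector("list", length(.relctxOrder)),
                               .relctxOrder)
  for (f in .relctxOrder)
    if (f %in% selection@relationFlags) bp$relctx[[f]] <- .fieldNode(counter)
  bp$references <- replicate(selection@referenceCount, .fieldNode(counter),
                             simplify = FALSE)
  bp$evidence <- replicate(selection@evidenceCount, .fieldNode(counter),
                           simplify = FALSE)
  bp$nextId <- counter$n
  bp
}

# ---------------------------------------------------------------------------
# Blueprint -> VsmSentence

.bpToSentence <- function(bp) {
  rows <- list()
  connectors <- list()
  addRow <- function(variant, label = NA_character_, id = NA_character_,
                     fieldId = NA_character_, role = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variant = variant, label = label, id = id, fieldId = fieldId,
      role = role,
      placeholder = if (is.na(role)) NA_character_ else
        unname(.placeholders[[role]]),
      stringsAsFactors = FALSE)
    length(rows) - 1L  # 0-based position
  }
  addField <- function(node, role) {
    if (is.null(node$fill))
      addRow("empty", fieldId = node$fieldId, role = role)
    else
      addRow("filled", label = node$fill$label, id = node$fill$id,
             fieldId = node$fieldId, role = role)
  }
  addTrident <- function(bearer, relation, argument) {
    connectors[[length(connectors) + 1L]] <<-
      as.integer(c(bearer, relation, argument))
  }
  # a feature = prefilled relation term + field, hung off its anchor
  addFeature <- function(anchorPos, role, node) {
    relPos <- addRow("prefilled", label = unname(.relLabels[[role]]))
    fieldPos <- addField(node, role)
    addTrident(anchorPos, relPos, fieldPos)
    fieldPos
  }
  addEntityBlock <- function(node, role) {
    entPos <- addField(node, role)
    if (!is.null(node$type))
      addFeature(entPos, "biological_type", node$type)
    if (!is.null(node$compartment))
      addFeature(entPos, "compartment", node$compartment)
    for (m in node$modifications) {
      modPos <- addFeature(entPos, "biological_modification", m)
      if (!is.null(m$residue)) addFeature(modPos, "residue", m$residue)
      if (!is.null(m$position)) addFeature(modPos, "position", m$position)
    }
    entPos
  }

  srcPos <- addEntityBlock(bp$source, "source_entity")
  relPos <- addField(bp$relation, "causal_relation")
  tgtPos <- addEntityBlock(bp$target, "target_entity")
  addTrident(srcPos, relPos, tgtPos)  # the core causal triple
  for (f in .relctxOrder)
    if (!is.null(bp$relctx[[f]])) addFeature(relPos, f, bp$relctx[[f]])
  for (r in bp$references) addFeature(relPos, "reference", r)
  for (e in bp$evidence) addFeature(relPos, "evidence", e)

  VsmSentence(do.call(rbind, rows), connectors)
}

# ---------------------------------------------------------------------------
# VsmSentence -> blueprint (inverse; the interpretation backbone)

.rowFieldNode <- function(t, pos) {
  i <- pos + 1L
  fill <- if (t$variant[i] == "filled")
    list(label = t$label[i], id = t$id[i]) else NULL
  list(fieldId = t$fieldId[i], fill = fill)
}

.sentenceToBlueprint <- function(sentence) {
  t <- sentence@terms
  cons <- sentence@connectors
  roleAt <- function(pos) t$role[pos + 1L]
  labelAt <- function(pos) t$label[pos + 1L]
  isPrefilled <- function(pos) t$variant[pos + 1L] == "prefilled"

  core <- NULL
  for (cn in cons) {
    if (!isPrefilled(cn[2]) && identical(roleAt(cn[2]), "causal_relation")) {
      if (!is.null(core))
        stop("sentence has more than one core causal triple", call. = FALSE)
      core <- cn
    }
  }
  if (is.null(core))
    stop("sentence has no core causal triple (source, causal relation, target)",
         call. = FALSE)
  srcPos <- core[1]; relPos <- core[2]; tgtPos <- core[3]
  if (!identical(roleAt(srcPos), "source_entity") ||
      !identical(roleAt(tgtPos), "target_entity"))
    stop("core triple endpoints are not source/target entity fields",
         call. = FALSE)

  entity <- function(pos) {
    node <- .rowFieldNode(t, pos)
    node$type <- NULL; node$compartment <- NULL
    node$modifications <- list()
    node
  }
  bp <- list(source = entity(srcPos), relation = .rowFieldNode(t, relPos),
             target = entity(tgtPos),
             relctx = stats::setNames(vector("list", length(.relctxOrder)),
                                      .relctxOrder),
             references = list(), evidence = list())

  # first pass: features anchored on the entities or the relation term
  modOwner <- list()   # key: as.character(mod term position) -> c("source"|"target", index)
  pending <- list()    # residue/position tridents, resolved in pass two
  refPos <- integer(); evPos <- integer()
  refNodes <- list(); evNodes <- list()

  sideOf <- function(pos) {
    if (pos == srcPos) "source" else if (pos == tgtPos) "target" else NA_character_
  }

  for (cn in cons) {
    if (identical(cn, core)) next
    b <- cn[1]; r <- cn[2]; a <- cn[3]
    if (!isPrefilled(r))
      stop("connector relation endpoint at position ", r,
           " is not a prefilled relation term", call. = FALSE)
    lab <- labelAt(r)
    role <- names(.relLabels)[match(lab, .relLabels)]
    if (is.na(role))
      stop("unrecognized relation term label '", lab, "'", call. = FALSE)
    side <- sideOf(b)
    if (role == "biological_modification") {
      if (is.na(side))
        stop("modification must attach to a source or target entity",
             call. = FALSE)
      node <- .rowFieldNode(t, a)
      node$residue <- NULL; node$position <- NULL
      node$.pos <- a
      bp[[side]]$modifications <- c(bp[[side]]$modifications, list(node))
      modOwner[[as.character(a)]] <- side
    } else if (role %in% c("residue", "position")) {
      pending[[length(pending) + 1L]] <- list(modPos = b, role = role,
                                              node = .rowFieldNode(t, a))
    } else if (role == "biological_type") {
      if (is.na(side)) stop("biological type must attach to an entity",
                            call. = FALSE)
      bp[[side]]$type <- .rowFieldNode(t, a)
    } else if (role == "compartment") {
      if (!is.na(side)) bp[[side]]$compartment <- .rowFieldNode(t, a)
      else if (b == relPos) bp$relctx$compartment <- .rowFieldNode(t, a)
      else stop("compartment must attach to an entity or the causal relation",
                call. = FALSE)
    } else if (role %in% .relctxOrder) {
      if (b != relPos)
        stop(role, " must attach to the causal relation", call. = FALSE)
      bp$relctx[[role]] <- .rowFieldNode(t, a)
    } else if (role == "reference") {
      refPos <- c(refPos, a); refNodes <- c(refNodes, list(.rowFieldNode(t, a)))
    } else if (role == "evidence") {
      evPos <- c(evPos, a); evNodes <- c(evNodes, list(.rowFieldNode(t, a)))
    }
  }

  # order repeated fields by sentence position (curation order)
  bp$references <- refNodes[order(refPos)]
  bp$evidence <- evNodes[order(evPos)]
  for (side in c("source", "target")) {
    mods <- bp[[side]]$modifications
    if (length(mods) > 1L)
      bp[[side]]$modifications <-
        mods[order(vapply(mods, function(m) m$.pos, integer(1)))]
  }

  # second pass: attach subfeatures to their own modification
  for (p in pending) {
    side <- modOwner[[as.character(p$modPos)]]
    if (is.null(side))
      stop("subfeature '", p$role, "' attaches to position ", p$modPos,
           ", which is not a modification field", call. = FALSE)
    mods <- bp[[side]]$modifications
    idx <- which(vapply(mods, function(m) m$.pos, integer(1)) == p$modPos)
    bp[[side]]$modifications[[idx]][[p$role]] <- p$node
  }
  for (side in c("source", "target"))
    bp[[side]]$modifications <- lapply(bp[[side]]$modifications,
                                       function(m) { m$.pos <- NULL; m })

  nums <- suppressWarnings(as.integer(sub("^f", "", t$fieldId)))
  bp$nextId <- if (all(is.na(nums))) 1L else max(nums, na.rm = TRUE) + 1L
  bp
}

# ---------------------------------------------------------------------------
# generateTemplate / addFeature / removeFeature

#' @rdname generateTemplate
setMethod("generateTemplate", "FeatureSelection", function(selection) {
  validObject(selection)
  .bpToSentence(.selectionToBlueprint(selection))
})

.bpFindAnchor <- function(bp, fieldId) {
  # returns list(kind, side, modIndex) describing where fieldId sits
  if (bp$source$fieldId == fieldId) return(list(kind = "entity", side = "source"))
  if (bp$target$fieldId == fieldId) return(list(kind = "entity", side = "target"))
  if (bp$relation$fieldId == fieldId) return(list(kind = "relation"))
  for (side in c("source", "target")) {
    mods <- bp[[side]]$modifications
    for (i in seq_along(mods))
      if (mods[[i]]$fieldId == fieldId)
        return(list(kind = "modification", side = side, modIndex = i))
  }
  NULL
}

#' @rdname addFeature
setMethod("addFeature", signature("VsmSentence", "character", "character"),
  function(template, feature, anchor) {
    bp <- .sentenceToBlueprint(template)
    counter <- .newFieldCounter(bp$nextId)
    at <- .bpFindAnchor(bp, anchor)
    if (is.null(at))
      stop("anchor '", anchor, "' is not an entity, relation or modification field",
           call. = FALSE)
    err <- function() stop("feature '", feature,
                           "' cannot be added at a ", at$kind, " field",
                           call. = FALSE)
    if (feature == "biological_modification") {
      if (at$kind != "entity") err()
      bp[[at$side]]$modifications <-
        c(bp[[at$side]]$modifications, list(.modNode(counter, character())))
    } else if (feature %in% c("residue", "position")) {
      if (at$kind != "modification") err()
      if (!is.null(bp[[at$side]]$modifications[[at$modIndex]][[feature]]))
        stop("modification already has a ", feature, " subfeature",
             call. = FALSE)
      bp[[at$side]]$modifications[[at$modIndex]][[feature]] <-
        .fieldNode(counter)
    } else if (feature == "biological_type") {
      if (at$kind != "entity") err()
      if (!is.null(bp[[at$side]]$type))
        stop("entity already has a biological type field", call. = FALSE)
      bp[[at$side]]$type <- .fieldNode(counter)
    } else if (feature == "compartment") {
      if (at$kind == "entity") {
        if (!is.null(bp[[at$side]]$compartment))
          stop("entity already has a compartment field", call. = FALSE)
        bp[[at$side]]$compartment <- .fieldNode(counter)
      } else if (at$kind == "relation") {
        if (!is.null(bp$relctx$compartment))
          stop("statement already has a compartment field", call. = FALSE)
        bp$relctx$compartment <- .fieldNode(counter)
      } else err()
    } else if (feature %in% .relctxOrder) {
      if (at$kind != "relation") err()
      if (!is.null(bp$relctx[[feature]]))
        stop("statement already has a ", feature, " field", call. = FALSE)
      bp$relctx[[feature]] <- .fieldNode(counter)
    } else if (feature == "reference") {
      if (at$kind != "relation") err()
      bp$references <- c(bp$references, list(.fieldNode(counter)))
    } else if (feature == "evidence") {
      if (at$kind != "relation") err()
      bp$evidence <- c(bp$evidence, list(.fieldNode(counter)))
    } else {
      stop("'", feature, "' is not an addable feature role", call. = FALSE)
    }
    .bpToSentence(bp)
  })

#' @rdname removeFeature
setMethod("removeFeature", signature("VsmSentence", "character"),
  function(template, fieldId) {
    bp <- .sentenceToBlueprint(template)
    if (fieldId %in% c(bp$source$fieldId, bp$target$fieldId,
                       bp$relation$fieldId))
      stop("cannot remove a mandatory source/target/relation field",
           call. = FALSE)
    found <- FALSE
    fidOf <- function(node) node$fieldId
    # references / evidence: removable only above the minimum multiplicity
    for (slot in c("references", "evidence")) {
      hit <- which(vapply(bp[[slot]], fidOf, character(1)) == fieldId)
      if (length(hit)) {
        if (length(bp[[slot]]) <= 1L)
          stop("cannot remove the sole ", sub("s$", "", slot),
               " field: at least one is mandatory", call. = FALSE)
        bp[[slot]] <- bp[[slot]][-hit]
        found <- TRUE
      }
    }
    for (f in .relctxOrder) {
      if (!found && !is.null(bp$relctx[[f]]) &&
          bp$relctx[[f]]$fieldId == fieldId) {
        bp$relctx[f] <- list(NULL)
        found <- TRUE
      }
    }
    for (side in c("source", "target")) {
      if (found) break
      ent <- bp[[side]]
      if (!is.null(ent$type) && ent$type$fieldId == fieldId) {
        bp[[side]]$type <- NULL; found <- TRUE; break
      }
      if (!is.null(ent$compartment) && ent$compartment$fieldId == fieldId) {
        bp[[side]]$compartment <- NULL; found <- TRUE; break
      }
      for (i in seq_along(ent$modifications)) {
        m <- ent$modifications[[i]]
        if (m$fieldId == fieldId) {
          # cascade: the modification's residue/position go with it
          bp[[side]]$modifications <- ent$modifications[-i]
          found <- TRUE; break
        }
        for (sf in c("residue", "position")) {
          if (!is.null(m[[sf]]) && m[[sf]]$fieldId == fieldId) {
            bp[[side]]$modifications[[i]][sf] <- list(NULL)
            found <- TRUE; break
          }
        }
        if (found) break
      }
    }
    if (!found)
      stop("no removable field with id '", fieldId, "'", call. = FALSE)
    .bpToSentence(bp)
  })

# ---------------------------------------------------------------------------
# Selection documents (JSON or YAML)

#' Read a feature selection from a JSON or YAML document
#'
#' The document mirrors [FeatureSelection]: see
#' `inst/schema/selection.schema.json` for the layout and
#' `inst/extdata/examples/` for examples. Modification entries are arrays of
#' subfeature names (one array per modification).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [FeatureSelection].
#' @export
readFeatureSelection <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  asChr <- function(x) as.character(unlist(x))
  mods <- function(side) {
    m <- doc[[side]]$modifications
    if (is.null(m)) list() else lapply(m, asChr)
  }
  flags <- function(side) {
    f <- doc[[side]]$flags
    if (is.null(f)) character() else asChr(f)
  }
  num <- function(key, default = 1L) {
    v <- doc[[key]]
    if (is.null(v)) default else as.integer(v)
  }
  FeatureSelection(
    sourceModifications = mods("source"),
    targetModifications = mods("target"),
    sourceFlags = flags("source"),
    targetFlags = flags("target"),
    relationFlags = if (is.null(doc$relation_flags)) character()
                    else asChr(doc$relation_flags),
    referenceCount = num("reference_count"),
    evidenceCount = num("evidence_count"))
}
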