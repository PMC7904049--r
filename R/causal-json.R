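#' @include vsm-json.R
NULL

# causal-JSON: the lossless statement interchange format. Top level is
# {"format_version", "statements": [...]}; every term serializes as an
# {"id", "label"} object (never a bare string) so the term + identifier
# couple survives the round trip. Layout documented in
# inst/schema/causal-json.schema.json.

.causalJsonVersion <- "1.0"

.termObj <- function(term) list(id = term@id, label = term@label)

.entityToList <- function(entity) {
  out <- list(id = entity@id, label = entity@label)
  if (!is.null(entity@biologicalType))
    out$biological_type <- .termObj(entity@biologicalType)
  if (length(entity@modifications))
    out$modifications <- lapply(entity@modifications, function(m) {
      mo <- list(term = .termObj(m@term))
      if (!is.null(m@residue)) mo$residue <- .termObj(m@residue)
      if (!is.na(m@position)) mo$position <- m@position
      mo
    })
  if (!is.null(entity@compartment))
    out$compartment <- .termObj(entity@compartment)
  out
}

.statementToList <- function(statement) {
  out <- list(
    source = .entityToList(statement@source),
    target = .entityToList(statement@target),
    relation = .termObj(statement@relation),
    references = lapply(statement@references, function(r) list(id = r)),
    evidence = lapply(statement@evidence, .termObj))
  ctx <- list(mechanism = statement@mechanism,
              compartment = statement@compartment,
              cell_line = statement@cellLine, cell_type = statement@cellType,
              tissue = statement@tissue, taxon = statement@taxon)
  for (key in names(ctx))
    if (!is.null(ctx[[key]])) out[[key]] <- .termObj(ctx[[key]])
  out
}

#' Write statements as causal-JSON
#'
#' @param statements A list of valid [CausalStatement] objects (a single
#'   statement is accepted too).
#' @param registry Registry used to validate before export.
#' @param pretty Pretty-print the JSON?
#' @return causal-JSON text.
#' @seealso [readCausalJson()]
#' @export
writeCausalJson <- function(statements, registry = fixtureRegistry(),
                            pretty = FALSE) {
  if (is(statements, "CausalStatement")) statements <- list(statements)
  for (i in seq_along(statements)) {
    rep <- validateStatement(statements[[i]], registry)
    if (nErrors(rep) > 0L) {
      v <- violations(rep)
      codes <- v$code[v$severity == "ERROR"]
      stop("statement ", i, " fails MI2CAST validation: ",
           paste(codes, collapse = ", "), call. = FALSE)
    }
  }
  doc <- list(format_version = .causalJsonVersion,
              statements = lapply(statements, .statementToList))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = pretty))
}

# --- reading -----------------------------------------------------------------

.jsonPathStop <- function(path, msg)
  stop(path, ": ", msg, call. = FALSE)

.checkKnownKeys <- function(x, known, path) {
  extra <- setdiff(names(x), known)
  if (length(extra))
    warning(path, ": unknown key(s) ", paste(extra, collapse = ", "),
            " ignored", call. = FALSE)
}

.parseTermObj <- function(x, registry, path) {
  if (!is.list(x)) .jsonPathStop(path, "expected an {id, label} object")
  .checkKnownKeys(x, c("id", "label"), path)
  if (is.null(x$id)) .jsonPathStop(paste0(path, ".id"), "missing")
  if (is.null(x$label)) .jsonPathStop(paste0(path, ".label"), "missing")
  .termFromFill(registry, list(label = as.character(x$label),
                               id = as.character(x$id)))
}

.parseEntity <- function(x, registry, path) {
  if (!is.list(x)) .jsonPathStop(path, "expected an entity object")
  .checkKnownKeys(x, c("id", "label", "biological_type", "modifications",
                       "compartment"), path)
  if (is.null(x$id)) .jsonPathStop(paste0(path, ".id"), "missing")
  if (is.null(x$label)) .jsonPathStop(paste0(path, ".label"), "missing")
  mods <- lapply(seq_along(x$modifications), function(i) {
    m <- x$modifications[[i]]
    mpath <- sprintf("%s.modifications[%d]", path, i)
    .checkKnownKeys(m, c("term", "residue", "position"), mpath)
    if (is.null(m$term)) .jsonPathStop(paste0(mpath, ".term"), "missing")
    Modification(
      term = .parseTermObj(m$term, registry, paste0(mpath, ".term")),
      residue = if (is.null(m$residue)) NULL else
        .parseTermObj(m$residue, registry, paste0(mpath, ".residue")),
      position = if (is.null(m$position)) NA_integer_ else
        as.integer(m$position))
  })
  BioEntity(
    id = as.character(x$id), label = as.character(x$label),
    biologicalType = if (is.null(x$biological_type)) NULL else
      .parseTermObj(x$biological_type, registry,
                    paste0(path, ".biological_type")),
    modifications = mods,
    compartment = if (is.null(x$compartment)) NULL else
      .parseTermObj(x$compartment, registry, paste0(path, ".compartment")))
}

.statementKeys <- c("source", "target", "relation", "references", "evidence",
                    "mechanism", "compartment", "cell_line", "cell_type",
                    "tissue", "taxon")

.parseStatement <- function(x, registry, path) {
  if (!is.list(x)) .jsonPathStop(path, "expected a statement object")
  .checkKnownKeys(x, .statementKeys, path)
  for (key in c("source", "target", "relation", "references", "evidence"))
    if (is.null(x[[key]]))
      .jsonPathStop(paste0(path, ".", key), "missing mandatory element")
  refs <- vapply(seq_along(x$references), function(i) {
    r <- x$references[[i]]
    rpath <- sprintf("%s.references[%d]", path, i)
    if (!is.list(r) || is.null(r$id)) .jsonPathStop(rpath, "expected {id}")
    as.character(r$id)
  }, character(1))
  ctx <- function(key) {
    if (is.null(x[[key]])) NULL else
      .parseTermObj(x[[key]], registry, paste0(path, ".", key))
  }
  CausalStatement(
    source = .parseEntity(x$source, registry, paste0(path, ".source")),
    target = .parseEntity(x$target, registry, paste0(path, ".target")),
    relation = .parseTermObj(x$relation, registry, paste0(path, ".relation")),
    references = refs,
    evidence = lapply(seq_along(x$evidence), function(i)
      .parseTermObj(x$evidence[[i]], registry,
                    sprintf("%s.evidence[%d]", path, i))),
    mechanism = ctx("mechanism"), compartment = ctx("compartment"),
    cellLine = ctx("cell_line"), cellType = ctx("cell_type"),
    tissue = ctx("tissue"), taxon = ctx("taxon"))
}

#' Read causal-JSON into causal statements
#'
#' Structural schema violations raise an error naming the JSON path;
#' unknown keys are tolerated with a warning. The inverse of
#' [writeCausalJson()]: `readCausalJson(writeCausalJson(S))` reconstructs
#' `S` exactly for statements whose terms come from the registry.
#'
#' @param text causal-JSON text, or a path to a `.causal.json` file.
#' @param registry Registry used to restore vocabulary names and
#'   descriptions for term ids.
#' @return List of [CausalStatement].
#' @export
readCausalJson <- function(text, registry = fixtureRegistry()) {
  if (length(text) == 1L && !grepl("[{\n]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed JSON: ", conditionMessage(e),
                         call. = FALSE))
  if (is.null(doc$format_version))
    .jsonPathStop("format_version", "missing")
  if (is.null(doc$statements) || !is.list(doc$statements))
    .jsonPathStop("statements", "missing or not an array")
  .checkKnownKeys(doc, c("format_version", "statements"), "$")
  lapply(seq_along(doc$statements), function(i)
    .parseStatement(doc$statements[[i]], registry,
                    sprintf("statements[%d]", i)))
}
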