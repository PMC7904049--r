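#' @include vsm.R
NULL

.vsmJsonVersion <- "1.0"

.termToJsonList <- function(t, i, light = FALSE) {
  out <- list(position = i - 1L, variant = t$variant[i])
  if (!is.na(t$label[i])) out$label <- t$label[i]
  if (!is.na(t$id[i])) out$id <- t$id[i]
  if (light) {
    # the light projection keeps ids, labels and (for still-empty fields)
    # the role, but no template data: no placeholder, lookup config or
    # field token
    if (t$variant[i] == "empty" && !is.na(t$role[i])) out$role <- t$role[i]
    return(out)
  }
  if (!is.na(t$fieldId[i])) out$fieldId <- t$fieldId[i]
  if (!is.na(t$role[i])) {
    out$role <- t$role[i]
    out$lookup <- list(roles = I(t$role[i]))
  }
  if (!is.na(t$placeholder[i])) out$placeholder <- t$placeholder[i]
  out
}

.sentenceToJsonList <- function(sentence, light = FALSE) {
  t <- sentence@terms
  list(
    format = if (light) "vsm-json-light" else "vsm-json",
    version = .vsmJsonVersion,
    terms = lapply(seq_len(nrow(t)), function(i)
      .termToJsonList(t, i, light = light)),
    connectors = lapply(sentence@connectors, as.integer))
}

#' @rdname toVsmJson
setMethod("toVsmJson", "VsmSentence", function(sentence, pretty = FALSE) {
  as.character(jsonlite::toJSON(.sentenceToJsonList(sentence, light = FALSE),
                                auto_unbox = TRUE, pretty = pretty))
})

#' @rdname toVsmJsonLight
setMethod("toVsmJsonLight", "VsmSentence", function(sentence, pretty = FALSE) {
  as.character(jsonlite::toJSON(.sentenceToJsonList(sentence, light = TRUE),
                                auto_unbox = TRUE, pretty = pretty))
})

#' Parse a VSM-JSON document into a sentence
#'
#' Reads the package's documented VSM-JSON dialect (see
#' `inst/schema/vsm-json.schema.json`). The light form is a lossy
#' projection and cannot be read back.
#'
#' @param text JSON text, or a path to a `.vsm.json` file.
#' @return A [VsmSentence] satisfying all sentence invariants.
#' @export
fromVsmJson <- function(text) {
  if (length(text) == 1L && !grepl("[{\n]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed JSON: ", conditionMessage(e),
                         call. = FALSE))
  if (identical(doc$format, "vsm-json-light"))
    stop("vsm-json-light is a lossy projection and cannot be parsed back; ",
         "use the full vsm-json form", call. = FALSE)
  if (!identical(doc$format, "vsm-json"))
    stop("not a vsm-json document (missing or wrong \"format\" key)",
         call. = FALSE)
  if (is.null(doc$terms) || !is.list(doc$terms))
    stop("vsm-json document has no \"terms\" array", call. = FALSE)

  n <- length(doc$terms)
  pos <- vapply(doc$terms, function(x) {
    if (is.null(x$position)) NA_integer_ else as.integer(x$position)
  }, integer(1))
  if (anyNA(pos)) stop("every term must carry a position", call. = FALSE)
  if (anyDuplicated(pos)) stop("duplicate term positions", call. = FALSE)
  if (!setequal(pos, seq_len(n) - 1L))
    stop("term positions must be 0-based and consecutive", call. = FALSE)

  getChr <- function(x, key) {
    v <- x[[key]]
    if (is.null(v)) NA_character_ else as.character(v)
  }
  ord <- order(pos)
  rows <- lapply(doc$terms[ord], function(x) {
    variant <- getChr(x, "variant")
    if (is.na(variant) || !variant %in% c("filled", "prefilled", "empty"))
      stop("term at position ", x$position,
           " has a missing or invalid variant", call. = FALSE)
    role <- getChr(x, "role")
    placeholder <- getChr(x, "placeholder")
    if (is.na(placeholder) && !is.na(role) && role %in% names(.placeholders))
      placeholder <- unname(.placeholders[[role]])
    data.frame(variant = variant, label = getChr(x, "label"),
               id = getChr(x, "id"), fieldId = getChr(x, "fieldId"),
               role = role, placeholder = placeholder,
               stringsAsFactors = FALSE)
  })
  terms <- do.call(rbind, rows)
  rownames(terms) <- NULL

  connectors <- lapply(doc$connectors, function(cn) {
    cn <- as.integer(unlist(cn))
    if (length(cn) != 3L)
      stop("connectors must be tridents of exactly 3 term positions",
           call. = FALSE)
    if (any(cn < 0L) || any(cn >= n))
      stop("connector endpoint ", cn[which(cn < 0L | cn >= n)[1]],
           " does not attach to a term (", n, " terms present)",
           call. = FALSE)
    if (anyDuplicated(cn))
      stop("connector endpoints must be pairwise distinct", call. = FALSE)
    cn
  })
  VsmSentence(terms, connectors)
}

#' Canonical VSM-JSON serialization of a sentence
#'
#' Relabels field tokens in sentence order (`f1`, `f2`, ...) before
#' serializing, so that two sentences that differ only in their opaque
#' field tokens serialize identically. Used as the graph-isomorphism
#' oracle for template mutation.
#'
#' @param sentence A [VsmSentence].
#' @return JSON text.
#' @export
canonicalVsmJson <- function(sentence) {
  t <- sentence@terms
  old <- t$fieldId[!is.na(t$fieldId)]
  t$fieldId[!is.na(t$fieldId)] <- paste0("f", seq_along(old))
  sentence@terms <- t
  toVsmJson(sentence)
}
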