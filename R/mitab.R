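#' @include causal-json.R
NULL

#' CausalTAB (PSI-MITAB2.8) column names
#'
#' The 46-column layout of PSI-MITAB2.8: the 42 columns of MITAB2.7
#' extended with the four causal columns (biological effect of interactor
#' A/B, causal regulatory mechanism, causal statement).
#'
#' @return Character vector of length 46.
#' @export
causalTabColumns <- function() .mitabColumns

.mitabColumns <- c(
  "ID(s) interactor A", "ID(s) interactor B",
  "Alt. ID(s) interactor A", "Alt. ID(s) interactor B",
  "Alias(es) interactor A", "Alias(es) interactor B",
  "Interaction detection method(s)", "Publication 1st author(s)",
  "Publication Identifier(s)", "Taxid interactor A", "Taxid interactor B",
  "Interaction type(s)", "Source database(s)", "Interaction identifier(s)",
  "Confidence value(s)", "Expansion method(s)",
  "Biological role(s) interactor A", "Biological role(s) interactor B",
  "Experimental role(s) interactor A", "Experimental role(s) interactor B",
  "Type(s) interactor A", "Type(s) interactor B",
  "Xref(s) interactor A", "Xref(s) interactor B", "Interaction Xref(s)",
  "Annotation(s) interactor A", "Annotation(s) interactor B",
  "Interaction annotation(s)", "Host organism(s)",
  "Interaction parameter(s)", "Creation date", "Update date",
  "Checksum(s) interactor A", "Checksum(s) interactor B",
  "Interaction Checksum(s)", "Negative",
  "Feature(s) interactor A", "Feature(s) interactor B",
  "Stoichiometry(s) interactor A", "Stoichiometry(s) interactor B",
  "Identification method participant A", "Identification method participant B",
  "Biological effect of interactor A", "Biological effect of interactor B",
  "Causal regulatory mechanism", "Causal statement")

# ---------------------------------------------------------------------------
# MITAB value escaping: multi-values are pipe-separated; a token containing
# a reserved character (tab, pipe, parentheses, quote, colon) is wrapped in
# double quotes with inner quotes backslash-escaped.

.mitabNeedsQuote <- function(x) grepl('[\t|()":]', x)

.mitabQuote <- function(x) {
  if (.mitabNeedsQuote(x))
    paste0('"', gsub('"', '\\\\"', x), '"')
  else x
}

# one cell entry: prefix:local(description), CURIE written verbatim
.mitabEntry <- function(id, desc = NULL) {
  prefix <- .curiePrefix(id)
  local <- sub("^[^:]+:", "", id)
  out <- paste0(prefix, ":", .mitabQuote(local))
  if (!is.null(desc) && nzchar(desc))
    out <- paste0(out, "(", .mitabQuote(desc), ")")
  out
}

.mitabTermEntry <- function(term) .mitabEntry(term@id, term@label)

# split a string on `sep`, honouring double quotes and backslash escapes
.splitQuoteAware <- function(x, sep) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  out <- character()
  buf <- character()
  inQuote <- FALSE
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\\" && i < n) {
      buf <- c(buf, ch, chars[i + 1L])
      i <- i + 2L
      next
    }
    if (ch == '"') inQuote <- !inQuote
    if (ch == sep && !inQuote) {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character()
    } else {
      buf <- c(buf, ch)
    }
    i <- i + 1L
  }
  c(out, paste(buf, collapse = ""))
}

.mitabUnquote <- function(x) {
  x <- trimws(x)
  if (nchar(x) >= 2L && startsWith(x, '"') && endsWith(x, '"'))
    x <- substr(x, 2L, nchar(x) - 1L)
  gsub('\\\\"', '"', x)
}

# parse one `prefix:local(description)` entry into list(id, desc)
.parseMitabEntry <- function(entry) {
  chars <- strsplit(entry, "", fixed = TRUE)[[1]]
  n <- length(chars)
  colonAt <- NA_integer_
  inQuote <- FALSE
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == "\\") next
    if (ch == '"') inQuote <- !inQuote
    if (ch == ":" && !inQuote) { colonAt <- i; break }
  }
  if (is.na(colonAt))
    stop("MITAB entry '", entry, "' has no database prefix", call. = FALSE)
  prefix <- paste(chars[seq_len(colonAt - 1L)], collapse = "")
  rest <- paste(chars[seq(colonAt + 1L, n)], collapse = "")
  desc <- NULL
  # a trailing (description), quote-aware
  m <- regmatches(rest, regexec('^("(?:[^"\\\\]|\\\\.)*"|[^()"]*)(\\((.*)\\))?$',
                                rest, perl = TRUE))[[1]]
  if (length(m) && nzchar(m[2])) {
    local <- .mitabUnquote(m[2])
    if (nzchar(m[3])) desc <- .mitabUnquote(m[4])
  } else {
    local <- .mitabUnquote(rest)
  }
  list(id = paste0(prefix, ":", local), desc = desc)
}

.parseMitabCell <- function(cell) {
  cell <- trimws(cell)
  if (!nzchar(cell) || cell == "-") return(list())
  lapply(.splitQuoteAware(cell, "|"), .parseMitabEntry)
}

# ---------------------------------------------------------------------------
# statement -> record

# MI2CAST -> MITAB column mapping (the documented CausalTAB-supported
# subset): entity id (cols 1/2), entity label as alias (5/6), evidence (7),
# references (9), statement taxon (10/11), biological type (21/22),
# mechanism (45), causal relation (46). Everything else has no CausalTAB
# column and is dropped with a lossiness log.
.mitabDropped <- function(statement) {
  dropped <- character()
  entDrops <- function(entity, side) {
    d <- character()
    if (!is.null(entity@compartment)) d <- c(d, paste0(side, ".compartment"))
    for (i in seq_along(entity@modifications)) {
      m <- entity@modifications[[i]]
      p <- sprintf("%s.modifications[%d]", side, i)
      d <- c(d, p)
      if (!is.null(m@residue)) d <- c(d, paste0(p, ".residue"))
      if (!is.na(m@position)) d <- c(d, paste0(p, ".position"))
    }
    d
  }
  dropped <- c(dropped, entDrops(statement@source, "source"),
               entDrops(statement@target, "target"))
  if (!is.null(statement@compartment)) dropped <- c(dropped, "compartment")
  if (!is.null(statement@cellLine)) dropped <- c(dropped, "cell_line")
  if (!is.null(statement@cellType)) dropped <- c(dropped, "cell_type")
  if (!is.null(statement@tissue)) dropped <- c(dropped, "tissue")
  dropped
}

#' Map a statement onto one CausalTAB record
#'
#' Lossy by design: MI2CAST fields with no CausalTAB column are dropped and
#' reported in the `"dropped"` attribute (the lossiness log). See
#' [mitabSupportedProjection()] for the retained subset.
#'
#' @param statement A valid [CausalStatement].
#' @return Character vector of length 46 (one MITAB cell per column), with
#'   attribute `dropped`: the field paths not representable in CausalTAB.
#' @export
statementToMitab <- function(statement) {
  cells <- rep("-", length(.mitabColumns))
  src <- statement@source; tgt <- statement@target
  cells[1] <- .mitabEntry(src@id)
  cells[2] <- .mitabEntry(tgt@id)
  cells[5] <- .mitabEntry(paste0(.curiePrefix(src@id), ":", src@label),
                          "display_short")
  cells[6] <- .mitabEntry(paste0(.curiePrefix(tgt@id), ":", tgt@label),
                          "display_short")
  if (length(statement@evidence))
    cells[7] <- paste(vapply(statement@evidence, .mitabTermEntry,
                             character(1)), collapse = "|")
  if (length(statement@references))
    cells[9] <- paste(vapply(statement@references, .mitabEntry, character(1)),
                      collapse = "|")
  if (!is.null(statement@taxon)) {
    cells[10] <- .mitabTermEntry(statement@taxon)
    cells[11] <- cells[10]
  }
  if (!is.null(src@biologicalType))
    cells[21] <- .mitabTermEntry(src@biologicalType)
  if (!is.null(tgt@biologicalType))
    cells[22] <- .mitabTermEntry(tgt@biologicalType)
  cells[36] <- "false"
  if (!is.null(statement@mechanism))
    cells[45] <- .mitabTermEntry(statement@mechanism)
  cells[46] <- .mitabTermEntry(statement@relation)
  structure(cells, dropped = .mitabDropped(statement))
}

#' Restrict a statement to the CausalTAB-representable subset
#'
#' The projection that [readCausalTab()] recovers from
#' [writeCausalTab()] output: entity ids, labels and biological types, the
#' causal relation, references, evidence, mechanism and taxon. The
#' complement is exactly what the lossiness log names.
#'
#' @param statement A [CausalStatement].
#' @return The projected [CausalStatement].
#' @export
mitabSupportedProjection <- function(statement) {
  strip <- function(entity)
    BioEntity(entity@id, entity@label,
              biologicalType = entity@biologicalType)
  CausalStatement(
    source = strip(statement@source), target = strip(statement@target),
    relation = statement@relation, references = statement@references,
    evidence = statement@evidence, mechanism = statement@mechanism,
    taxon = statement@taxon)
}

#' Write statements as a CausalTAB (PSI-MITAB2.8) file
#'
#' @param statements List of valid [CausalStatement] objects.
#' @param includeHeader Emit the `#`-prefixed header row of column names?
#' @param registry Registry used to validate before export.
#' @return Tab-delimited, newline-terminated text with one data row per
#'   statement; attribute `lossiness` holds one character vector of dropped
#'   field paths per statement.
#' @export
writeCausalTab <- function(statements, includeHeader = TRUE,
                           registry = fixtureRegistry()) {
  if (is(statements, "CausalStatement")) statements <- list(statements)
  for (i in seq_along(statements)) {
    rep <- validateStatement(statements[[i]], registry)
    if (nErrors(rep) > 0L)
      stop("statement ", i, " fails MI2CAST validation: ",
           paste(violations(rep)$code[violations(rep)$severity == "ERROR"],
                 collapse = ", "), call. = FALSE)
  }
  records <- lapply(statements, statementToMitab)
  lines <- character()
  if (includeHeader)
    lines <- paste0("#", paste(.mitabColumns, collapse = "\t"))
  lines <- c(lines, vapply(records, paste, character(1), collapse = "\t"))
  structure(paste0(paste(lines, collapse = "\n"), "\n"),
            lossiness = lapply(records, attr, "dropped"))
}

# ---------------------------------------------------------------------------
# reading

.mitabTerm <- function(registry, entry) {
  if (is.null(entry$desc)) {
    t <- tryCatch(resolveTerm(registry, entry$id), error = function(e) NULL)
    if (is.null(t)) {
      warning("cannot resolve '", entry$id,
              "'; keeping the identifier with its local id as label",
              call. = FALSE)
      local <- sub("^[^:]+:", "", entry$id)
      return(OntologyTerm(entry$id, local, .curiePrefix(entry$id)))
    }
    return(t)
  }
  .termFromFill(registry, list(label = entry$desc, id = entry$id))
}

#' Read a CausalTAB (PSI-MITAB2.8) file into causal statements
#'
#' Recovers the MITAB-representable subset of each statement (see
#' [mitabSupportedProjection()]); `#`-prefixed header rows are skipped.
#'
#' @param text TSV text or a path to a file.
#' @param registry Registry used to restore vocabulary names.
#' @return List of [CausalStatement].
#' @export
readCausalTab <- function(text, registry = fixtureRegistry()) {
  if (length(text) == 1L && !grepl("[\t\n]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  out <- list()
  for (li in seq_along(lines)) {
    line <- lines[li]
    if (!nzchar(line) || startsWith(line, "#")) next
    cells <- .splitQuoteAware(line, "\t")
    if (length(cells) != length(.mitabColumns))
      stop("line ", li, ": expected ", length(.mitabColumns),
           " columns, found ", length(cells), call. = FALSE)
    one <- function(i) {
      entries <- .parseMitabCell(cells[i])
      if (length(entries)) entries[[1]] else NULL
    }
    entity <- function(idCol, aliasCol, typeCol) {
      idE <- one(idCol)
      if (is.null(idE))
        stop("line ", li, ": interactor identifier column ", idCol,
             " is empty", call. = FALSE)
      alias <- one(aliasCol)
      label <- if (!is.null(alias)) sub("^[^:]+:", "", alias$id) else
        sub("^[^:]+:", "", idE$id)
      typeE <- one(typeCol)
      BioEntity(idE$id, label,
                biologicalType = if (is.null(typeE)) NULL else
                  .mitabTerm(registry, typeE))
    }
    relE <- one(46)
    mechE <- one(45)
    taxE <- one(10)
    out[[length(out) + 1L]] <- CausalStatement(
      source = entity(1, 5, 21),
      target = entity(2, 6, 22),
      relation = if (is.null(relE)) NULL else .mitabTerm(registry, relE),
      references = vapply(.parseMitabCell(cells[9]),
                          function(e) e$id, character(1)),
      evidence = lapply(.parseMitabCell(cells[7]),
                        function(e) .mitabTerm(registry, e)),
      mechanism = if (is.null(mechE)) NULL else .mitabTerm(registry, mechE),
      taxon = if (is.null(taxE)) NULL else .mitabTerm(registry, taxE))
  }
  out
}
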