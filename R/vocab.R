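#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Field roles and the MI2CAST role -> vocabulary map

#' Field roles known to the annotation model
#'
#' @return Character vector of the role names used throughout the package:
#'   the five mandatory roles (`source_entity`, `target_entity`,
#'   `causal_relation`, `reference`, `evidence`) plus the optional context
#'   roles.
#' @examples fieldRoles()
#' @export
fieldRoles <- function() names(.defaultRoleMap)

# MI2CAST-recommended vocabularies per annotatable role. causal_relation is
# restricted to PSI-MI + Relation Ontology; the rest follow the checklist's
# recommendation table. PubMed and Numeric are virtual namespaces (open-ended
# local ids, no enumerated terms).
.defaultRoleMap <- list(
  source_entity           = "UniProt",
  target_entity           = "UniProt",
  causal_relation         = c("PSI-MI", "RO"),
  reference               = "PubMed",
  evidence                = "ECO",
  biological_type         = "PSI-MI",
  biological_modification = "PSI-MOD",
  residue                 = "ChEBI",
  position                = "Numeric",
  compartment             = "GO",
  mechanism               = "PSI-MI",
  cell_line               = "Cellosaurus",
  cell_type               = "CL",
  tissue                  = "BTO",
  taxon                   = "NCBITaxon")

.virtualVocabs <- data.frame(
  name = c("PubMed", "Numeric"),
  namespace = c("pubmed", "num"),
  virtual = c(TRUE, TRUE),
  stringsAsFactors = FALSE)

#' Allowed vocabularies for a field role
#'
#' @param role A role name from [fieldRoles()].
#' @param registry Optionally, a [VocabRegistry] whose role map should be
#'   consulted instead of the package default.
#' @return Character vector of vocabulary names; always non-empty. The
#'   `causal_relation` role maps to exactly `c("PSI-MI", "RO")`.
#' @examples allowedVocabularies("causal_relation")
#' @export
allowedVocabularies <- function(role, registry = NULL) {
  map <- if (is.null(registry)) .defaultRoleMap else registry@roleMap
  if (!role %in% names(map))
    stop("unknown field role: '", role, "'", call. = FALSE)
  map[[role]]
}

# ---------------------------------------------------------------------------
# Identifier normalization

#' Normalize an identifier to canonical CURIE form
#'
#' The canonical internal form is `PREFIX:LOCAL` with a colon separator.
#' The underscore spelling sometimes seen in print (`"MI_2235"`) is accepted
#' on input: the first underscore is promoted to a colon. The operation is
#' idempotent.
#'
#' @param raw Non-empty identifier string.
#' @return Canonical CURIE string.
#' @examples
#' normalizeId("MI_2235")  # "MI:2235"
#' normalizeId("MI:2235")  # unchanged
#' @export
normalizeId <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop("identifier must be a non-empty string", call. = FALSE)
  x <- trimws(raw)
  if (grepl(":", x, fixed = TRUE)) return(x)
  if (grepl("_", x, fixed = TRUE)) return(sub("_", ":", x))
  stop("cannot normalize '", raw,
       "': no prefix separator (':' or '_') found", call. = FALSE)
}

# ---------------------------------------------------------------------------
# Registry construction

#' Create an empty vocabulary registry
#'
#' The registry starts with the two virtual namespaces (PubMed, Numeric)
#' and the default MI2CAST role map; concrete vocabularies are added with
#' [registerVocabulary()].
#'
#' @param roleMap Role -> vocabulary-name map; defaults to the package's
#'   MI2CAST map (see [allowedVocabularies()]).
#' @return A [VocabRegistry].
#' @export
VocabRegistry <- function(roleMap = .defaultRoleMap) {
  new("VocabRegistry",
      terms = data.frame(id = character(), label = character(),
                         vocabulary = character(), description = character(),
                         stringsAsFactors = FALSE),
      vocabularies = .virtualVocabs,
      roleMap = roleMap)
}

#' @rdname registerVocabulary
setMethod("registerVocabulary", signature("VocabRegistry", "Vocabulary"),
  function(registry, vocab) {
    if (vocab@namespace %in% registry@vocabularies$namespace)
      stop("namespace '", vocab@namespace, "' is already registered",
           call. = FALSE)
    registry@vocabularies <- rbind(
      registry@vocabularies,
      data.frame(name = vocab@name, namespace = vocab@namespace,
                 virtual = FALSE, stringsAsFactors = FALSE))
    if (length(vocab@terms)) {
      add <- data.frame(
        id = vapply(vocab@terms, termId, character(1)),
        label = vapply(vocab@terms, termLabel, character(1)),
        vocabulary = vocab@name,
        description = vapply(vocab@terms, function(t) t@description,
                             character(1)),
        stringsAsFactors = FALSE)
      registry@terms <- rbind(registry@terms, add)
    }
    validObject(registry)
    registry
  })

#' Read a vocabulary fixture file
#'
#' Fixture vocabularies are minimal TSV files with header
#' `id<TAB>label<TAB>vocabulary<TAB>description`, UTF-8, one term per line.
#'
#' @param path Path to the TSV file.
#' @param namespace CURIE prefix of the vocabulary; inferred from the first
#'   term id when omitted.
#' @return A [Vocabulary].
#' @export
readVocabularyTsv <- function(path, namespace = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  need <- c("id", "label", "vocabulary", "description")
  if (!all(need %in% names(df)))
    stop("vocabulary TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(df)) stop("vocabulary TSV '", path, "' contains no terms",
                      call. = FALSE)
  name <- unique(df$vocabulary)
  if (length(name) != 1L)
    stop("one fixture file must hold exactly one vocabulary", call. = FALSE)
  if (is.null(namespace)) namespace <- .curiePrefix(df$id[1])
  terms <- lapply(seq_len(nrow(df)), function(i)
    OntologyTerm(df$id[i], df$label[i], name, df$description[i]))
  Vocabulary(name, namespace, terms)
}

.pkgCache <- new.env(parent = emptyenv())

#' The bundled fixture registry
#'
#' Loads every vocabulary fixture shipped under `inst/extdata/vocab/` (small
#' curated subsets of PSI-MI, Relation Ontology, ECO, GO cellular component,
#' PSI-MOD, ChEBI, UniProt, Cellosaurus, CL, BTO and NCBITaxon) into a
#' [VocabRegistry]. The result is cached for the session.
#'
#' @param rebuild Force re-reading the fixture files.
#' @return A [VocabRegistry].
#' @examples
#' reg <- fixtureRegistry()
#' resolveTerm(reg, "MI:2235")
#' @export
fixtureRegistry <- function(rebuild = FALSE) {
  if (!rebuild && !is.null(.pkgCache$registry)) return(.pkgCache$registry)
  dir <- system.file("extdata", "vocab", package = "mi2cast")
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  reg <- VocabRegistry()
  for (f in files) reg <- registerVocabulary(reg, readVocabularyTsv(f))
  .pkgCache$registry <- reg
  reg
}

# ---------------------------------------------------------------------------
# Resolution

.vocabForPrefix <- function(registry, prefix) {
  v <- registry@vocabularies
  hit <- match(prefix, v$namespace)
  if (is.na(hit)) NULL else v[hit, , drop = FALSE]
}

.synthesizeVirtualTerm <- function(vocabName, id) {
  local <- sub("^[^:]+:", "", id)
  if (!grepl("^[0-9]+$", local))
    stop("'", id, "': local id in virtual namespace must be numeric",
         call. = FALSE)
  if (vocabName == "Numeric" && as.numeric(local) < 1)
    stop("numeric position must be >= 1", call. = FALSE)
  OntologyTerm(id, local, vocabName,
               if (vocabName == "PubMed") "publication reference" else
                 "sequence position")
}

#' @rdname resolveTerm
setMethod("resolveTerm", signature("VocabRegistry", "character"),
  function(registry, id) {
    if (length(id) != 1L || is.na(id) || !nzchar(id))
      stop("id must be a single non-empty string", call. = FALSE)
    if (!grepl(":", id, fixed = TRUE))
      stop("'", id, "' is not in canonical PREFIX:LOCAL form", call. = FALSE)
    voc <- .vocabForPrefix(registry, .curiePrefix(id))
    if (!is.null(voc) && voc$virtual)
      return(.synthesizeVirtualTerm(voc$name, id))
    hit <- match(id, registry@terms$id)
    if (is.na(hit))
      stop("cannot resolve '", id, "': unknown identifier", call. = FALSE)
    row <- registry@terms[hit, ]
    OntologyTerm(row$id, row$label, row$vocabulary, row$description)
  })

# ---------------------------------------------------------------------------
# Autocomplete lookup

#' @rdname lookupTerms
setMethod("lookupTerms", signature("VocabRegistry", "character", "character"),
  function(registry, query, role, limit = 10L) {
    allowed <- allowedVocabularies(role, registry)
    limit <- as.integer(limit)
    if (length(limit) != 1L || is.na(limit) || limit < 1L)
      stop("limit must be >= 1", call. = FALSE)
    query <- trimws(query)
    if (!nzchar(query)) return(list())  # empty query matches nothing
    # virtual vocabularies synthesize the queried value itself
    virt <- registry@vocabularies[registry@vocabularies$virtual &
                                  registry@vocabularies$name %in% allowed, ]
    out <- list()
    if (nrow(virt) && grepl("^[0-9]+$", query)) {
      for (i in seq_len(nrow(virt))) {
        t <- tryCatch(.synthesizeVirtualTerm(
          virt$name[i], paste0(virt$namespace[i], ":", query)),
          error = function(e) NULL)  # e.g. "0" is not a valid position
        if (!is.null(t)) out <- c(out, list(t))
      }
    }
    cand <- registry@terms[registry@terms$vocabulary %in% allowed, ,
                           drop = FALSE]
    if (nrow(cand)) {
      ql <- tolower(query)
      ll <- tolower(cand$label)
      tier <- ifelse(ll == ql, 1L,
              ifelse(startsWith(ll, ql), 2L,
              ifelse(grepl(ql, ll, fixed = TRUE), 3L, NA_integer_)))
      keep <- !is.na(tier)
      cand <- cand[keep, , drop = FALSE]
      ord <- order(tier[keep], cand$label, cand$id, method = "radix")
      cand <- cand[ord, , drop = FALSE]
      hits <- lapply(seq_len(nrow(cand)), function(i)
        OntologyTerm(cand$id[i], cand$label[i], cand$vocabulary[i],
                     cand$description[i]))
      out <- c(out, hits)
    }
    if (length(out) > limit) out <- out[seq_len(limit)]
    out
  })
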