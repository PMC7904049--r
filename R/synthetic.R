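#' @include mitab.R
NULL

# ---------------------------------------------------------------------------
# A small portable pseudo-random generator (Lehmer/Park-Miller minstd) so
# that generated fixtures are bit-identical across platforms and R sessions
# without touching R's global RNG state.

.makePrng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- (as.numeric(seed) %% 2147483646) + 1
  env
}

.prngInt <- function(prng, n) {
  # next state in [1, 2^31-2]; products stay exact in doubles (< 2^53)
  prng$state <- (16807 * prng$state) %% 2147483647
  as.integer(1 + (prng$state %% n))
}

.prngPick <- function(prng, xs) xs[[.prngInt(prng, length(xs))]]

# id pools the generator draws from (all present in the fixture registry);
# relation picks are restricted to genuinely causal terms
.genPools <- list(
  relation = c("MI:2235", "MI:2236", "MI:2240", "MI:2241",
               "RO:0002213", "RO:0002212", "RO:0002211",
               "RO:0002304", "RO:0002305"),
  entity = c("uniprot:P31750", "uniprot:P31749", "uniprot:Q9WUA6",
             "uniprot:O43524", "uniprot:P04637", "uniprot:P06493",
             "uniprot:P42336", "uniprot:Q60823"),
  evidence = c("ECO:0000269", "ECO:0000314", "ECO:0000353",
               "ECO:0000250", "ECO:0007682"),
  biological_type = c("MI:0326", "MI:0250", "MI:0320"),
  biological_modification = c("MOD:00696", "MOD:00492", "MOD:01148",
                              "MOD:00599"),
  residue = c("CHEBI:17115", "CHEBI:16857", "CHEBI:17895", "CHEBI:18019"),
  compartment = c("GO:0005634", "GO:0005737", "GO:0005886", "GO:0005739",
                  "GO:0005576"),
  mechanism = c("MI:0217", "MI:0220", "MI:0192", "MI:0407"),
  cell_line = c("cellosaurus:CVCL_0030", "cellosaurus:CVCL_0031",
                "cellosaurus:CVCL_0045", "cellosaurus:CVCL_0004"),
  cell_type = c("CL:0000057", "CL:0000084", "CL:0000540", "CL:0000182"),
  tissue = c("BTO:0000759", "BTO:0000142", "BTO:0000089", "BTO:0001103"),
  taxon = c("NCBITaxon:9606", "NCBITaxon:10090", "NCBITaxon:10116"))

#' Generate a random valid causal statement
#'
#' Draws terms only from the fixture vocabularies, one slot per feature
#' selected in `profile`. Identical `seed` + `profile` always yield an
#' identical statement (a dedicated portable PRNG is used; R's global RNG
#' is untouched).
#'
#' @param seed Integer seed.
#' @param profile A [FeatureSelection] describing which optional context
#'   to populate; the default is the minimal (mandatory-only) profile.
#' @param registry The vocabulary registry to draw from.
#' @return A [CausalStatement] that passes [isValid()].
#' @export
genStatement <- function(seed, profile = FeatureSelection(),
                         registry = fixtureRegistry()) {
  validObject(profile)
  prng <- .makePrng(seed)
  pickTerm <- function(role) {
    pool <- .genPools[[role]]
    if (is.null(pool) || !length(pool))
      stop("no fixture pool for role '", role, "'", call. = FALSE)
    resolveTerm(registry, .prngPick(prng, pool))
  }
  genEntity <- function(flags, modSubs) {
    t <- pickTerm("entity")
    mods <- lapply(modSubs, function(sf)
      Modification(
        term = pickTerm("biological_modification"),
        residue = if ("residue" %in% sf) pickTerm("residue") else NULL,
        position = if ("position" %in% sf) .prngInt(prng, 1000L) else
          NA_integer_))
    BioEntity(t@id, t@label,
              biologicalType = if ("biological_type" %in% flags)
                pickTerm("biological_type") else NULL,
              modifications = mods,
              compartment = if ("compartment" %in% flags)
                pickTerm("compartment") else NULL)
  }
  relFlag <- function(flag, role) {
    if (flag %in% profile@relationFlags) pickTerm(role) else NULL
  }
  CausalStatement(
    source = genEntity(profile@sourceFlags, profile@sourceModifications),
    target = genEntity(profile@targetFlags, profile@targetModifications),
    relation = pickTerm("relation"),
    references = vapply(seq_len(profile@referenceCount), function(i)
      sprintf("pubmed:%d", 10000000L + .prngInt(prng, 89999999L)),
      character(1)),
    evidence = lapply(seq_len(profile@evidenceCount), function(i)
      pickTerm("evidence")),
    mechanism = relFlag("mechanism", "mechanism"),
    compartment = relFlag("compartment", "compartment"),
    cellLine = relFlag("cell_line", "cell_line"),
    cellType = relFlag("cell_type", "cell_type"),
    tissue = relFlag("tissue", "tissue"),
    taxon = relFlag("taxon", "taxon"))
}

#' Generate a statement that violates exactly one mandatory rule
#'
#' @param seed Integer seed.
#' @param violation One of the ERROR codes in [violationCodes()]
#'   (`VOCAB_VIOLATION` plants a GO term as the causal relation).
#' @param registry The vocabulary registry.
#' @return A [CausalStatement] whose validation report contains exactly the
#'   requested ERROR code and no other ERROR.
#' @export
genInvalid <- function(seed, violation, registry = fixtureRegistry()) {
  s <- genStatement(seed, registry = registry)
  switch(violation,
    MISSING_SOURCE = { s@source <- NULL },
    MISSING_TARGET = { s@target <- NULL },
    MISSING_RELATION = { s@relation <- NULL },
    MISSING_REFERENCE = { s@references <- character() },
    MISSING_EVIDENCE = { s@evidence <- list() },
    VOCAB_VIOLATION = { s@relation <- resolveTerm(registry, "GO:0005634") },
    stop("unknown violation code: '", violation, "'", call. = FALSE))
  s
}

# ---------------------------------------------------------------------------
# Exhaustive selection enumeration

.powerSet <- function(xs) {
  n <- length(xs)
  lapply(seq_len(2^n) - 1L, function(mask)
    xs[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L])
}

# all ordered lists of length 0..maxMods over the subfeature subsets
.modConfigs <- function(maxMods, subfeatureSubsets) {
  out <- list(list())
  if (maxMods < 1L) return(out)
  prev <- list(list())
  for (k in seq_len(maxMods)) {
    nxt <- list()
    for (p in prev)
      for (s in subfeatureSubsets)
        nxt[[length(nxt) + 1L]] <- c(p, list(s))
    out <- c(out, nxt)
    prev <- nxt
  }
  out
}

#' Enumerate all feature selections within bounds
#'
#' Exhaustive, duplicate-free, deterministically ordered enumeration of
#' every [FeatureSelection] with reference/evidence counters up to
#' `maxCounter`, up to `maxModifications` modifications per side, and the
#' given families of flag subsets (by default: the full power sets, which
#' grows combinatorially — restrict the subset families to keep the
#' enumeration desk-sized).
#'
#' @param maxCounter Upper bound (inclusive, `>= 1`) for the reference and
#'   evidence counters.
#' @param maxModifications Upper bound (`>= 0`) on modifications per side.
#' @param entityFlagSubsets List of entity-flag subsets to enumerate;
#'   default: all subsets of `c("biological_type", "compartment")`.
#' @param relationFlagSubsets List of relation-flag subsets; default: all
#'   64 subsets of the six statement-context flags.
#' @param subfeatureSubsets List of per-modification subfeature subsets;
#'   default: all subsets of `c("residue", "position")`.
#' @return List of [FeatureSelection], always including the minimal
#'   selection first.
#' @export
enumerateSelections <- function(maxCounter, maxModifications,
                                entityFlagSubsets = .powerSet(.entityFlagSet),
                                relationFlagSubsets = .powerSet(.relationFlagSet),
                                subfeatureSubsets = .powerSet(.subfeatureSet)) {
  stopifnot(maxCounter >= 1L, maxModifications >= 0L)
  modCfgs <- .modConfigs(maxModifications, subfeatureSubsets)
  out <- list()
  for (refs in seq_len(maxCounter))
    for (evs in seq_len(maxCounter))
      for (sflags in entityFlagSubsets)
        for (tflags in entityFlagSubsets)
          for (rflags in relationFlagSubsets)
            for (smods in modCfgs)
              for (tmods in modCfgs)
                out[[length(out) + 1L]] <- FeatureSelection(
                  sourceModifications = smods, targetModifications = tmods,
                  sourceFlags = sflags, targetFlags = tflags,
                  relationFlags = rflags,
                  referenceCount = refs, evidenceCount = evs)
  out
}
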