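test_that("vocabulary registration resolves new terms and rejects duplicate namespaces", {
  r <- VocabRegistry()
  expect_error(resolveTerm(r, "MI:2235"), "unknown identifier")
  psimi <- readVocabularyTsv(
    system.file("extdata", "vocab", "psi-mi.tsv", package = "mi2cast"))
  r <- registerVocabulary(r, psimi)
  t <- resolveTerm(r, "MI:2235")
  expect_identical(termLabel(t), "up-regulates")
  expect_identical(termVocabulary(t), "PSI-MI")

  nTerms <- nrow(r@terms)
  r2 <- registerVocabulary(r, Vocabulary("EmptyVoc", "EV", list()))
  expect_identical(nrow(r2@terms), nTerms)

  expect_error(registerVocabulary(r, Vocabulary("PSI-MI-bis", "MI", list())),
               "already registered")
})

test_that("identifier normalization is canonical and idempotent", {
  expect_identical(normalizeId("MI_2235"), "MI:2235")
  expect_identical(normalizeId("MI:2235"), "MI:2235")
  expect_identical(normalizeId(normalizeId("MI_2235")),
                   normalizeId("MI_2235"))
  expect_identical(normalizeId("NCBITaxon_10090"), "NCBITaxon:10090")
  expect_error(normalizeId("2235"), "no prefix separator")
  expect_error(normalizeId(""), "non-empty")
  expect_identical(resolveTerm(reg, normalizeId("MI_2235")),
                   resolveTerm(reg, "MI:2235"))
})

test_that("autocomplete ranks exact, prefix then substring matches and respects roles", {
  hits <- lookupTerms(reg, "up-reg", "causal_relation")
  expect_gt(length(hits), 0L)
  expect_identical(termId(hits[[1]]), "MI:2235")
  expect_identical(termLabel(hits[[1]]), "up-regulates")

  # exact match outranks prefix matches
  exact <- lookupTerms(reg, "up-regulates", "causal_relation")
  expect_identical(termId(exact[[1]]), "MI:2235")
  expect_identical(termId(exact[[2]]), "MI:2236")  # "up-regulates activity"

  # empty query matches nothing
  expect_identical(lookupTerms(reg, "", "causal_relation"), list())
  expect_identical(lookupTerms(reg, "   ", "evidence"), list())

  # role restriction: PSI-MI causal terms are invisible to compartment lookup
  expect_identical(lookupTerms(reg, "up-regulates", "compartment"), list())

  # limit
  expect_length(lookupTerms(reg, "e", "evidence", limit = 2L), 2L)
  expect_error(lookupTerms(reg, "e", "evidence", limit = 0L), "limit")
  expect_error(lookupTerms(reg, "x", "not_a_role"), "unknown field role")
})

test_that("lookup results stay inside the role's allowed vocabularies and resolve to themselves", {
  queries <- c("a", "e", "re", "up", "0", "protein")
  for (role in fieldRoles()) {
    allowed <- allowedVocabularies(role)
    for (q in queries) {
      hits <- lookupTerms(reg, q, role, limit = 50L)
      for (h in hits) {
        expect_true(termVocabulary(h) %in% allowed)
        expect_identical(resolveTerm(reg, termId(h)), h)
      }
      # determinism
      expect_identical(hits, lookupTerms(reg, q, role, limit = 50L))
    }
  }
})

test_that("lookup closure matches a brute-force filter of all fixture terms", {
  # independent oracle: substring-match every registry term, filter by the
  # role's allowed vocabularies, compare the id sets
  for (role in c("causal_relation", "compartment", "evidence", "mechanism")) {
    allowed <- allowedVocabularies(role)
    for (q in c("regulates", "e", "nucleus")) {
      hits <- lookupTerms(reg, q, role, limit = 100L)
      expected <- reg@terms$id[
        grepl(tolower(q), tolower(reg@terms$label), fixed = TRUE) &
        reg@terms$vocabulary %in% allowed]
      expect_setequal(vapply(hits, termId, character(1)), expected)
    }
  }
})

test_that("the role map restricts the causal relation to PSI-MI and Relation Ontology", {
  expect_setequal(allowedVocabularies("causal_relation"), c("PSI-MI", "RO"))
  expect_identical(allowedVocabularies("evidence"), "ECO")
  expect_identical(allowedVocabularies("compartment"), "GO")
  for (role in fieldRoles())
    expect_gt(length(allowedVocabularies(role)), 0L)
  expect_error(allowedVocabularies("nope"), "unknown field role")
})

test_that("virtual namespaces synthesize reference and position terms", {
  p <- resolveTerm(reg, "pubmed:12345")
  expect_identical(termLabel(p), "12345")
  expect_identical(termVocabulary(p), "PubMed")
  n <- resolveTerm(reg, "num:92")
  expect_identical(termLabel(n), "92")
  expect_error(resolveTerm(reg, "num:0"), "must be >= 1")
  expect_error(resolveTerm(reg, "pubmed:abc"), "must be numeric")
  expect_error(resolveTerm(reg, "MI:0000000"), "unknown identifier")

  hits <- lookupTerms(reg, "12345", "reference")
  expect_identical(termId(hits[[1]]), "pubmed:12345")
})

test_that("bundled fixtures contain the anchor terms of each recommended vocabulary", {
  anchors <- c("MI:2235", "RO:0002213", "ECO:0000269", "GO:0005634",
               "MOD:00696", "uniprot:P31750")
  labels <- vapply(anchors, function(id) termLabel(resolveTerm(reg, id)),
                   character(1))
  expect_identical(unname(labels[c(1, 6)]), c("up-regulates", "AKT1_MOUSE"))
})
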