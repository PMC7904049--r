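test_that("filling is restricted to the field's allowed vocabularies", {
  tpl <- generateTemplate(FeatureSelection())
  relId <- fieldIdFor(tpl, "causal_relation")
  srcId <- fieldIdFor(tpl, "source_entity")

  out <- fillField(tpl, relId, resolveTerm(reg, "MI:2235"), reg)
  t <- vsmTerms(out)
  row <- t[!is.na(t$fieldId) & t$fieldId == relId, ]
  expect_identical(row$variant, "filled")
  expect_identical(row$label, "up-regulates")

  out <- fillField(out, srcId, resolveTerm(reg, "uniprot:P31750"), reg)
  expect_identical(sum(vsmTerms(out)$variant == "filled"), 2L)

  err <- tryCatch(fillField(tpl, relId, resolveTerm(reg, "GO:0005634"), reg),
                  error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "causal_relation")
  expect_match(conditionMessage(err), "PSI-MI, RO")

  expect_error(fillField(tpl, "f999", resolveTerm(reg, "MI:2235"), reg),
               "no field")
})

test_that("completeness requires every field to be filled", {
  tpl <- generateTemplate(FeatureSelection(evidenceCount = 2L))
  expect_false(isComplete(tpl))
  s <- genStatement(11L, registry = reg)
  expect_true(isComplete(statementToSentence(s)))
  # one of two evidence fields filled is still incomplete
  partial <- fillField(tpl, fieldIdFor(tpl, "evidence"),
                       resolveTerm(reg, "ECO:0000269"), reg)
  expect_false(isComplete(partial))
})

test_that("VSM-JSON serialization round-trips structurally", {
  # a fresh template (empty fields, placeholders, lookup config)
  tpl <- generateTemplate(figSelection())
  expect_sentence_identical(fromVsmJson(toVsmJson(tpl)), tpl)

  # filled sentences from synthetic statements
  for (seed in c(21L, 22L, 23L)) {
    sen <- statementToSentence(genStatement(seed, rtProfiles()[[7]], reg))
    expect_sentence_identical(fromVsmJson(toVsmJson(sen)), sen)
  }

  # degenerate single-term sentence with no connectors
  one <- VsmSentence(
    data.frame(variant = "filled", label = "x", id = "MI:2235",
               fieldId = "f1", role = "causal_relation",
               placeholder = "causal relation", stringsAsFactors = FALSE),
    list())
  expect_sentence_identical(fromVsmJson(toVsmJson(one)), one)
})

test_that("malformed VSM-JSON is rejected with the violated rule", {
  tpl <- generateTemplate(FeatureSelection())
  doc <- jsonlite::fromJSON(toVsmJson(tpl), simplifyVector = FALSE)

  bad <- doc; bad$connectors[[1]] <- list(0L, 1L, 99L)
  expect_error(fromVsmJson(jsonlite::toJSON(bad, auto_unbox = TRUE)),
               "does not attach to a term")

  bad <- doc; bad$terms[[2]]$position <- 0L
  expect_error(fromVsmJson(jsonlite::toJSON(bad, auto_unbox = TRUE)),
               "duplicate term positions")

  bad <- doc; bad$connectors[[1]] <- list(0L, 1L)
  expect_error(fromVsmJson(jsonlite::toJSON(bad, auto_unbox = TRUE)),
               "tridents")

  bad <- doc; bad$connectors[[1]] <- list(0L, 1L, 1L)
  expect_error(fromVsmJson(jsonlite::toJSON(bad, auto_unbox = TRUE)),
               "pairwise distinct")

  expect_error(fromVsmJson("{not json"), "malformed JSON")
  light <- toVsmJsonLight(tpl)
  expect_error(fromVsmJson(light), "lossy projection")
})

test_that("the light form is a projection of the full form", {
  sens <- c(list(generateTemplate(figSelection())),
            lapply(c(31L, 32L), function(s)
              statementToSentence(genStatement(s, rtProfiles()[[5]], reg))))
  for (sen in sens) {
    full <- jsonlite::fromJSON(toVsmJson(sen), simplifyVector = FALSE)
    light <- jsonlite::fromJSON(toVsmJsonLight(sen), simplifyVector = FALSE)
    expect_identical(length(light$terms), length(full$terms))
    expect_identical(light$connectors, full$connectors)
    for (i in seq_along(light$terms)) {
      lt <- light$terms[[i]]; ft <- full$terms[[i]]
      # no template data in the light form
      expect_true(all(names(lt) %in%
                      c("position", "variant", "label", "id", "role")))
      # every id/label couple present in the full form
      expect_identical(lt$label, ft$label)
      expect_identical(lt$id, ft$id)
      expect_identical(lt$position, ft$position)
      # empty fields keep their role (but not the autocomplete filter)
      if (identical(ft$variant, "empty")) expect_identical(lt$role, ft$role)
    }
  }
})

test_that("a filled panel interprets into the annotated statement", {
  tpl <- generateTemplate(figSelection())
  f <- annotatableFields(tpl)
  fid <- function(role) f$fieldId[f$role == role]
  tpl <- fillField(tpl, fid("source_entity"),
                   resolveTerm(reg, "uniprot:P31750"), reg)
  tpl <- fillField(tpl, fid("biological_modification"),
                   resolveTerm(reg, "MOD:00696"), reg)
  tpl <- fillField(tpl, fid("causal_relation"),
                   resolveTerm(reg, "MI:2235"), reg)
  tpl <- fillField(tpl, fid("target_entity"),
                   resolveTerm(reg, "uniprot:Q9WUA6"), reg)
  tpl <- fillField(tpl, fid("compartment"),
                   resolveTerm(reg, "GO:0005737"), reg)
  tpl <- fillField(tpl, fid("reference"),
                   resolveTerm(reg, "pubmed:31160049"), reg)
  tpl <- fillField(tpl, fid("evidence"),
                   resolveTerm(reg, "ECO:0000269"), reg)
  s <- sentenceToStatement(tpl, reg)
  expect_true(isValid(s, reg))
  expect_identical(s@source@label, "AKT1_MOUSE")
  expect_length(s@source@modifications, 1L)
  expect_identical(s@source@modifications[[1]]@term@id, "MOD:00696")
  expect_identical(s@compartment@id, "GO:0005737")
  expect_identical(s@references, "pubmed:31160049")
})

test_that("interpretation refuses incomplete sentences", {
  tpl <- generateTemplate(FeatureSelection())
  expect_error(sentenceToStatement(tpl, reg), "empty fields")
  expect_error(sentenceToStatement(
    fillField(tpl, fieldIdFor(tpl, "causal_relation"),
              resolveTerm(reg, "MI:2235"), reg), reg), "empty fields")
})

test_that("statement and sentence forms are mutually inverse", {
  # minimal statement -> a 5-field filled sentence
  s <- genStatement(40L, registry = reg)
  sen <- statementToSentence(s)
  f <- annotatableFields(sen)
  expect_identical(nrow(f), 5L)
  expect_true(all(f$variant == "filled"))
  expect_statement_equal(sentenceToStatement(sen, reg), s)

  # two source modifications, each with its own position
  prof <- FeatureSelection(sourceModifications = list("position", "position"))
  s2 <- genStatement(41L, prof, reg)
  sen2 <- statementToSentence(s2)
  t <- vsmTerms(sen2)
  posFields <- which(!is.na(t$role) & t$role == "position") - 1L
  modFields <- which(!is.na(t$role) & t$role == "biological_modification") - 1L
  bearers <- vapply(posFields, function(p) {
    cn <- Filter(function(c) c[3] == p, vsmConnectors(sen2))[[1]]
    cn[1]
  }, integer(1))
  expect_setequal(bearers, modFields)  # each position on its own modification
  expect_statement_equal(sentenceToStatement(sen2, reg), s2)

  expect_error(statementToSentence(genInvalid(5L, "MISSING_TARGET", reg)),
               "mandatory MI2CAST rules")
})

test_that("every connector in generated and synthetic sentences is a legal trident", {
  sens <- c(
    lapply(list(FeatureSelection(), figSelection(), rtProfiles()[[7]]),
           generateTemplate),
    lapply(c(51L, 52L, 53L), function(s)
      statementToSentence(genStatement(s, rtProfiles()[[3]], reg))))
  for (sen in sens) {
    n <- nrow(vsmTerms(sen))
    inConnector <- logical(n)
    for (cn in vsmConnectors(sen)) {
      expect_length(cn, 3L)
      expect_true(all(cn >= 0L & cn < n))
      expect_identical(anyDuplicated(cn), 0L)
      inConnector[cn + 1L] <- TRUE
    }
    expect_true(all(inConnector))  # no isolated terms in these sentences
  }
})
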