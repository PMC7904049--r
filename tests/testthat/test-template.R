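test_that("the minimal selection yields exactly the five mandatory fields", {
  tpl <- generateTemplate(FeatureSelection())
  f <- annotatableFields(tpl)
  expect_setequal(f$role, c("source_entity", "causal_relation",
                            "target_entity", "reference", "evidence"))
  expect_identical(nrow(f), 5L)
  expect_true(all(f$variant == "empty"))
  expect_true(all(nzchar(f$placeholder)))
  # deterministic output
  expect_sentence_identical(tpl, generateTemplate(FeatureSelection()))
})

test_that("counters multiply the reference/evidence fields", {
  tpl <- generateTemplate(FeatureSelection(evidenceCount = 3L))
  f <- annotatableFields(tpl)
  expect_identical(sum(f$role == "evidence"), 3L)
  expect_identical(nrow(f), 7L)  # 4 other mandatory roles + 3 evidence
})

test_that("the modification+compartment selection reproduces the seven-field panel", {
  tpl <- generateTemplate(figSelection())
  f <- annotatableFields(tpl)
  expect_identical(nrow(f), 7L)
  expect_setequal(f$placeholder,
                  c("source entity", "modification", "causal relation",
                    "target entity", "compartment", "reference", "evidence"))
})

test_that("modifications alone carry residue/position subfeatures", {
  expect_setequal(subfeaturesFor("biological_modification"),
                  c("residue", "position"))
  expect_identical(subfeaturesFor("evidence"), character())
  expect_identical(subfeaturesFor("compartment"), character())
  expect_error(subfeaturesFor("nope"), "unknown field role")
})

test_that("added features hang off their anchor through a prefilled relation term", {
  base <- generateTemplate(FeatureSelection())
  srcId <- fieldIdFor(base, "source_entity")
  tpl <- addFeature(base, "biological_modification", srcId)
  t <- vsmTerms(tpl)
  modPos <- which(!is.na(t$role) & t$role == "biological_modification") - 1L
  srcPos <- which(!is.na(t$role) & t$role == "source_entity") - 1L
  hm <- Filter(function(cn) cn[1] == srcPos && cn[3] == modPos,
               vsmConnectors(tpl))
  expect_length(hm, 1L)
  expect_identical(t$label[hm[[1]][2] + 1L], "has modif.")
  expect_identical(t$variant[hm[[1]][2] + 1L], "prefilled")

  # a subfeature attaches to its own modification
  modId <- t$fieldId[modPos + 1L]
  tpl2 <- addFeature(tpl, "position", modId)
  t2 <- vsmTerms(tpl2)
  posPos <- which(!is.na(t2$role) & t2$role == "position") - 1L
  modPos2 <- which(!is.na(t2$fieldId) & t2$fieldId == modId) - 1L
  ap <- Filter(function(cn) cn[3] == posPos, vsmConnectors(tpl2))
  expect_identical(ap[[1]][1], modPos2)
  expect_identical(t2$label[ap[[1]][2] + 1L], "at position")
})

test_that("features cannot attach to incompatible anchors", {
  base <- generateTemplate(FeatureSelection())
  evId <- fieldIdFor(base, "evidence")
  relId <- fieldIdFor(base, "causal_relation")
  expect_error(addFeature(base, "residue", evId), "not an entity")
  expect_error(addFeature(base, "position", relId), "cannot be added")
  expect_error(addFeature(base, "biological_modification", relId),
               "cannot be added")
  expect_error(addFeature(base, "tissue", fieldIdFor(base, "source_entity")),
               "cannot be added")
})

test_that("removal cascades to dependent subfeatures", {
  tpl <- generateTemplate(
    FeatureSelection(sourceModifications = list(c("residue", "position"))))
  f <- annotatableFields(tpl)
  modId <- f$fieldId[f$role == "biological_modification"]
  out <- removeFeature(tpl, modId)
  # modification + residue + position fields and their 3 relation terms
  expect_identical(nrow(vsmTerms(tpl)) - nrow(vsmTerms(out)), 6L)
  expect_identical(length(vsmConnectors(tpl)) - length(vsmConnectors(out)), 3L)
  # isomorphic to the minimal template up to the opaque field tokens
  expect_identical(canonicalVsmJson(out),
                   canonicalVsmJson(generateTemplate(FeatureSelection())))
})

test_that("mandatory fields cannot drop below their minimum multiplicity", {
  base <- generateTemplate(FeatureSelection())
  expect_error(removeFeature(base, fieldIdFor(base, "evidence")),
               "at least one is mandatory")
  expect_error(removeFeature(base, fieldIdFor(base, "reference")),
               "at least one is mandatory")
  expect_error(removeFeature(base, fieldIdFor(base, "source_entity")),
               "mandatory source/target/relation")
  # a second evidence field is removable
  two <- generateTemplate(FeatureSelection(evidenceCount = 2L))
  f <- annotatableFields(two)
  out <- removeFeature(two, f$fieldId[f$role == "evidence"][2])
  expect_identical(sum(annotatableFields(out)$role == "evidence"), 1L)
})

test_that("remove-then-re-add restores an isomorphic template", {
  tpl <- generateTemplate(figSelection())
  f <- annotatableFields(tpl)
  compId <- f$fieldId[f$role == "compartment"]
  relId <- f$fieldId[f$role == "causal_relation"]
  out <- addFeature(removeFeature(tpl, compId), "compartment", relId)
  expect_identical(canonicalVsmJson(out), canonicalVsmJson(tpl))
})

test_that("generation equals the corresponding add-feature sequence in any order", {
  sels <- list(
    figSelection(),
    FeatureSelection(sourceModifications = list(c("residue", "position"),
                                                "position"),
                     targetFlags = "biological_type",
                     relationFlags = c("mechanism", "taxon"),
                     referenceCount = 2L, evidenceCount = 3L),
    FeatureSelection(targetModifications = list("residue"),
                     sourceFlags = c("biological_type", "compartment"),
                     relationFlags = c("compartment", "cell_line",
                                       "cell_type", "tissue")))
  for (sel in sels) {
    direct <- canonicalVsmJson(generateTemplate(sel))
    expect_identical(canonicalVsmJson(buildByAdds(sel)), direct)
    expect_identical(canonicalVsmJson(buildByAdds(sel, reverse = TRUE)),
                     direct)
  }
})

test_that("mutation preserves values already filled elsewhere", {
  tpl <- generateTemplate(figSelection())
  srcId <- fieldIdFor(tpl, "source_entity")
  relId <- fieldIdFor(tpl, "causal_relation")
  tpl <- fillField(tpl, srcId, resolveTerm(reg, "uniprot:P31750"), reg)
  tpl <- fillField(tpl, relId, resolveTerm(reg, "MI:2235"), reg)

  mutated <- addFeature(tpl, "taxon", relId)
  f <- annotatableFields(mutated)
  modId <- f$fieldId[f$role == "biological_modification"]
  mutated <- removeFeature(mutated, modId)
  t <- vsmTerms(mutated)
  expect_identical(t$label[!is.na(t$fieldId) & t$fieldId == srcId],
                   "AKT1_MOUSE")
  expect_identical(t$id[!is.na(t$fieldId) & t$fieldId == relId], "MI:2235")
})

test_that("every selection in a bounded enumeration keeps the mandatory core", {
  sels <- enumerateSelections(
    2L, 1L,
    entityFlagSubsets = list(character(), "biological_type"),
    relationFlagSubsets = list(character(), "compartment"),
    subfeatureSubsets = list(character(), c("residue", "position")))
  expect_gt(length(sels), 100L)
  mandatory <- c("source_entity", "target_entity", "causal_relation",
                 "reference", "evidence")
  for (sel in sels) {
    f <- annotatableFields(generateTemplate(sel))
    expect_true(all(mandatory %in% f$role))
    # field count = adjusted mandatory core + selected optional features
    nOpt <- length(sel@sourceFlags) + length(sel@targetFlags) +
      length(sel@relationFlags) +
      length(sel@sourceModifications) + sum(lengths(sel@sourceModifications)) +
      length(sel@targetModifications) + sum(lengths(sel@targetModifications))
    expect_identical(nrow(f),
                     3L + sel@referenceCount + sel@evidenceCount + nOpt)
  }
})

test_that("selection documents load from JSON and YAML", {
  sel <- readFeatureSelection(system.file("extdata", "examples",
                                          "fig-template.selection.json",
                                          package = "mi2cast"))
  expect_identical(canonicalVsmJson(generateTemplate(sel)),
                   canonicalVsmJson(generateTemplate(figSelection())))

  yml <- tempfile(fileext = ".yaml")
  writeLines(c("source:", "  modifications:", "    - [residue, position]",
               "relation_flags: [taxon]", "evidence_count: 2"), yml)
  sel2 <- readFeatureSelection(yml)
  expect_identical(sel2@sourceModifications,
                   list(c("residue", "position")))
  expect_identical(sel2@relationFlags, "taxon")
  expect_identical(sel2@evidenceCount, 2L)
})
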