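# Shared fixtures and oracles for the suite. The registry is the bundled
# fixture registry; statement equality is checked through the canonical
# causal-JSON serialization, sentence equality structurally.

reg <- fixtureRegistry()

stmtJson <- function(s) writeCausalJson(list(s), reg)

expect_statement_equal <- function(a, b) {
  expect_identical(stmtJson(a), stmtJson(b))
}

expect_sentence_identical <- function(a, b) {
  expect_identical(vsmTerms(a), vsmTerms(b))
  expect_identical(vsmConnectors(a), vsmConnectors(b))
}

# the worked-example selection: one source modification + statement
# compartment (7 annotatable fields)
figSelection <- function() {
  FeatureSelection(sourceModifications = list(character()),
                   relationFlags = "compartment")
}

fieldIdFor <- function(template, role, which = 1L) {
  f <- annotatableFields(template)
  f$fieldId[f$role == role][which]
}

# profiles that jointly cover every optional MI2CAST field at least once
rtProfiles <- function() list(
  FeatureSelection(),
  FeatureSelection(sourceModifications = list(character())),
  FeatureSelection(sourceModifications = list(c("residue", "position")),
                   relationFlags = "compartment"),
  FeatureSelection(targetModifications = list("residue", "position"),
                   sourceFlags = "biological_type"),
  FeatureSelection(sourceFlags = c("biological_type", "compartment"),
                   targetFlags = "biological_type",
                   relationFlags = c("mechanism", "cell_line")),
  FeatureSelection(relationFlags = c("cell_type", "tissue", "taxon"),
                   referenceCount = 2L, evidenceCount = 3L),
  FeatureSelection(sourceModifications = list(c("residue", "position"),
                                              "position"),
                   targetModifications = list(character()),
                   sourceFlags = "compartment",
                   targetFlags = c("biological_type", "compartment"),
                   relationFlags = c("mechanism", "compartment", "cell_line",
                                     "cell_type", "tissue", "taxon"),
                   referenceCount = 3L, evidenceCount = 2L))

genSuite <- function(n, seedBase = 1000L) {
  profiles <- rtProfiles()
  lapply(seq_len(n), function(i)
    genStatement(seedBase + i, profiles[[1L + (i - 1L) %% length(profiles)]],
                 reg))
}

# independent enumeration of the field paths CausalTAB cannot carry
expectedMitabDropped <- function(s) {
  d <- character()
  for (side in c("source", "target")) {
    ent <- slot(s, side)
    if (!is.null(ent@compartment)) d <- c(d, paste0(side, ".compartment"))
    for (i in seq_along(ent@modifications)) {
      m <- ent@modifications[[i]]
      p <- sprintf("%s.modifications[%d]", side, i)
      d <- c(d, p)
      if (!is.null(m@residue)) d <- c(d, paste0(p, ".residue"))
      if (!is.na(m@position)) d <- c(d, paste0(p, ".position"))
    }
  }
  if (!is.null(s@compartment)) d <- c(d, "compartment")
  if (!is.null(s@cellLine)) d <- c(d, "cell_line")
  if (!is.null(s@cellType)) d <- c(d, "cell_type")
  if (!is.null(s@tissue)) d <- c(d, "tissue")
  d
}

# rebuild generateTemplate(sel) from the minimal template by addFeature
# calls; `reverse` flips the order of the independent add groups to
# exercise order-insensitivity
buildByAdds <- function(sel, reverse = FALSE) {
  tpl <- generateTemplate(FeatureSelection())
  srcId <- fieldIdFor(tpl, "source_entity")
  tgtId <- fieldIdFor(tpl, "target_entity")
  relId <- fieldIdFor(tpl, "causal_relation")

  newFieldId <- function(before, after, role) {
    fa <- annotatableFields(after); fb <- annotatableFields(before)
    setdiff(fa$fieldId[fa$role == role], fb$fieldId[fb$role == role])
  }
  addMods <- function(tpl, side, anchor, mods) {
    for (sf in mods) {
      before <- tpl
      tpl <- addFeature(tpl, "biological_modification", anchor)
      modId <- newFieldId(before, tpl, "biological_modification")
      for (sub in c("residue", "position"))
        if (sub %in% sf) tpl <- addFeature(tpl, sub, modId)
    }
    tpl
  }
  steps <- list(
    function(tpl) addMods(tpl, "source", srcId, sel@sourceModifications),
    function(tpl) addMods(tpl, "target", tgtId, sel@targetModifications),
    function(tpl) { for (fl in sel@sourceFlags)
      tpl <- addFeature(tpl, fl, srcId); tpl },
    function(tpl) { for (fl in sel@targetFlags)
      tpl <- addFeature(tpl, fl, tgtId); tpl },
    function(tpl) { for (fl in sel@relationFlags)
      tpl <- addFeature(tpl, fl, relId); tpl },
    function(tpl) { for (i in seq_len(sel@referenceCount - 1L))
      tpl <- addFeature(tpl, "reference", relId); tpl },
    function(tpl) { for (i in seq_len(sel@evidenceCount - 1L))
      tpl <- addFeature(tpl, "evidence", relId); tpl })
  if (reverse) steps <- rev(steps)
  for (st in steps) tpl <- st(tpl)
  tpl
}

# quote-aware column count oracle: strip quoted runs, then count tabs
mitabColumnCount <- function(line) {
  stripped <- gsub('"[^"]*"', "", line)
  length(gregexpr("\t", stripped, fixed = TRUE)[[1]]) + 1L
}
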