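test_that("the causal statement column carries the relation couple", {
  s <- genStatement(71L, registry = reg)
  s@relation <- resolveTerm(reg, "MI:2235")
  cells <- statementToMitab(s)
  expect_length(cells, 46L)
  expect_identical(cells[46], "MI:2235(up-regulates)")
  expect_identical(cells[1], s@source@id)
  expect_identical(cells[3], "-")
})

test_that("records have a fixed width and the lossiness log names dropped fields", {
  prof <- FeatureSelection(sourceModifications = list(c("residue", "position")),
                           relationFlags = c("compartment", "cell_line"))
  s <- genStatement(72L, prof, reg)
  cells <- statementToMitab(s)
  expect_length(cells, 46L)
  expect_setequal(attr(cells, "dropped"),
                  c("source.modifications[1]",
                    "source.modifications[1].residue",
                    "source.modifications[1].position",
                    "compartment", "cell_line"))

  txt <- writeCausalTab(list(s, genStatement(73L, registry = reg)), TRUE, reg)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  expect_length(lines, 3L)  # header + 2 records
  expect_true(startsWith(lines[1], "#ID(s) interactor A"))
  for (line in lines[-1])
    expect_identical(mitabColumnCount(line), 46L)
  # header can be suppressed
  expect_length(strsplit(writeCausalTab(list(s), FALSE, reg),
                         "\n", fixed = TRUE)[[1]], 1L)
})

test_that("reserved characters survive the quoting dialect", {
  s <- genStatement(74L, registry = reg)
  s@source <- BioEntity("uniprot:P00001", "ODD|NAME (v2)")
  txt <- writeCausalTab(list(s), TRUE, reg)
  line <- strsplit(txt, "\n", fixed = TRUE)[[1]][2]
  expect_identical(mitabColumnCount(line), 46L)
  back <- readCausalTab(txt, reg)[[1]]
  expect_identical(back@source@label, "ODD|NAME (v2)")
  expect_identical(back@source@id, "uniprot:P00001")
})

test_that("write-then-read is the identity on the supported subset", {
  suite <- genSuite(40L, seedBase = 7500L)
  txt <- writeCausalTab(suite, TRUE, reg)
  back <- readCausalTab(txt, reg)
  expect_length(back, length(suite))
  for (i in seq_along(suite)) {
    expect_statement_equal(back[[i]], mitabSupportedProjection(suite[[i]]))
    # the lossiness log is exactly the complement of the projection
    expect_setequal(attr(txt, "lossiness")[[i]],
                    expectedMitabDropped(suite[[i]]))
  }
})

test_that("multi-valued cells preserve curation order", {
  prof <- FeatureSelection(referenceCount = 3L, evidenceCount = 2L)
  s <- genStatement(76L, prof, reg)
  back <- readCausalTab(writeCausalTab(list(s), TRUE, reg), reg)[[1]]
  expect_identical(back@references, s@references)
  expect_identical(lapply(back@evidence, termId), lapply(s@evidence, termId))
})

test_that("malformed rows are rejected with their line number", {
  s <- genStatement(77L, registry = reg)
  txt <- writeCausalTab(list(s), TRUE, reg)
  broken <- sub("\tfalse\t", "\t", txt, fixed = TRUE)  # drop one column
  expect_error(readCausalTab(broken, reg), "line 2.*45")
  expect_error(readCausalTab("a\tb\tc\n", reg), "line 1")
})

test_that("empty optional columns read back as absent context", {
  s <- genStatement(78L, registry = reg)  # minimal: taxon/mechanism unset
  cells <- statementToMitab(s)
  expect_identical(cells[10], "-")
  expect_identical(cells[45], "-")
  back <- readCausalTab(writeCausalTab(list(s), TRUE, reg), reg)[[1]]
  expect_null(back@taxon)
  expect_null(back@mechanism)
  expect_null(back@source@biologicalType)
})

test_that("the golden CausalTAB file is byte-stable across runs", {
  prof <- FeatureSelection(sourceModifications = list(c("residue", "position")),
                           relationFlags = c("mechanism", "taxon"),
                           referenceCount = 2L)
  ss <- list(genStatement(101, prof, reg), genStatement(202, registry = reg),
             genStatement(303, prof, reg))
  golden <- system.file("extdata", "examples", "golden.causaltab.tsv",
                        package = "mi2cast")
  expected <- readChar(golden, file.size(golden))
  out <- writeCausalTab(ss, TRUE, reg)
  attributes(out) <- NULL
  expect_identical(out, expected)
})
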