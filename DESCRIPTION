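Package: mi2cast
Title: Build, Validate and Exchange MI2CAST Molecular Causal Statements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for curating molecular causal interactions under
    the MI2CAST (Minimum Information about a Molecular Interaction Causal
    Statement) checklist. Generates Visual Syntax Method (VSM) annotation
    templates from a feature selection, restricts term filling to
    MI2CAST-recommended controlled vocabularies through an offline, pluggable
    registry with prefix autocomplete, validates statements against the
    mandatory and optional MI2CAST rules, and exports to VSM-JSON,
    VSM-JSON-light, causal-JSON and CausalTAB (PSI-MITAB2.8). Ships fixture
    vocabulary subsets, a deterministic synthetic-statement generator for
    testing, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    jsonlite,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'vocab.R'
    'validate.R'
    'template.R'
    'vsm.R'
    'vsm-json.R'
    'causal-json.R'
    'mitab.R'
    'synthetic.R'
    'cli.R'
    'mi2cast-package.R'
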