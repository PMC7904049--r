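# mi2cast

Headless R toolkit for curating **molecular causal statements** under the
MI2CAST checklist (Minimum Information about a Molecular Interaction Causal
Statement). A causal statement is a directed regulatory assertion — a source
biological entity up- or down-regulates the activity of a target entity —
plus the context in which it holds. MI2CAST fixes the mandatory core
(source, target, causal relation, ≥ 1 reference, ≥ 1 evidence term) and the
optional context (protein modifications with residue/position subfeatures,
biological types, compartments, mechanism, cell line, cell type, tissue,
taxon).

The package is for biocurators and curation-tool developers who need the
mechanics of that standard without a browser: it generates Visual Syntax
Method (VSM) annotation templates from a feature selection, restricts term
filling to MI2CAST-recommended controlled vocabularies through an offline
pluggable registry, validates statements against the mandatory rules, and
exports to four interchange formats.

## The model in brief

A VSM template is a sentence of terms — each a couple of readable label and
unique CURIE identifier, or an empty field awaiting one — joined by
**trident connectors**: triples (bearer, relation, argument) of term
positions that each define one semantic subunit. The template always
contains the core triple
*(source entity) —(causal relation)→ (target entity)*; every selected
feature hangs off its anchor through a prefilled relation term (e.g. a
modification attaches to its entity via `has modif.`, a position to its own
modification via `at position`). Validation is a report, not an exception:
`ERROR` codes for the five missing-mandatory elements and for
relation/evidence terms outside their allowed vocabularies
({PSI-MI, Relation Ontology} and ECO respectively), `WARNING`s for optional
context in unexpected namespaces.

## Worked example

```r
library(mi2cast)
reg <- fixtureRegistry()

# Step 1: select features -> generate the template
sel <- FeatureSelection(sourceModifications = list(character()),
                        relationFlags = "compartment")
tpl <- generateTemplate(sel)
tpl
#> VsmSentence: 11 term(s) (7 empty field(s)), 5 connector(s) [template]
#>   <source entity> | has modif. | <modification> | <causal relation> | <target entity> | has compartment | <compartment> | reported in | <reference> | has evidence | <evidence>

# Step 2: vocabulary-restricted autocomplete, then fill
lookupTerms(reg, "up-reg", "causal_relation")
#> OntologyTerm: up-regulates (MI:2235) [PSI-MI]
#> OntologyTerm: up-regulates activity (MI:2236) [PSI-MI]

f <- annotatableFields(tpl)
fid <- function(role) f$fieldId[f$role == role]
tpl <- fillField(tpl, fid("source_entity"), resolveTerm(reg, "uniprot:P31750"), reg)
tpl <- fillField(tpl, fid("biological_modification"), resolveTerm(reg, "MOD:00696"), reg)
tpl <- fillField(tpl, fid("causal_relation"), resolveTerm(reg, "MI:2235"), reg)
tpl <- fillField(tpl, fid("target_entity"), resolveTerm(reg, "uniprot:Q9WUA6"), reg)
tpl <- fillField(tpl, fid("compartment"), resolveTerm(reg, "GO:0005737"), reg)
tpl <- fillField(tpl, fid("reference"), resolveTerm(reg, "pubmed:31160049"), reg)
tpl <- fillField(tpl, fid("evidence"), resolveTerm(reg, "ECO:0000269"), reg)

# Step 3: interpret, validate, export
s <- sentenceToStatement(tpl, reg)
s
#> CausalStatement
#>   AKT1_MOUSE —up-regulates→ FOXO3_MOUSE [2 context/evidence item(s)]
validateStatement(s, reg)
#> ValidationReport: compliant (no violations)
```

The one-line summary reads: phosphorylated AKT1 (mouse) up-regulates FOXO3,
observed in the cytoplasm, with one reference and one evidence item counted
as context. `writeCausalJson(list(s), reg)` serializes every populated slot
losslessly (terms as `{id, label}` objects); `writeCausalTab(list(s))`
emits one 46-column PSI-MITAB2.8 row whose causal-statement column holds
`MI:2235(up-regulates)` and whose lossiness log reports what CausalTAB
cannot carry — here `source.modifications[1], compartment`.

A command-line front end installs as `exec/mi2cast`
(`template`, `validate`, `convert`, `lookup` subcommands; exit codes
0 = success/valid, 1 = validation failure, 2 = I/O or parse failure).

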