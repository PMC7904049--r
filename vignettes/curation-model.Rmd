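---
title: "Curating molecular causal statements with mi2cast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating molecular causal statements with mi2cast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mi2cast)
```

## The annotation model

A *molecular causal statement* asserts that a source biological entity
up- or down-regulates the activity of a target entity, together with the
context in which the assertion holds. The MI2CAST checklist (Minimum
Information about a Molecular Interaction Causal Statement) fixes the
mandatory core of such a statement — a source entity, a target entity, a
causal relation term, at least one literature reference and at least one
evidence term — and enumerates the optional context a curator may add:
the entities' biological type, subcellular location and protein
modifications (each modification optionally carrying a modified residue
and a 1-based sequence position), and statement-level context (biological
mechanism, compartment, cell line, cell type, tissue, taxon).

`mi2cast` implements this model headlessly in three coupled layers:

1. **Template generation.** A `FeatureSelection` mirrors a curation
   tool's configuration panel: per-side modification counters with a
   subfeature subset per modification, per-side entity flags, six
   statement-context flags, and the reference/evidence multiplicity
   counters (never below 1 — those slots are mandatory).
   `generateTemplate()` turns a selection into a Visual Syntax Method
   (VSM) sentence: an ordered list of terms joined by *trident*
   connectors, each assigning a (bearer, relation, argument) triple of
   term positions to one semantic subunit. Connectors attach only to
   terms, and their three endpoints are pairwise distinct.
2. **Vocabulary-restricted filling.** Every empty field carries a role
   that restricts which vocabularies may fill it (`fillField()`,
   `lookupTerms()`). A term is always a couple of readable label and
   unique CURIE identifier.
3. **Validation and export.** `validateStatement()` reports violations
   of the mandatory rules; exporters serialize to causal-JSON (lossless),
   VSM-JSON and its light projection, and CausalTAB (PSI-MITAB2.8, a
   lossy column subset).

## Template structure and its invariants

The template graph always contains one core trident: bearer = source
entity field, relation = causal relation field, argument = target entity
field. Every other feature hangs off its anchor through a trident whose
relation endpoint is a *prefilled* constant relation term:

| feature | anchor | prefilled term |
|---|---|---|
| modification | entity field | `has modif.` |
| residue / position | its own modification field | `has residue` / `at position` |
| biological type | entity field | `is a` |
| compartment | entity field or relation field | `has compartment` |
| mechanism, cell line, cell type, tissue, taxon | relation field | `has mechanism`, `in cell line`, ... |
| reference / evidence | relation field | `reported in` / `has evidence` |

Only `has modif.` is an externally fixed label; the others are package
constants chosen for readability. Anchoring subfeatures on their own
modification keeps multiple modifications unambiguous: two phosphosites
each connect their position to the right modification term.

Term order follows the panel's reading order — source block, causal
relation, target block, statement context (mechanism, compartment, cell
line, cell type, tissue, taxon), references, evidence — and field tokens
(`f1`, `f2`, ...) are assigned in creation order, so generation is fully
deterministic and exports are diffable.

`addFeature()`/`removeFeature()` mutate a template by reconstructing its
structured form from the connector graph, editing it, and re-emitting the
sentence. Consequences that the test suite asserts as properties:

* generation and mutation commute — `generateTemplate(selection)` is
  graph-isomorphic (equal canonical serialization after token
  relabeling, `canonicalVsmJson()`) to generating the minimal template
  and applying the corresponding `addFeature()` calls in any valid
  order;
* removal cascades to dependent subfeatures, so no orphaned
  residue/position fields can exist;
* filled values of unrelated fields survive any mutation;
* the mandatory core can never shrink: source/target/relation fields are
  not removable, and the last reference or evidence field is protected.

## Vocabularies and the role map

The registry is an offline, pluggable access layer: `VocabRegistry` is
the default implementation backed by fixture files, and a live dictionary
client could implement the same generics. The role→vocabulary map is
frozen from the MI2CAST recommendations: entities→UniProt,
relation→{PSI-MI, Relation Ontology} exactly, evidence→ECO,
compartment→GO (cellular component), modification→PSI-MOD,
residue→ChEBI amino-acid terms, mechanism and biological type→PSI-MI,
cell line→Cellosaurus, cell type→CL, tissue→BTO, taxon→NCBITaxon.
Two slots are open-ended rather than enumerable — literature references
and sequence positions — so the registry supports *virtual* namespaces
(`pubmed:`, `num:`) whose resolution synthesizes a term from any positive
integer local id instead of consulting a fixture list.

Autocomplete ranking is deterministic by construction: case-insensitive
exact label matches, then label-prefix matches, then substring matches,
each tier sorted lexicographically by label and id. The empty query
returns nothing rather than the whole vocabulary — lookups stay bounded
and predictable. Identifiers are canonicalized to the OBO-style
`PREFIX:LOCAL` colon form; the underscore print form (`MI_2235`) is
accepted on input only.

The bundled fixtures are small curated subsets (4–12 terms per
vocabulary) anchored on well-known identifiers (`MI:2235` up-regulates,
`GO:0005634` nucleus, `uniprot:P31750` AKT1_MOUSE, `ECO:0000269`, ...).
They are not mirrors of the source ontologies: tests passing against
them demonstrate the mechanics of restriction, ranking and resolution,
not coverage of any real ontology release.

## Validation semantics

`validateStatement()` never raises on content problems; it reports.
Severity is two-valued and frozen in the public enumeration
(`violationCodes()`): the five missing-mandatory-element codes and
namespace violations on the two MI2CAST-restricted roles (relation,
evidence) are `ERROR`s; namespace checks on optional context are
`WARNING`s, because only the five-element core is mandatory. Reports are
emitted in canonical field order (source, target, relation, references,
evidence, context), so validation is pure and reproducible, and
`isValid()` is exactly "zero ERROR rows". Downstream platforms can map
the code enumeration onto their own quality control.

## Serialization choices

**VSM-JSON** is this package's own documented dialect (schema under
`inst/schema/`): a `terms` array with explicit 0-based consecutive
positions and a `connectors` array of 3-element position triples. The
upstream browser widget's wire format is defined in its own repository
and is not claimed or targeted here; an adapter would be separate work.
The **light** form is a strict projection — all ids, labels and
connectors, the roles of still-empty fields, and nothing
template-related (no placeholders, autocomplete configuration or field
tokens) — and is therefore write-only.

**causal-JSON** is field-complete for the model: every populated slot of
every statement round-trips (`readCausalJson(writeCausalJson(S)) = S`).
Terms serialize as `{id, label}` objects, never bare strings. The reader
does its own structural validation with JSON-path error messages and
tolerates unknown keys with a warning. Vocabulary names and descriptions
are not serialized; the reader restores them by resolving ids through the
registry, so exact round-tripping is guaranteed for statements whose
terms come from the registry (the only kind the generator produces).

**CausalTAB** uses the 46-column PSI-MITAB2.8 layout (MITAB2.7 plus the
four causal columns). The documented supported subset is: entity ids
(columns 1/2), labels as aliases (5/6), evidence (7), references (9),
statement taxon (10/11), biological types (21/22), mechanism (45) and
the causal relation (46). Modifications and their subfeatures, entity
and statement compartments, cell line, cell type and tissue have no
column in this mapping; `statementToMitab()` drops them and names each
dropped field path in the lossiness log, which tests verify to be
*exactly* the complement of `mitabSupportedProjection()`. The model has
no biological-effect slot, so columns 43/44 stay empty. Cell values
follow common MITAB practice — `|`-separated multi-values, `-` for empty
cells, `"`-quoting of tokens containing tabs, pipes, parentheses, quotes
or colons, with quote-aware parsing on the way back; CURIEs are written
verbatim as `prefix:local(description)`.

## The synthetic generator

`genStatement(seed, profile)` draws every slot from fixed id pools inside
the fixture vocabularies, using a small embedded Lehmer (minstd) PRNG so
that output is bit-identical across platforms and sessions and R's
global RNG is never touched. Relation picks are restricted to genuinely
causal terms (the up-/down-regulation family and the Relation Ontology
regulation terms) rather than the whole PSI-MI namespace, for realism.
References are synthesized as eight-digit PubMed ids and positions as
integers in 1–1000, a plausible range for protein sequence coordinates.
`genInvalid(seed, code)` plants exactly one fault, which makes
single-fault detection testable by construction. What the generator does
*not* emulate: free-text curation noise, terms outside the fixture
subsets, statements with repeated context slots, or realistic
co-occurrence statistics of biological annotations — so passing round
trips demonstrate structural losslessness, not robustness to arbitrary
real-world files.

`enumerateSelections()` enumerates the full cross product of counters,
per-side modification configurations and flag subsets. The cross product
explodes combinatorially (the full space at counters ≤ 3 with ≤ 2
modifications per side is in the millions), so the property suites run
on a deterministic union of slices that covers every dimension: all
1 024 flag combinations at minimal counters, all 441 modification/
subfeature configurations up to two modifications per side, and all nine
counter combinations up to 3 — about 1 500 templates and 12 500
connectors per run, which keeps the whole suite and the acceptance
script within a few minutes on one CPU. Round-trip suites use 200 seeded
statements cycling through seven profiles that jointly populate every
optional field at least once.

## Degenerate inputs and tie-breaks

* Duplicate CURIEs within a registry, duplicate namespaces, connector
  endpoints out of range or coincident, empty labels, position 0 — all
  rejected at object validity or parse time, with the violated rule in
  the message.
* A sentence with several core triples (more than one causal-relation
  field in connector position 2) is ambiguous and refused.
* Repeated fields (references, evidence, modifications) preserve
  curation order everywhere: sentence position order, JSON array order,
  MITAB pipe order.
* `statementToSentence()` requires a valid statement; conversely
  `sentenceToStatement()` refuses incomplete sentences, so the
  statement↔sentence bijection is only claimed (and tested) on the
  valid/complete domain.

## Known limitations

* The role→vocabulary map beyond the causal relation follows the MI2CAST
  recommendation table as commonly cited, but slots such as cell line
  admit alternatives (e.g. BTO); the map is a frozen package constant,
  replaceable per registry.
* Compartment may be annotated on an entity and on the statement
  simultaneously; whether a curation guideline would ever require both is
  left to the user.
* One compartment/mechanism/cell-line/... per statement: the
  checkbox-style context slots are single-valued, only the
  counter-style slots (references, evidence, modifications) are lists.
* No nested protein-complex templates; the template grammar is fixed to
  the causal-statement shape rather than compiled from a generic
  meta-schema.
* MI-JSON export and live ontology lookups are out of scope; the
  registry interface is the extension point for the latter.
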