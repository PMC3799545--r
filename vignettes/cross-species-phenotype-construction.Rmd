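---
title: "Constructing a cross-species phenotype ontology from EQ definitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing a cross-species phenotype ontology from EQ definitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xspheno)
```

## The problem

Human, mouse and zebrafish phenotype data live in three incompatible
vocabularies. HPO and MPO are *pre-composed*: classes such as
*Hypoglycemia* exist with stable identifiers, and a growing fraction carry
logical definitions in the Entity–Quality (EQ) scheme. ZFIN is
*post-composed*: each annotation assembles a phenotype on the fly from a
PATO quality, a ZFA anatomical entity and a modifier tag. `xspheno` builds
a single reasoned hierarchy over all three and transfers the model-organism
gene annotations onto human genes via orthology.

## The EQ fragment and its structural subsumption

Every phenotype class is interpreted as

```
C ≡ has_part some (Q ⊓ inheres_in some E ⊓ towards some T ⊓ qualifier some PATO:0000460)
```

The `has_part` wrapper is shared by all phenotype classes, so it cancels in
pairwise comparison and is never materialized; this is what lets the
reasoner stay a structural one rather than a full EL calculus with role
chains. `eq_subsumes()` decides `A ⊑ B` by componentwise entailment of
`B`'s conjuncts over the building-block closure (see the README for the
exact rule). Three consequences of the existential semantics are worth
spelling out:

* **Absent conjuncts of the subsumer are entailed.** A quality-only class
  ("decreased concentration of anything") subsumes every anatomically or
  chemically specific refinement of that quality.
* **Absent conjuncts of the subsumee block entailment.** A class with no
  `towards` filler is never placed under one that has one.
* **Extra differentia match pairwise by relation.** Definitions carrying a
  second `inheres_in` filler (relational qualities over two entities) keep
  the first filler as the bearer and the rest as extra differentia; a
  subsumer's extras must each be entailed by one of the subsumee's extras
  under the same relation. This is the conservative reading: it never
  infers a subsumption the definitions do not support.

`classify()` runs the pairwise test over all definitions, prefiltered by
quality ancestry (a candidate subsumer's quality must subsume the
subsumee's, which prunes the quadratic loop cheaply), unions the asserted
`is_a` edges inside each phenotype ontology — through which classes
without logical definitions participate — and any asserted equivalences
(the lexical HP–MP alignments), and transitively closes the result.
Equivalence groups are the strongly connected components. The suite checks
this implementation against an independent brute-force oracle
(exhaustive condition enumeration, Floyd–Warshall closure, mutual-reachability
components) on hundreds of randomized small worlds.

## Bearer entities and the two entity modes

Subclass closure over the building blocks contracts asserted equivalence
axioms (Uberon bridges, and any others) with a union–find before computing
reachability, so equivalent classes are mutually substitutable; an `is_a`
cycle that is *not* explained by equivalences aborts the build as a data
error. `part_of` edges are stored but excluded from the closure by
default. The original OWL pipelines delegate their `part_of` semantics to
axioms that are not reproduced here, and whether phenotype subsumption
propagated across `inheres_in ∘ part_of` chains is not decidable from the
published description — so the conservative `is_a_only` mode is the
default, and `entity_mode = "is_a_plus_part_of"` exposes the liberal
reading for bearer entailment only. The liberal mode provably yields a
superset of subclass pairs (tested as an invariant); neither mode is
claimed to be "the" published semantics.

GO process bearers get one extra treatment. Process cross-products
(`pigmentation ⊓ occurs_in some eye`) are plain equivalences without the
`has_part` wrapper, so a defined process *is* subsumed by its genus. The
pipeline classifies the process definitions first (genus edges plus
pairwise structural subsumption, with `occurs_in` normalized to
`inheres_in`), injects the inferred edges into the building-block graph,
and rebuilds the closure — after which an MP class inhering in *eye
pigmentation* classifies under an HP class inhering in *pigmentation*.

## Qualifier and relation normalization

Some definition files omit the `abnormal` qualifier; `normalize_definitions()`
adds `PATO:0000460` wherever it is missing so that the qualifier conjunct
never spuriously blocks subsumption, and rewrites bearer-position relations
(`occurs_in`, `results_in_morphogenesis_of`, ...) to `inheres_in` via a
config-driven map whose chains must terminate. The operation is idempotent
— a property the suite asserts — and the map is deliberately open: any
relation a cross-product file uses in the bearer position can be declared
`inheres_in`-like without code changes.

## ZP synthesis and identifier stability

Each abnormal post-composed line contributes its (quality, entity) pair;
one class is minted per distinct pair, labelled
`abnormal(ly) <quality label> <entity label>`. Lines whose modifier is not
`abnormal` are dropped and reported — retaining "normal" observations as
differently-qualified classes would poison the equivalence machinery, and
their intended semantics is not recoverable from the annotation format.
Identifiers are assigned by sorting definitions on (quality CURIE, entity
CURIE) and numbering from a configurable base, *except* that a persisted
two-column id map (definition key → ZP id) always wins, so re-releases
keep previously minted ids and only novel definitions receive fresh
numbers. The definition key is the readable `quality|entity` string rather
than a digest: it is stable, collision-free by construction and
greppable.

## Bridging

Uberon bridges are generated from cross-references declared **on** the
Uberon class (never reverse xrefs in the species ontologies, mirroring how
the axiom set is described), one axiom per xref whose prefix is ZFA, MA or
FMA, skipping classes in the `upper_level` subset so that "tissue"-grade
abstractions do not glue unrelated anatomies together. Lexical HP–MP
alignment matches exactly on normalized labels (lowercase, punctuation
stripped, whitespace collapsed); a label naming more than one class on
either side produces no axiom. Exact-synonym participation exists behind a
flag, default off, because the original alignment's recipe is not
specified beyond "lexical matching" — exact label equality is the
reproducible floor, and the axiom count of any given release is bound to
ontology versions anyway.

## Merging and export

Equivalence clusters collapse to their primary id: HP beats MP beats ZP,
ties broken by the lexicographically smallest id. MP outranking ZP when no
HP member exists is this package's own deterministic choice (only the
HP-first rule is externally fixed); it favours the larger curated
vocabulary. The subclass relation is rewritten onto primaries,
transitively reduced (an edge implied by two others is dropped — the suite
checks reduction preserves closure exactly), and exported with `alt_id`
bookkeeping. Every input phenotype id appears exactly once in the export,
as a primary or an alt_id. A single root class in the reserved `CP:`
namespace (`CP:0000001`, "cross-species phenotype") collects otherwise
parentless clusters so downstream tools see a rooted, connected DAG;
building-block classes never appear in the file. The OBO writer is
canonical — stanzas sorted by id, tags in fixed order, lists sorted — so
equal builds are byte-identical, which is also what makes the
shuffled-input determinism tests meaningful.

## Annotation transfer

Human annotations come from joining the disease–phenotype table with the
OMIM and simplified Orphanet disease–gene maps; records identical up to
evidence merge with their evidence unioned, so a gene–phenotype pair
supported by both databases is counted once. Orphanet rows name genes by
symbol and are resolved to Entrez ids through the OMIM map's symbols
(unresolvable symbols are dropped and counted); a converter for the full
Orphanet XML is out of scope, the two-column table being the documented
interface. Mouse annotations are genotype-level; every marker listed for a
genotype receives the annotation (a declared, overridable policy — the
data format does not say which gene of a multi-gene genotype "owns" the
phenotype). Model annotations fan out to *all* orthologous human genes,
with the fan-out counted in the run report, and phenotype ids are rewritten
to cluster primaries through the alt_id lookup before output. The output
row format is four tab-separated fields: Entrez id, human symbol,
`label (CLASS:ID)`, and a provenance field — `symbol (id/ZEBRAF)` or
`symbol (id/MOUSE)` for transfers, `(EVIDENCE/HUMAN)` for direct human
records, the species tags matching the published file's conventions.

## What the synthetic fixtures emulate — and what they do not

`generate_fixture()` builds, from one seed, a complete input set:
a quality tree, one master anatomy tree mirrored into ZFA/MA/FMA with
Uberon cross-references over a configurable fraction of classes, HP/MP
ontologies mixing defined (~80%) and undefined classes with sparse
asserted edges, a post-composed zebrafish file covering a fixed number of
distinct abnormal combinations plus duplicate and "normal" lines,
orthology tables, a genotype-level mouse phenotype report (including one
multi-marker genotype) and OMIM/Orphanet disease maps with one
dual-evidence overlap. Default sizes (12 anatomy classes, 8 qualities,
10 phenotype classes and 8 genes per species, 80% bridging, depth 3) keep
a full pipeline run under a second while still producing non-trivial
cross-species equivalence clusters; they are scale models, chosen once as
plausible miniatures of the real inputs' structure.

With `include_fig1_cases = TRUE` the fixture embeds two hand-built cases:
the hypoglycemia/aldohexose inference, whose sole driver is the single
ChEBI `glucose is_a aldohexose` edge (removing it must remove the
inference), and a microphthalmia-style case in which a synthesized ZP
class (`abnormal(ly) hypoplastic eye`, pinned to `ZP:0003395` through the
id map) and a more specific MP class both classify under an HP class, with
gene annotations in all three species so the downstream query exercises
alt_id resolution, descendant walking and orthology transfer at once. The
embedded axioms are *sufficient* for these inferences; they do not claim
to reconstruct the historical definition files (in particular, laterality
is not modelled — the "bilateral" class is defined simply by decreased
size of the eye).

What passing on fixtures does **not** show: real cross-product files carry
metadata quirks, multi-entity relational qualities and dangling references
at rates the generator does not imitate; real Uberon xrefs are not a clean
partial bijection; and the published class/annotation counts depend on
dated database releases, so no fixture-scale number is comparable to them.
The fixtures validate the machinery — parsing, normalization, reasoning,
merging, transfer and their invariants — not any empirical claim about a
specific release.

## Numerical and degenerate-input choices

* All writers sort; all artifacts are byte-stable under reruns and input
  shuffles. No stage consults the clock, the locale or hash order.
* CURIEs are opaque `PREFIX:LOCAL` strings; a CURIE referenced by a
  definition but absent from the loaded graphs entails only itself and is
  reported once per build.
* Duplicate term ids within one OBO document are a hard error; malformed
  tag lines name their line number; wrong-width annotation lines are
  skipped and counted, never guessed at.
* An empty phenotype file yields a valid build with zero ZP classes; an
  empty cluster set exports a header-only document.
* The OBO writer emits `format-version: 1.2`, a fixed choice (the released
  file's version string is not recorded anywhere recoverable).

## Known limitations

The reasoner is deliberately not an OWL-DL (or even a complete EL)
reasoner: no role chains, no negation, no cardinality, no unsatisfiability
detection. Definitions nested beyond one level of differentia are out of
scope, as is OWL/RDF serialization. Orthology maps are consumed, never
inferred. These boundaries match the EQ fragment the construction actually
uses; widening any of them would mean trading the brute-force verifiability
of the pairwise reasoner for calculus machinery the inputs do not need.
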